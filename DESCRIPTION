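Package: btxbmd
Title: Benchmark-Dose and Mixture Analysis of Occupational BTX Hematotoxicity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for occupational risk analysis of co-exposure to benzene,
    toluene and xylenes (BTX): cumulative-exposure quantification from
    workplace 8h-TWA air monitoring with LOD/2 substitution, four-year
    hematologic decline endpoints and a two-criteria hematological-damage
    classifier, covariate-adjusted and stratified association models,
    generalized weighted-quantile-sum (WQS) mixture regression with bootstrap
    weight stability selection, a dichotomous benchmark-dose suite (eight
    model families, binomial maximum likelihood, Pearson goodness of fit,
    AIC-based model selection, extra-risk BMD and profile-likelihood BMDL),
    and derivation of 8h-TWA reference exposure levels. A calibrated
    synthetic-cohort generator provides fully reproducible worker data for
    testing and simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
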