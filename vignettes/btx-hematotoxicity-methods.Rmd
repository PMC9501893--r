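---
title: "Methods: BTX hematotoxicity, mixture effects and benchmark doses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: BTX hematotoxicity, mixture effects and benchmark doses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(btxbmd)
```

## The problem

Benzene, toluene and xylenes (BTX) co-occur in petrochemical workplaces and
are all suspected hematotoxicants; benzene is an established one. Workers
are exposed for years at concentrations well below current occupational
limits, so the questions of interest are longitudinal: does cumulative
exposure predict a decline in blood parameters, which mixture component
carries the effect, and what daily 8h exposure would keep the risk of
hematological damage below a benchmark over a working life? This package
implements that full chain — exposure metrics, endpoints, single-pollutant
and mixture regressions, benchmark-dose (BMD) estimation and reference
exposure levels (RELs) — plus a synthetic-cohort generator so that every
stage can be exercised and validated without access to worker data.

## Exposure metrics

Ambient 8h-TWA concentrations are monitored per workplace. Below-LOD values
are substituted at LOD/2 (the conventional occupational-hygiene treatment;
LODs default to 0.01 mg/m3 for benzene and 0.02 mg/m3 for toluene and
xylene). Cumulative exposure is `CE = work years x workplace mean 8h-TWA`,
in mg/m3 x year, and is log-transformed for regression. Eligibility
requires at least one year of employment, and mean TWA is at least LOD/2,
so CE is strictly positive and `ln CE` is always defined; this is asserted
at load.

Quantile scoring (quartiles for WQS, tertiles for baseline stratification)
uses linear-interpolation empirical quantiles throughout (the `type = 7`
rule), with values equal to a cut-point assigned to the lower group. The
rule is fixed and documented because tied observations must share a score;
any consistent convention would do, but mixing conventions across stages
would silently shift group counts. For WQS the cut-points are computed on
the training split only and then applied to the validation split, so the
validation data never inform the scoring.

## Hematological endpoints

Decline is baseline minus follow-up, per parameter, positive when the
parameter fell. The damage endpoint is deliberately a two-criteria
disjunction, each requiring at least two parameters, which trades a little
sensitivity for specificity:

1. at least two parameters below the lower reference limit at follow-up.
   MPV is excluded here because no reference interval exists for it. The
   shipped limits table is derived from the Chinese adult reference
   intervals for blood cell analysis (WS/T 405-2012) and is plain,
   replaceable configuration — the classifier takes any limits table keyed
   by parameter and (optionally) sex.
2. at least two parameters whose decline exceeds the sex-specific 95th
   percentile of the cohort's declines. MPV is included here: it has a
   well-defined decline even without a reference interval. The exceedance
   is strict (`>`), matching the percentile construction: by design about
   5% of each sex exceed any single parameter's threshold, and with nine
   roughly independent parameters the two-or-more rate tracks the
   binomial(9, 0.05) tail, near 7%. Correlation between parameters lowers
   the effective number of independent channels, so real cohorts sit
   somewhat off that reference point.

An upper-limit ("abnormally high") criterion is intentionally absent: the
hematological effect of interest is suppression.

## Association models

Paired Student's t-tests compare baseline and follow-up levels. The
dose-response layer is ordinary least squares of decline on `ln CE` with
covariates (age, sex, factory location, BMI, smoking status, pack-years,
drinking status, and the corresponding baseline parameter); the reported
beta is the `ln CE` coefficient, in decline units per ln(mg/m3 x year).
Group comparisons ("covariance analysis") are OLS on a group indicator
plus covariates, with adjusted means evaluated at covariate means.
Stratified analyses refit within strata — dropping the stratum variable
and any covariate that is constant within a stratum — and effect
modification is tested by the Wald F-test on the exposure-by-stratum
product term in the pooled model. Following common practice in this
literature, tests are two-sided at alpha = 0.05 with no multiple-testing
correction; the package reports raw p-values and leaves any correction to
the analyst.

## WQS regression

The weighted-quantile-sum index is `sum_i w_i q_i` over quartile scores
`q_i` in 0..3, with weights on the 2-simplex. Estimation is from first
principles rather than delegated, because the simplex-constrained
likelihood is the methodological core here:

- 40/60 train/validation split (floor of 0.4n training), seeded.
- B = 100 bootstrap resamples of the training set. In each, the Gaussian
  likelihood of `outcome ~ beta1 * index(w) + covariates` is maximized.
  For fixed weights the inner problem is OLS, so only the simplex
  coordinates are searched: weights are parameterized by softmax and
  optimized by quasi-Newton iterations from five deterministic starts
  (the simplex centre and each vertex-leaning corner), which avoids
  boundary pathologies when the likelihood is flat in the weights.
- Weights are aggregated across converged resamples by arithmetic mean
  (default); an alternative mode weights resamples by the magnitude of
  their index coefficient. The aggregation rule is configuration, not a
  claim — the "stability selection" label in the mixture literature does
  not pin down a formula.
- The aggregated weights are frozen and the per-quartile index effect is
  estimated on the validation split by covariate-adjusted OLS.

A single signed index with non-negative weights is fitted (no separate
positive/negative runs). The outcome family is Gaussian (decline is
continuous); the fitting code isolates the likelihood so other families
could be plugged in, but Gaussian is the only implemented one.

## Benchmark-dose suite

Workers are sorted by CE and split into 7–8 contiguous groups; each
group's dose is its median CE, and the 70–200 per-group size window is
treated as a guideline — infeasible cohorts fall back to equal-frequency
groups with a warning rather than failing. Tied CE values never straddle
a boundary. Using the group median as the dose compresses wide groups
(especially the top group of a right-skewed CE distribution, whose mean
exceeds its median): fitted slopes then absorb the extra response from
the group's upper tail, biasing single-cohort BMD estimates downward when
the true BMD is near the top of the dose range. This is a property of the
grouped design itself and is visible in the end-to-end simulations; the
replicate-level sampling distribution still covers the truth.

Eight dichotomous families are fitted by binomial maximum likelihood:
Multistage degree 1 and 2 (`P = g + (1-g)(1 - exp(-b1 d - b2 d^2))`, stage
coefficients >= 0), Gamma and Weibull (background `g` plus the
corresponding CDF, shapes bounded in [0.2, 18]), Logistic and Probit
(`F(a + b d)`, slopes unconstrained), Log-Logistic and Log-Probit
(`g + (1-g) F(a + b ln d)`, slopes >= 0), and Dichotomous Hill
(`g + (v - v g) / (1 + exp(-a - b ln d))` with plateau `v` in (0, 1]).
`Log` is the natural log, and log-dose families return `g` at dose 0 by
continuity. Optimization is bounded quasi-Newton from deterministic
data-driven multi-starts (no RNG is consumed while fitting, so
simulations stay reproducible); convergence and boundary contact are
recorded on the fit.

The BMD solves extra risk `(P(d) - P(0)) / (1 - P(0)) = BMR` (default
10%), in closed form for all families except Logistic and Probit, which
use bracketed root-finding to 1e-8 relative tolerance. The Dichotomous
Hill plateau caps attainable extra risk, so `v <= BMR` is reported as
"BMR unreachable" instead of a number.

The BMDL profiles the likelihood: each family is reparameterized so the
BMD is explicit (one slope-like parameter solved from the BMR constraint),
the remaining parameters are re-maximized at each candidate BMD, and the
BMDL is the smallest candidate whose profiled log-likelihood stays within
`qchisq(0.90, 1) / 2 = 1.35277` of the maximum — the one-sided 95% bound.
The cutoff is stated explicitly because guidance documents often cite the
procedure without the constant. The search scans geometrically below the
BMD and finishes with root-finding; a flat profile (no information below
the BMD) returns the search floor with a warning.

Model selection mirrors EPA practice: keep fits with goodness-of-fit
p > 0.1 (Pearson chi-squared, df = groups − parameters), BMD not above the
maximum group dose, and BMD/BMDL < 3; choose the lowest AIC among
survivors; report "no adequate model" when none survive — never a silent
fallback. Finally `REL = BMDL / working years` (default 40: employment
from age 20 to retirement at 60), with ppm conversion via a configurable
molar volume defaulting to 24.45 L/mol at 25 °C; the convention is exposed
rather than hard-coded because published mg/m3-to-ppm conversions are not
always internally consistent.

## Synthetic cohorts

The generator reproduces the statistical structure the analysis assumes,
calibrated to a petrochemical-worker cohort: ~77% male, age 39.9 ± 6.6 y,
BMI 23.3 ± 3.1, 33% smokers, 47% drinkers, 18.8 ± 7.7 work years, baseline
hemograms with the cohort's means and SDs (e.g. monocytes 0.47 ± 0.23
x10^9/L), median CE near 0.65 / 0.84 / 1.37 mg/m3 x year for benzene /
toluene / xylene, and cross-analyte Spearman correlations near 0.47.

- **Exposure dependence** comes from a Gaussian copula on ln CE; the
  Pearson copula parameter is `2 sin(pi rho_s / 6)` for a target Spearman
  `rho_s`, since only rank correlations are reported for such data. The
  log-scale SDs (0.75 / 0.60 / 0.90) were chosen to give realistic
  right-skewed CE distributions with interquartile ranges matching the
  medians above.
- **Decline** is `baseline − (sum_a beta_a ln CE_a + noise)`, with default
  single-pollutant effects benzene→monocytes 0.012, toluene→lymphocytes
  0.047, xylene→hematocrit 0.259 (decline units per ln(mg/m3 x year)) and
  residual SDs set to the observed decline SDs. Follow-up counts are
  truncated at zero; the truncation rate is logged (about 1% at the
  defaults, dominated by the hematocrit/platelet tails).
- **Damage outcomes** are Bernoulli draws from a configurable
  dose-response mechanism. The default is a one-stage multistage on
  benzene CE with background 0.12 and slope 0.0493 — a true BMD of
  2.14 mg/m3 x year and ~16% overall incidence at the default exposure
  mix. At n ≈ 1000 this true BMD sits at the upper edge of the observed
  dose range, so single cohorts often (correctly) end in "no adequate
  model"; the recovery simulations therefore also use a steeper reference
  mechanism (slope 0.3, true BMD 0.35) that is identifiable inside the
  dose range.
- **Covariates are generated independently of exposure** — no confounding
  — because the joint covariate-exposure structure of real cohorts is not
  identifiable from published marginals. Passing tests on this generator
  shows the estimators are correct under the assumed model; it does not
  show robustness to confounding, measurement error in workplace means,
  informative loss to follow-up, or workplace clustering, none of which
  are simulated.
- One RNG stream per table, derived from the master seed by fixed
  offsets, so regenerating one table never perturbs the others.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use: 2000 workers for copula
rank-correlation checks (±0.05 attainable), 4000–5000 for moment and
effect-recovery checks (3 standard errors), 100–200 replicate cohorts of
n = 1000 with 8 dose groups for BMD sampling-distribution and BMDL
coverage studies, WQS recovery at n = 2000 with B = 100, and null
calibration studies at 60–400 replicates of smaller instances. These sizes
give stable pass/fail behaviour at the stated tolerances while keeping a
full run inside a few minutes on one core.

Likelihood evaluations clamp probabilities to [1e-12, 1 − 1e-12]; the
goodness-of-fit statistic guards fitted probabilities at 1e-8 with a
logged note. Optimizer tolerance is `factr = 1e5` (≈1e-11 relative on the
log-likelihood); profile root-finding stops at 1e-6 relative on the dose.
Degenerate inputs fail loudly by design: constant vectors cannot be
quantile-scored, zero-variance paired differences have no t-statistic,
rank-deficient designs name their collinear columns, and a non-positive-
definite rank-correlation target names the matrix.

## Known limitations

- Group-level BMD only: no covariate adjustment inside the dose-response
  stage, and the group-median dose convention biases BMDs downward when
  the response is convex over a wide top group (see above).
- Gaussian WQS only; quartile scoring discards within-quartile dose
  information by construction.
- The damage classifier's criterion-2 thresholds are estimated from the
  same cohort being classified, so the endpoint is partly relative; this
  mirrors the two-criteria design but means case status is not portable
  across cohorts with different decline distributions.
- The reference-limits table is a default, not an authority; analyses for
  other populations should supply their own limits.
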