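# Shared fixtures, built in code.

# small ambient-sample table with a below-LOD benzene row
ambient_fixture <- function() {
  data.frame(
    workplace_id = c(1, 1, 2, 2),
    analyte = "benzene",
    period = 1:4,
    concentration = c(NA, 0.025, 0.04, 0.012),
    below_lod = c(TRUE, FALSE, FALSE, FALSE),
    lod = 0.01
  )
}

# a complete hemogram row builder
hemogram_row <- function(worker_id = 1, ...) {
  defaults <- c(wbc = 6.5, neutrophils = 3.5, monocytes = 0.47,
                lymphocytes = 2.4, rbc = 5.0, hemoglobin = 152,
                hematocrit = 44, platelets = 244, mpv = 9.5)
  override <- c(...)
  defaults[names(override)] <- override
  as.data.frame(c(list(worker_id = worker_id), as.list(defaults)))
}

# dose-group table drawn from a known one-stage multistage law
multistage_groups <- function(g = 0.05, b1 = 0.3, n = 100,
                              dose = c(0.25, 0.5, 1, 1.5, 2, 3, 4, 6),
                              seed = 42) {
  set.seed(seed)
  p <- g + (1 - g) * (1 - exp(-b1 * dose))
  data.frame(dose = dose, n = n, cases = rbinom(length(dose), n, p))
}

# admissible random parameters per family, for property tests
random_family_params <- function(family) {
  switch(family,
    multistage1 = c(g = runif(1, 0, 0.3), b1 = runif(1, 0.1, 2)),
    multistage2 = c(g = runif(1, 0, 0.3), b1 = runif(1, 0.05, 1),
                    b2 = runif(1, 0.01, 1)),
    gamma = c(g = runif(1, 0, 0.3), shape = runif(1, 0.5, 4),
              rate = runif(1, 0.1, 2)),
    weibull = c(g = runif(1, 0, 0.3), shape = runif(1, 0.5, 4),
                rate = runif(1, 0.1, 2)),
    logistic = c(a = runif(1, -3, 0), b = runif(1, 0.2, 2)),
    probit = c(a = runif(1, -2, 0), b = runif(1, 0.2, 2)),
    log_logistic = c(g = runif(1, 0, 0.3), a = runif(1, -2, 1),
                     b = runif(1, 0.3, 3)),
    log_probit = c(g = runif(1, 0, 0.3), a = runif(1, -1.5, 0.5),
                   b = runif(1, 0.3, 2)),
    dichotomous_hill = c(g = runif(1, 0, 0.2), v = runif(1, 0.4, 1),
                         a = runif(1, -1, 1), b = runif(1, 0.5, 3))
  )
}
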