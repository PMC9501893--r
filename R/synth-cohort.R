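# Synthetic cohort generation.
#
# The generator reproduces the statistical structure the downstream analysis
# assumes: log-normal per-analyte cumulative exposure with cross-analyte
# rank correlation (Gaussian copula), normal baseline hemograms, follow-up
# values driven by linear dose-decline effects on ln-CE plus residual noise,
# and dichotomous damage outcomes drawn from a configurable dose-response
# mechanism. Defaults are calibrated to a petrochemical worker cohort:
# mean age ~40 y, ~77% male, ~19 work years, median CE of roughly
# 0.65 / 0.84 / 1.37 mg/m3 x year for benzene / toluene / xylene, and
# cross-analyte Spearman correlations near 0.47.

#' Specify a synthetic worker cohort
#'
#' @param n_workers cohort size (>= 10).
#' @param seed master integer seed; all tables derive their own RNG stream
#'   from it by fixed offsets.
#' @param sex_male_frac,smoker_frac,drinker_frac proportions in [0, 1].
#' @param age_mean_sd,bmi_mean_sd,workyears_mean_sd length-2 numeric
#'   `c(mean, sd)` for age (years), BMI (kg/m2) and work years.
#' @param ce_log_mean_sd named list per analyte of `c(mean, sd)` on the
#'   ln(mg/m3 x year) scale.
#' @param ce_rank_correlation 3x3 symmetric Spearman correlation target for
#'   CE across analytes, unit diagonal.
#' @param baseline_hemogram_mean_sd named list per hematologic parameter of
#'   `c(mean, sd)`.
#' @param decline_effect_beta named list per analyte: named numeric vector
#'   of per-parameter slopes of decline on ln-CE (decline units per
#'   ln(mg/m3 x year)); absent entries are zero.
#' @param decline_noise_sd named numeric vector of residual decline SD per
#'   parameter.
#' @param damage_mechanism list with `analyte`, `family` and `params`
#'   describing the dose-response law used to simulate true case status
#'   (see [response_probability()]), or `NULL` to skip outcome simulation.
#' @return object of class `btx_cohort_spec`.
#' @export
cohort_spec <- function(n_workers = 1054L,
                        seed = 1L,
                        sex_male_frac = 0.7742,
                        age_mean_sd = c(39.91, 6.57),
                        bmi_mean_sd = c(23.33, 3.11),
                        smoker_frac = 0.3254,
                        drinker_frac = 0.4677,
                        workyears_mean_sd = c(18.75, 7.70),
                        ce_log_mean_sd = list(
                          benzene = c(log(0.65), 0.75),
                          toluene = c(log(0.84), 0.60),
                          xylene  = c(log(1.37), 0.90)),
                        ce_rank_correlation = default_ce_rank_correlation(),
                        baseline_hemogram_mean_sd = default_baseline_hemogram(),
                        decline_effect_beta = default_decline_effects(),
                        decline_noise_sd = default_decline_noise(),
                        damage_mechanism = default_damage_mechanism()) {
  spec <- list(
    n_workers = as.integer(n_workers), seed = as.integer(seed),
    sex_male_frac = sex_male_frac, age_mean_sd = age_mean_sd,
    bmi_mean_sd = bmi_mean_sd, smoker_frac = smoker_frac,
    drinker_frac = drinker_frac, workyears_mean_sd = workyears_mean_sd,
    ce_log_mean_sd = ce_log_mean_sd,
    ce_rank_correlation = ce_rank_correlation,
    baseline_hemogram_mean_sd = baseline_hemogram_mean_sd,
    decline_effect_beta = decline_effect_beta,
    decline_noise_sd = decline_noise_sd,
    damage_mechanism = damage_mechanism
  )
  validate_cohort_spec(spec)
  class(spec) <- "btx_cohort_spec"
  spec
}

validate_cohort_spec <- function(spec) {
  with(spec, {
    if (n_workers < 10L) stop_btx("n_workers must be at least 10")
    for (p in c(sex_male_frac, smoker_frac, drinker_frac)) {
      if (p < 0 || p > 1) stop_btx("proportions must lie in [0, 1]")
    }
    for (ms in list(age_mean_sd, bmi_mean_sd, workyears_mean_sd)) {
      if (length(ms) != 2L || ms[2] <= 0) stop_btx("mean/sd pairs need sd > 0")
    }
    for (a in BTX_ANALYTES) {
      ms <- ce_log_mean_sd[[a]]
      if (is.null(ms) || ms[2] <= 0) stop_btx("ce_log_mean_sd missing or sd <= 0 for %s", a)
    }
    R <- ce_rank_correlation
    if (!isTRUE(all.equal(R, t(R))) || any(diag(R) != 1)) {
      stop_btx("ce_rank_correlation must be symmetric with unit diagonal")
    }
    for (p in HEME_PARAMS) {
      ms <- baseline_hemogram_mean_sd[[p]]
      if (is.null(ms) || ms[2] <= 0) stop_btx("baseline mean/sd missing for %s", p)
      if (is.na(decline_noise_sd[p]) || decline_noise_sd[p] < 0) {
        stop_btx("decline_noise_sd missing for %s", p)
      }
    }
  })
  invisible(spec)
}

#' @rdname cohort_spec
#' @export
default_ce_rank_correlation <- function() {
  R <- matrix(0.47, 3, 3, dimnames = list(BTX_ANALYTES, BTX_ANALYTES))
  diag(R) <- 1
  R
}

#' @rdname cohort_spec
#' @export
default_baseline_hemogram <- function() {
  list(wbc = c(6.49, 1.58), neutrophils = c(3.54, 1.15),
       monocytes = c(0.47, 0.23), lymphocytes = c(2.42, 0.67),
       rbc = c(5.05, 0.60), hemoglobin = c(152.10, 17.93),
       hematocrit = c(43.76, 4.88), platelets = c(243.60, 58.01),
       mpv = c(9.52, 1.18))
}

#' @rdname cohort_spec
#' @export
default_decline_effects <- function() {
  # single-pollutant slopes of decline on ln-CE, calibrated to the observed
  # positive associations: benzene-monocytes, toluene-lymphocytes,
  # xylene-hematocrit
  list(
    benzene = c(monocytes = 0.012),
    toluene = c(lymphocytes = 0.047),
    xylene  = c(hematocrit = 0.259)
  )
}

#' @rdname cohort_spec
#' @export
default_decline_noise <- function() {
  c(wbc = 2.35, neutrophils = 1.03, monocytes = 0.22, lymphocytes = 0.54,
    rbc = 0.39, hemoglobin = 13.85, hematocrit = 3.90, platelets = 38.07,
    mpv = 0.74)
}

#' @rdname cohort_spec
#' @export
default_damage_mechanism <- function() {
  # one-stage multistage with a true benchmark dose of -ln(0.9)/0.0493 =
  # 2.14 mg/m3 x year and ~16% overall incidence at the default CE mix
  list(analyte = "benzene", family = "multistage1",
       params = c(g = 0.12, b1 = 0.0493))
}

# Pearson copula parameter that yields a target Spearman correlation for a
# bivariate Gaussian copula
spearman_to_pearson <- function(rho_s) 2 * sin(pi * rho_s / 6)

#' Generate a synthetic worker cohort
#'
#' Produces the three tables the pipeline consumes: worker records
#' (demographics, lifestyle, work years), paired hemograms with decline,
#' and per-worker exposure profiles. Cross-analyte CE dependence comes from
#' a Gaussian copula on ln-CE whose Pearson parameter is chosen (via the
#' sin transform) to hit the target Spearman rank correlation. Follow-up
#' cell counts are truncated at zero after noise.
#'
#' @param spec a [cohort_spec()].
#' @return list with elements `workers`, `baseline`, `follow_up`, `decline`,
#'   `exposure` (data frames) and `truncation_rate` (fraction of follow-up
#'   values truncated at zero).
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  n <- spec$n_workers
  ids <- seq_len(n)

  # workers table (stream 1)
  set.seed(child_seed(spec$seed, 1L))
  workers <- data.frame(
    worker_id = ids,
    sex = ifelse(stats::runif(n) < spec$sex_male_frac, "male", "female"),
    age = stats::rnorm(n, spec$age_mean_sd[1], spec$age_mean_sd[2]),
    bmi = stats::rnorm(n, spec$bmi_mean_sd[1], spec$bmi_mean_sd[2]),
    smoker = stats::runif(n) < spec$smoker_frac,
    drinker = stats::runif(n) < spec$drinker_frac,
    location = ifelse(stats::runif(n) < 0.3672, "guangzhou", "maoming"),
    work_years = pmax(1, stats::rnorm(n, spec$workyears_mean_sd[1],
                                      spec$workyears_mean_sd[2]))
  )
  workers$pack_years <- ifelse(workers$smoker,
                               pmax(0, stats::rnorm(n, 8.7, 7)), 0)

  # exposure table via Gaussian copula on ln-CE (stream 2)
  set.seed(child_seed(spec$seed, 2L))
  R <- spearman_to_pearson(spec$ce_rank_correlation)
  diag(R) <- 1
  ch <- tryCatch(chol(R), error = function(e) {
    stop_btx("ce_rank_correlation is not positive definite after the Spearman-to-Pearson adjustment")
  })
  z <- matrix(stats::rnorm(n * 3), n, 3) %*% ch
  exposure <- data.frame(worker_id = ids)
  for (j in seq_along(BTX_ANALYTES)) {
    a <- BTX_ANALYTES[j]
    ms <- spec$ce_log_mean_sd[[a]]
    ln_ce <- ms[1] + ms[2] * z[, j]
    exposure[[paste0("ce_", a)]] <- exp(ln_ce)
    exposure[[paste0("ln_ce_", a)]] <- ln_ce
    exposure[[paste0("q_", a)]] <- quantile_score(exp(ln_ce), 4L)
  }

  # hemograms (stream 3): follow-up = baseline - (sum_a beta * lnCE + noise)
  set.seed(child_seed(spec$seed, 3L))
  baseline <- data.frame(worker_id = ids)
  follow_up <- data.frame(worker_id = ids)
  truncated <- 0L
  for (p in HEME_PARAMS) {
    ms <- spec$baseline_hemogram_mean_sd[[p]]
    b <- pmax(0, stats::rnorm(n, ms[1], ms[2]))
    drop <- rep(0, n)
    for (a in BTX_ANALYTES) {
      beta <- spec$decline_effect_beta[[a]][p]
      if (length(beta) == 1L && !is.na(beta)) {
        drop <- drop + beta * exposure[[paste0("ln_ce_", a)]]
      }
    }
    if (spec$decline_noise_sd[p] > 0) {
      drop <- drop + stats::rnorm(n, 0, spec$decline_noise_sd[p])
    }
    f <- b - drop
    truncated <- truncated + sum(f < 0)
    baseline[[p]] <- b
    follow_up[[p]] <- pmax(0, f)
  }
  trunc_rate <- truncated / (n * length(HEME_PARAMS))
  if (trunc_rate > 0) {
    message(sprintf("follow-up truncation at zero: %.3f%% of values",
                    100 * trunc_rate))
  }

  decline <- compute_decline(baseline, follow_up)

  out <- list(workers = workers, baseline = baseline, follow_up = follow_up,
              decline = decline, exposure = exposure,
              truncation_rate = trunc_rate)

  if (!is.null(spec$damage_mechanism)) {
    out$damage <- generate_damage_outcomes(
      exposure, spec$damage_mechanism, seed = child_seed(spec$seed, 4L))
  }
  out
}

#' Generate ambient workplace air samples
#'
#' Concentrations are log-normal per analyte around configurable medians;
#' values below the LOD are flagged and their raw value withheld, matching
#' what a monitoring lab would report.
#'
#' @param workplaces number of workplaces.
#' @param per_workplace samples per (workplace, analyte).
#' @param lod named LOD vector, mg/m3, per analyte.
#' @param median_twa named vector of median 8h-TWA concentrations, mg/m3.
#' @param log_sd log-scale SD of the sample distribution.
#' @param seed integer seed.
#' @return ambient sample data frame (`workplace_id`, `analyte`, `period`,
#'   `concentration`, `below_lod`, `lod`).
#' @export
generate_ambient_samples <- function(workplaces = 32L, per_workplace = 12L,
                                     lod = c(benzene = 0.01, toluene = 0.02,
                                             xylene = 0.02),
                                     median_twa = c(benzene = 0.012,
                                                    toluene = 0.024,
                                                    xylene = 0.068),
                                     log_sd = 0.5, seed = 1L) {
  if (workplaces < 1L || per_workplace < 1L) stop_btx("counts must be >= 1")
  if (any(lod <= 0)) stop_btx("LODs must be positive")
  set.seed(child_seed(seed, 5L))
  rows <- expand.grid(period = seq_len(per_workplace),
                      analyte = BTX_ANALYTES,
                      workplace_id = seq_len(workplaces),
                      stringsAsFactors = FALSE)
  # workplace-level random level shift shared across periods
  wp_shift <- stats::rnorm(workplaces, 0, 0.3)
  conc <- exp(log(median_twa[rows$analyte]) + wp_shift[rows$workplace_id] +
                stats::rnorm(nrow(rows), 0, log_sd))
  below <- conc < lod[rows$analyte]
  data.frame(
    workplace_id = rows$workplace_id,
    analyte = rows$analyte,
    period = rows$period,
    concentration = ifelse(below, NA_real_, conc),
    below_lod = below,
    lod = unname(lod[rows$analyte])
  )
}

#' Simulate dichotomous damage outcomes from a dose-response mechanism
#'
#' Draws Bernoulli case indicators with probability given by the chosen
#' dose-response family evaluated at each worker's cumulative exposure.
#'
#' @param exposure exposure-profile table with a `ce_<analyte>` column.
#' @param mechanism list with `analyte`, `family`, `params` (see
#'   [response_probability()]).
#' @param seed integer seed.
#' @return data frame with `worker_id`, `p_true`, `is_case`.
#' @export
generate_damage_outcomes <- function(exposure, mechanism, seed = 1L) {
  col <- paste0("ce_", mechanism$analyte)
  check_columns(exposure, c("worker_id", col), "exposure table")
  p <- response_probability(mechanism$family, mechanism$params,
                            exposure[[col]])
  set.seed(as.integer(seed %% 2147483587))
  data.frame(worker_id = exposure$worker_id, p_true = p,
             is_case = stats::runif(nrow(exposure)) < p)
}

#' Write cohort tables to CSV
#'
#' @param cohort output of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cohort_csvs <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in c("workers", "baseline", "follow_up", "decline", "exposure",
               "damage")) {
    if (is.null(cohort[[nm]])) next
    path <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(cohort[[nm]], path, row.names = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}
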