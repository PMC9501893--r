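# Binomial maximum-likelihood fitting of the dichotomous families,
# goodness of fit, model selection and reference-level derivation.

binom_loglik <- function(family, p, groups) {
  pr <- .resp_prob(family, p, groups$dose)
  pr <- pmin(pmax(pr, 1e-12), 1 - 1e-12)
  sum(groups$cases * log(pr) + (groups$n - groups$cases) * log(1 - pr))
}

# deterministic multi-start values derived from the observed group
# incidences; no RNG is consumed
family_starts <- function(family, groups) {
  p_obs <- (groups$cases + 0.5) / (groups$n + 1)
  g0 <- min(p_obs)
  g0 <- min(max(g0, 1e-4), 1 - 1e-4)
  dmax <- max(groups$dose)
  p_max <- max(p_obs)
  er_max <- max((p_max - g0) / (1 - g0), 0.05)
  A <- -log(1 - min(er_max, 0.99))
  slope0 <- A / dmax
  mult <- c(0.1, 0.3, 1, 3, 10)

  # intercept/slope starts on the (log-)dose scale from the incidence range
  lin_ab <- function(log_dose) {
    d <- if (log_dose) log(pmax(groups$dose, min(groups$dose[groups$dose > 0]) / 2))
         else groups$dose
    zr <- stats::qlogis(pmin(pmax(p_obs, 0.01), 0.99))
    b <- (max(zr) - min(zr)) / max(diff(range(d)), 1e-6)
    a <- stats::median(zr - b * d)
    c(a = a, b = max(b, 0.1))
  }

  starts <- switch(family,
    multistage1 = lapply(mult, function(m) c(g = g0, b1 = slope0 * m)),
    multistage2 = c(
      lapply(mult, function(m) c(g = g0, b1 = slope0 * m, b2 = 1e-6)),
      lapply(c(0.3, 1, 3), function(m)
        c(g = g0, b1 = slope0 * m / 2, b2 = m * A / dmax^2 / 2))),
    gamma = unlist(lapply(c(0.5, 1, 2), function(s)
      lapply(c(0.3, 1, 3), function(m)
        c(g = g0, shape = s, rate = stats::qgamma(0.5, s) / dmax * m))),
      recursive = FALSE),
    weibull = unlist(lapply(c(0.5, 1, 2), function(s)
      lapply(c(0.3, 1, 3), function(m)
        c(g = g0, shape = s, rate = A / dmax^s * m))),
      recursive = FALSE),
    logistic = {
      ab <- lin_ab(FALSE)
      lapply(c(0.2, 0.5, 1, 2, 5), function(m)
        c(a = ab["a"], b = ab["b"] * m))
    },
    probit = {
      ab <- lin_ab(FALSE)
      lapply(c(0.2, 0.5, 1, 2, 5), function(m)
        c(a = ab["a"] * 0.6, b = ab["b"] * 0.6 * m))
    },
    log_logistic = {
      ab <- lin_ab(TRUE)
      lapply(c(0.2, 0.5, 1, 2, 5), function(m)
        c(g = g0, a = ab["a"], b = max(ab["b"], 0.2) * m))
    },
    log_probit = {
      ab <- lin_ab(TRUE)
      lapply(c(0.2, 0.5, 1, 2, 5), function(m)
        c(g = g0, a = ab["a"] * 0.6, b = max(ab["b"] * 0.6, 0.2) * m))
    },
    dichotomous_hill = {
      ab <- lin_ab(TRUE)
      v0 <- min(max(er_max + 0.1, 0.3), 1)
      unlist(lapply(c(v0, 1), function(v)
        lapply(c(0.3, 1, 3), function(m)
          c(g = g0, v = v, a = ab["a"], b = max(ab["b"], 0.2) * m))),
        recursive = FALSE)
    }
  )
  lapply(starts, function(s) stats::setNames(as.numeric(s),
                                             family_par_names(family)))
}

clamp_to_bounds <- function(par, bounds) {
  pmin(pmax(par, bounds$lower + 1e-10), pmin(bounds$upper - 1e-10, 1e8))
}

#' Fit a dichotomous dose-response model by binomial maximum likelihood
#'
#' Maximizes the grouped binomial log-likelihood
#' `sum(cases * log(P(d)) + (n - cases) * log(1 - P(d)))` within the
#' family's box bounds, using bounded quasi-Newton iterations from a set
#' of deterministic data-driven starts. The best converged solution is
#' kept. Benchmark dose, profile-likelihood BMDL and Pearson goodness of
#' fit are attached.
#'
#' @param groups dose-group table with columns `dose`, `n`, `cases`
#'   (see [assign_dose_groups()]).
#' @param family one of `BMD_FAMILIES`.
#' @param bmr benchmark response (extra risk), default 0.10.
#' @param confidence one-sided confidence level for the BMDL.
#' @param compute_bmdl set `FALSE` to skip the profile (faster).
#' @return object of class `btx_drfit`: family, params, loglik, k, aic,
#'   gof_chi2 / gof_df / gof_p, bmd, bmdl, bmr, converged, boundary.
#' @export
fit_dichotomous <- function(groups, family, bmr = 0.10, confidence = 0.95,
                            compute_bmdl = TRUE) {
  check_columns(groups, c("dose", "n", "cases"), "dose-group table")
  if (nrow(groups) < 3L) stop_btx("need at least 3 dose groups")
  if (anyDuplicated(groups$dose)) stop_btx("group doses must be distinct")
  if (any(groups$cases < 0 | groups$cases > groups$n)) {
    stop_btx("cases must lie in [0, n] per group")
  }
  family <- match.arg(family, BMD_FAMILIES)
  bounds <- family_bounds(family)
  nm <- family_par_names(family)

  negll <- function(par) {
    -binom_loglik(family, as.list(stats::setNames(par, nm)), groups)
  }

  best <- NULL
  for (start in family_starts(family, groups)) {
    start <- clamp_to_bounds(start, bounds)
    res <- tryCatch(
      stats::optim(start, negll, method = "L-BFGS-B",
                   lower = bounds$lower, upper = bounds$upper,
                   control = list(factr = 1e5, maxit = 500)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) {
    stop_btx("optimizer failed for family '%s' from every start", family)
  }

  params <- stats::setNames(best$par, nm)
  loglik <- -best$value
  k <- length(params)
  on_boundary <- any(abs(params - bounds$lower[nm]) < 1e-7) ||
    any(abs(params - pmin(bounds$upper[nm], 1e8)) < 1e-7)

  fit <- structure(list(
    family = family, params = params, loglik = loglik, k = k,
    aic = 2 * k - 2 * loglik, bmr = bmr,
    converged = best$convergence == 0, boundary = on_boundary,
    groups = groups
  ), class = "btx_drfit")

  gof <- goodness_of_fit(fit, groups)
  fit$gof_chi2 <- gof$chi2
  fit$gof_df <- gof$df
  fit$gof_p <- gof$p

  fit$bmd <- tryCatch(solve_bmd(fit, bmr), error = function(e) NA_real_)
  fit$bmdl <- if (compute_bmdl && is.finite(fit$bmd)) {
    tryCatch(profile_bmdl(fit, groups, bmr, confidence),
             error = function(e) NA_real_)
  } else NA_real_
  fit
}

#' @export
print.btx_drfit <- function(x, ...) {
  cat(sprintf("Dichotomous dose-response fit: %s\n", x$family))
  cat("  params:", paste(sprintf("%s = %.5g", names(x$params), x$params),
                         collapse = ", "), "\n")
  cat(sprintf("  logLik = %.3f, AIC = %.3f, GOF chi2 = %.3f (df %d, p = %.3f)\n",
              x$loglik, x$aic, x$gof_chi2, x$gof_df, x$gof_p))
  cat(sprintf("  BMD = %.4g, BMDL = %.4g (BMR = %g extra risk)\n",
              x$bmd, x$bmdl, x$bmr))
  invisible(x)
}

#' Pearson chi-squared goodness of fit for a dose-group fit
#'
#' `chi2 = sum((cases - n*P)^2 / (n*P*(1-P)))` with `df = n_groups - k`
#' and an upper-tail p-value. Fitted probabilities of exactly 0 or 1 are
#' continuity-guarded at 1e-8 with a note.
#'
#' @param fit a `btx_drfit` (or list with `family`, `params`, `k`).
#' @param groups dose-group table.
#' @return list with `chi2`, `df`, `p`.
#' @export
goodness_of_fit <- function(fit, groups) {
  pr <- .resp_prob(fit$family, as.list(fit$params), groups$dose)
  if (any(pr <= 0 | pr >= 1)) {
    message("fitted probabilities at 0 or 1; continuity guard applied")
    pr <- pmin(pmax(pr, 1e-8), 1 - 1e-8)
  }
  chi2 <- sum((groups$cases - groups$n * pr)^2 / (groups$n * pr * (1 - pr)))
  df <- nrow(groups) - fit$k
  p <- if (df >= 1) stats::pchisq(chi2, df, lower.tail = FALSE) else NA_real_
  list(chi2 = chi2, df = df, p = p)
}

#' Fit the full dichotomous model suite to one dose-group table
#'
#' @inheritParams fit_dichotomous
#' @param families families to fit; defaults to the full suite.
#' @return named list of `btx_drfit` objects (failed fits dropped with a
#'   warning).
#' @export
fit_model_suite <- function(groups, families = BMD_FAMILIES, bmr = 0.10,
                            confidence = 0.95) {
  fits <- list()
  for (f in families) {
    fit <- tryCatch(fit_dichotomous(groups, f, bmr, confidence),
                    error = function(e) {
                      warning(sprintf("family '%s' failed: %s", f,
                                      conditionMessage(e)), call. = FALSE)
                      NULL
                    })
    if (!is.null(fit)) fits[[f]] <- fit
  }
  fits
}

#' Select the best adequate dose-response model
#'
#' Filters fits to those with goodness-of-fit p > 0.1, a BMD not above the
#' maximum group dose, and BMD/BMDL < 3; among survivors the fit with the
#' lowest AIC wins. An empty survivor set yields an explicit
#' "no adequate model" result rather than a fallback.
#'
#' @param fits list of `btx_drfit` objects (e.g. [fit_model_suite()]).
#' @param max_dose maximum group dose; taken from the first fit's groups
#'   when omitted.
#' @param gof_min minimum goodness-of-fit p-value, default 0.1.
#' @param bmd_bmdl_ratio_max maximum allowed BMD/BMDL ratio, default 3.
#' @return list of class `btx_model_selection` with `chosen` (a
#'   `btx_drfit` or `NULL`), `adequate` (names), and a diagnostics table.
#' @export
select_best <- function(fits, max_dose = NULL, gof_min = 0.1,
                        bmd_bmdl_ratio_max = 3) {
  if (!length(fits)) stop_btx("no fits supplied")
  if (is.null(max_dose)) max_dose <- max(fits[[1]]$groups$dose)
  diag_tab <- do.call(rbind, lapply(fits, function(f) {
    data.frame(family = f$family, aic = f$aic, gof_p = f$gof_p,
               bmd = f$bmd, bmdl = f$bmdl,
               ratio = ifelse(is.finite(f$bmd) & is.finite(f$bmdl) & f$bmdl > 0,
                              f$bmd / f$bmdl, NA_real_))
  }))
  rownames(diag_tab) <- NULL
  ok <- vapply(fits, function(f) {
    is.finite(f$gof_p) && f$gof_p > gof_min &&
      is.finite(f$bmd) && f$bmd <= max_dose &&
      is.finite(f$bmdl) && f$bmdl > 0 &&
      f$bmd / f$bmdl < bmd_bmdl_ratio_max
  }, logical(1))
  chosen <- NULL
  if (any(ok)) {
    surv <- fits[ok]
    chosen <- surv[[which.min(vapply(surv, `[[`, numeric(1), "aic"))]]
  }
  structure(list(chosen = chosen, adequate = names(fits)[ok],
                 diagnostics = diag_tab,
                 reason = if (is.null(chosen)) "no adequate model" else NULL),
            class = "btx_model_selection")
}

#' @export
print.btx_model_selection <- function(x, ...) {
  if (is.null(x$chosen)) {
    cat("Model selection: no adequate model\n")
  } else {
    cat(sprintf("Model selection: chose '%s' (AIC %.3f) among {%s}\n",
                x$chosen$family, x$chosen$aic,
                paste(x$adequate, collapse = ", ")))
  }
  print(x$diagnostics, digits = 4)
  invisible(x)
}

#' Molecular weights of the BTX analytes (g/mol)
#' @return named numeric vector.
#' @export
btx_molecular_weights <- function() {
  c(benzene = 78.11, toluene = 92.14, xylene = 106.17)
}

#' Derive an 8h-TWA reference exposure level from a BMDL
#'
#' The point of departure (the BMDL, in mg/m3 x year of cumulative
#' exposure) is divided by a full working duration — default 40 years,
#' i.e. employment from age 20 to the legal retirement age of 60 — to
#' give a daily 8h-TWA concentration that keeps lifetime cumulative
#' exposure below the POD. The ppm conversion uses a configurable molar
#' volume (default 24.45 L/mol at 25 degrees C, 1 atm).
#'
#' @param bmdl benchmark-dose lower bound, mg/m3 x year.
#' @param working_years working duration divisor, years.
#' @param molecular_weight g/mol (see [btx_molecular_weights()]).
#' @param molar_volume L/mol.
#' @return list of class `btx_rel`: `bmdl`, `working_years`, `rel_mgm3`,
#'   `rel_ppm`, `molar_volume`.
#' @examples
#' derive_rel(1.559, 40, 78.11)$rel_mgm3  # 0.0390
#' @export
derive_rel <- function(bmdl, working_years = 40, molecular_weight = NA_real_,
                       molar_volume = 24.45) {
  if (bmdl <= 0 || working_years <= 0) {
    stop_btx("bmdl and working_years must be positive")
  }
  bmdl <- unname(bmdl)
  molecular_weight <- unname(molecular_weight)
  rel <- bmdl / working_years
  structure(list(
    bmdl = bmdl, working_years = working_years, rel_mgm3 = rel,
    rel_ppm = if (is.finite(molecular_weight))
      rel * molar_volume / molecular_weight else NA_real_,
    molar_volume = molar_volume
  ), class = "btx_rel")
}

#' @export
print.btx_rel <- function(x, ...) {
  cat(sprintf("8h-TWA REL: %.4f mg/m3 (BMDL %.4g / %g working years)",
              x$rel_mgm3, x$bmdl, x$working_years))
  if (is.finite(x$rel_ppm)) cat(sprintf(" = %.4f ppm", x$rel_ppm))
  cat("\n")
  invisible(x)
}
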