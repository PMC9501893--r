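# Association layer: paired change tests, covariate-adjusted linear models
# of decline on ln-CE, stratified fits and interaction tests.
#
# Modelling follows the conventional occupational-epidemiology analysis:
# ordinary least squares with the exposure on the natural-log scale,
# two-sided alpha = 0.05, no multiple-testing correction.

#' Paired test of baseline vs follow-up parameter levels
#'
#' Classical paired Student's t-test on the per-worker differences
#' (baseline minus follow-up), so a positive mean decline indicates a
#' decrease over follow-up.
#'
#' @param baseline,follow_up aligned numeric vectors.
#' @return list with `mean_decline`, `t`, `df`, `p`.
#' @export
paired_change_test <- function(baseline, follow_up) {
  stopifnot(length(baseline) == length(follow_up))
  d <- baseline - follow_up
  if (length(d) < 2L) stop_btx("need at least two pairs")
  if (stats::var(d) == 0) {
    stop_btx("zero variance of paired differences; t statistic undefined")
  }
  tt <- stats::t.test(d)
  list(mean_decline = mean(d), t = unname(tt$statistic),
       df = unname(tt$parameter), p = tt$p.value)
}

check_full_rank <- function(X) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop_btx("design matrix rank deficient; collinear column(s): %s",
             paste(bad, collapse = ", "))
  }
  invisible(qrX)
}

#' Covariate-adjusted linear model of decline on ln-CE
#'
#' Ordinary least squares of a decline outcome on log cumulative exposure
#' plus covariates; the reported beta is the ln-CE coefficient with its
#' Wald 95% CI and p-value (the trend test).
#'
#' @param decline numeric outcome vector (decline units).
#' @param ln_ce numeric vector of log cumulative exposure.
#' @param covariates data frame of adjustment covariates (may be empty).
#' @return list of class `btx_lm_result`: `beta`, `se`, `ci95`, `p_trend`,
#'   `n`, `model` (the `lm` fit).
#' @export
adjusted_decline_model <- function(decline, ln_ce, covariates = NULL) {
  df <- data.frame(.decline = decline, .ln_ce = ln_ce)
  if (!is.null(covariates) && ncol(covariates)) {
    df <- cbind(df, covariates)
  }
  fml <- stats::as.formula(paste(".decline ~ .ln_ce",
                                 if (!is.null(covariates) && ncol(covariates))
                                   paste("+", paste(sprintf("`%s`",
                                     names(covariates)), collapse = " + "))
                                 else ""))
  X <- stats::model.matrix(stats::update(fml, NULL ~ .), data = df)
  check_full_rank(X)
  fit <- stats::lm(fml, data = df)
  sm <- summary(fit)$coefficients
  beta <- sm[".ln_ce", "Estimate"]
  se <- sm[".ln_ce", "Std. Error"]
  ci <- beta + c(-1, 1) * stats::qt(0.975, fit$df.residual) * se
  structure(list(beta = beta, se = se, ci95 = ci,
                 p_trend = sm[".ln_ce", "Pr(>|t|)"],
                 n = length(decline), model = fit),
            class = "btx_lm_result")
}

#' @export
print.btx_lm_result <- function(x, ...) {
  cat(sprintf("beta = %.4g (95%% CI %.4g, %.4g), p_trend = %.4g, n = %d\n",
              x$beta, x$ci95[1], x$ci95[2], x$p_trend, x$n))
  invisible(x)
}

#' Stratified decline models with an interaction test
#'
#' Fits the covariate-adjusted decline model separately within each level
#' of a categorical stratum variable, and tests effect modification by
#' adding an exposure-by-stratum product term to the pooled model
#' (Wald F-test on the product term(s)).
#'
#' @inheritParams adjusted_decline_model
#' @param stratum factor or character vector with at least two levels.
#' @return list with `strata` (named list of `btx_lm_result`) and
#'   `p_interaction`.
#' @export
stratified_with_interaction <- function(decline, ln_ce, covariates = NULL,
                                        stratum) {
  stratum <- as.factor(stratum)
  if (nlevels(droplevels(stratum)) < 2L) {
    stop_btx("stratified analysis needs at least two strata")
  }
  stratum <- droplevels(stratum)
  n_cov <- if (is.null(covariates)) 0L else ncol(covariates)
  strata <- list()
  for (lv in levels(stratum)) {
    idx <- stratum == lv
    if (sum(idx) < n_cov + 3L) {
      stop_btx("stratum '%s' has too few observations (%d)", lv, sum(idx))
    }
    # the stratum variable itself (and constant covariates within the
    # stratum) are dropped from the within-stratum adjustment set
    cov_s <- if (n_cov) {
      keep <- vapply(covariates, function(col)
        length(unique(col[idx])) > 1L, logical(1))
      covariates[idx, keep, drop = FALSE]
    } else NULL
    strata[[lv]] <- adjusted_decline_model(decline[idx], ln_ce[idx], cov_s)
  }

  df <- data.frame(.decline = decline, .ln_ce = ln_ce, .stratum = stratum)
  if (n_cov) df <- cbind(df, covariates)
  cov_terms <- if (n_cov) paste("+", paste(sprintf("`%s`", names(covariates)),
                                           collapse = " + ")) else ""
  f0 <- stats::as.formula(paste(".decline ~ .ln_ce + .stratum", cov_terms))
  f1 <- stats::as.formula(paste(".decline ~ .ln_ce * .stratum", cov_terms))
  m0 <- stats::lm(f0, data = df)
  m1 <- stats::lm(f1, data = df)
  p_int <- stats::anova(m0, m1)[2, "Pr(>F)"]

  list(strata = strata, p_interaction = p_int)
}

#' Adjusted group comparison of decline magnitude
#'
#' Covariance-analysis style comparison: OLS of decline on a group
#' indicator plus covariates; adjusted group means are predictions at the
#' covariate means, and the group effect is tested by a Wald F-test.
#'
#' @param decline numeric outcome.
#' @param group factor of group membership.
#' @param covariates data frame of covariates.
#' @return list with `adjusted_means` (named), `p_group`.
#' @export
adjusted_group_comparison <- function(decline, group, covariates = NULL) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) < 2L) stop_btx("need at least two groups")
  df <- data.frame(.decline = decline, .group = group)
  if (!is.null(covariates) && ncol(covariates)) df <- cbind(df, covariates)
  cov_terms <- if (!is.null(covariates) && ncol(covariates))
    paste("+", paste(sprintf("`%s`", names(covariates)), collapse = " + "))
  else ""
  m1 <- stats::lm(stats::as.formula(paste(".decline ~ .group", cov_terms)),
                  data = df)
  m0 <- stats::lm(stats::as.formula(paste(".decline ~ 1", cov_terms)),
                  data = df)
  p_group <- stats::anova(m0, m1)[2, "Pr(>F)"]

  newdata <- lapply(df[-1], function(col) {
    if (is.numeric(col)) rep(mean(col), nlevels(group))
    else factor(rep(levels(as.factor(col))[1], nlevels(group)),
                levels = levels(as.factor(col)))
  })
  newdata <- as.data.frame(newdata)
  newdata$.group <- factor(levels(group), levels = levels(group))
  means <- stats::predict(m1, newdata = newdata)
  list(adjusted_means = stats::setNames(means, levels(group)),
       p_group = p_group)
}

#' Tertile labels for baseline-stratified analyses
#'
#' @param x numeric vector (e.g. a baseline hematologic parameter).
#' @return factor with levels `low`, `medium`, `high` cut at the
#'   interpolation tertiles.
#' @export
tertile_groups <- function(x) {
  sc <- quantile_score(x, 3L)
  factor(c("low", "medium", "high")[sc + 1L],
         levels = c("low", "medium", "high"))
}
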