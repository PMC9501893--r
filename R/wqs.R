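# Generalized weighted-quantile-sum (WQS) regression for the three-analyte
# mixture, written from first principles.
#
# The mixture components are quartile-scored (0..3); the WQS index is
# sum_i w_i * q_i with non-negative weights summing to one. Weights are
# estimated by bootstrap stability selection on a training split: in each
# bootstrap resample the Gaussian likelihood of
#   outcome ~ beta1 * index(w) + covariates
# is maximized over the simplex (softmax reparameterization, multi-start
# quasi-Newton; for fixed w the inner problem is ordinary least squares,
# so only the simplex coordinates are searched). Aggregated weights are
# then frozen and the index effect is estimated on the validation split.

softmax <- function(theta) {
  z <- exp(c(theta, 0) - max(c(theta, 0)))
  z / sum(z)
}

# residual sum of squares of outcome ~ index + covariates for fixed weights
wqs_rss <- function(w, Q, y, X) {
  idx <- as.numeric(Q %*% w)
  fit <- stats::lm.fit(cbind(X, idx), y)
  sum(fit$residuals^2)
}

#' Split workers into training and validation sets
#'
#' @param ids vector of worker ids.
#' @param train_frac fraction assigned to training (default 0.40).
#' @param seed integer seed.
#' @return list with `train` and `validation` id vectors: disjoint,
#'   exhaustive, sizes `floor(train_frac * n)` and the remainder.
#' @export
split_train_validation <- function(ids, train_frac = 0.40, seed = 1L) {
  if (train_frac <= 0 || train_frac >= 1) {
    stop_btx("train_frac must be in (0, 1)")
  }
  n <- length(ids)
  if (n < 10L) stop_btx("need at least 10 workers to split")
  set.seed(child_seed(seed, 11L))
  n_train <- floor(train_frac * n)
  train <- sort(sample(n, n_train))
  list(train = ids[train], validation = ids[-train])
}

#' Bootstrap estimation of WQS component weights
#'
#' For each of `B` bootstrap resamples of the training set, maximizes the
#' Gaussian likelihood of the outcome on the weighted quantile index plus
#' covariates over the weight simplex. Replicates whose optimizer fails
#' are dropped with a warning; more than 50% failures is an error.
#'
#' @param scores matrix or data frame of quantile scores (workers x
#'   components, values 0..q-1).
#' @param outcome numeric outcome (decline) vector.
#' @param covariates data frame of covariates or `NULL`.
#' @param B number of bootstrap resamples (default 100).
#' @param seed integer seed.
#' @param n_starts simplex multi-starts per resample.
#' @return list with `weights` (B x components matrix), `betas` (index
#'   coefficient per resample), `n_failed`.
#' @export
fit_bootstrap_weights <- function(scores, outcome, covariates = NULL,
                                  B = 100L, seed = 1L, n_starts = 5L) {
  if (B < 1L) stop_btx("B must be at least 1")
  Q <- as.matrix(scores)
  k <- ncol(Q)
  if (k < 2L) stop_btx("need at least two mixture components")
  n <- nrow(Q)
  X <- if (is.null(covariates) || !ncol(covariates)) {
    matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
  } else stats::model.matrix(~ ., data = covariates)

  set.seed(child_seed(seed, 12L))
  # deterministic simplex starts: centre + each vertex-leaning corner
  base_starts <- c(list(rep(0, k - 1L)),
                   lapply(seq_len(k), function(j) {
                     th <- rep(-2, k); th[j] <- 2; th[-k] - th[k]
                   }))

  W <- matrix(NA_real_, B, k, dimnames = list(NULL, colnames(Q)))
  betas <- rep(NA_real_, B)
  failed <- 0L
  for (bb in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    Qb <- Q[idx, , drop = FALSE]
    yb <- outcome[idx]
    Xb <- X[idx, , drop = FALSE]
    obj <- function(theta) wqs_rss(softmax(theta), Qb, yb, Xb)

    starts <- base_starts[seq_len(min(n_starts, length(base_starts)))]
    if (n_starts > length(base_starts)) {
      starts <- c(starts, lapply(seq_len(n_starts - length(base_starts)),
                                 function(i) stats::rnorm(k - 1L)))
    }
    best <- NULL
    for (s in starts) {
      res <- tryCatch(stats::optim(s, obj, method = "BFGS",
                                   control = list(maxit = 200)),
                      error = function(e) NULL)
      if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
    }
    if (is.null(best)) {
      failed <- failed + 1L
      next
    }
    w <- softmax(best$par)
    W[bb, ] <- w
    fitb <- stats::lm.fit(cbind(Xb, as.numeric(Qb %*% w)), yb)
    betas[bb] <- fitb$coefficients[ncol(Xb) + 1L]
  }
  if (failed > B / 2) stop_btx("more than half of bootstraps failed")
  if (failed > 0L) {
    warning(sprintf("%d of %d bootstraps failed and were dropped",
                    failed, B), call. = FALSE)
  }
  ok <- !is.na(betas)
  list(weights = W[ok, , drop = FALSE], betas = betas[ok], n_failed = failed)
}

#' Aggregate bootstrap weights
#'
#' Default: arithmetic mean over converged replicates. The `"signal"`
#' mode weights each replicate by the magnitude of its index t-statistic
#' proxy (|beta|), emphasizing resamples where the index carried signal.
#'
#' @param boot output of [fit_bootstrap_weights()].
#' @param method `"mean"` or `"signal"`.
#' @return weight vector on the simplex.
#' @export
aggregate_weights <- function(boot, method = c("mean", "signal")) {
  method <- match.arg(method)
  W <- boot$weights
  w <- if (method == "mean") colMeans(W) else {
    wt <- abs(boot$betas)
    if (sum(wt) == 0) colMeans(W) else colSums(W * wt) / sum(wt)
  }
  w / sum(w)
}

#' Finalize a WQS fit on the validation split
#'
#' Freezes the aggregated weights, computes the WQS index on validation
#' workers, and estimates the per-quartile index effect by covariate-
#' adjusted OLS.
#'
#' @param weights aggregated weight vector (see [aggregate_weights()]).
#' @param scores validation quantile-score matrix.
#' @param outcome validation outcome vector.
#' @param covariates validation covariates or `NULL`.
#' @return object of class `btx_wqs_fit`: `weights`, `beta`, `se`, `ci95`,
#'   `p_trend`, `n`.
#' @export
finalize_wqs <- function(weights, scores, outcome, covariates = NULL) {
  if (!nrow(as.matrix(scores))) stop_btx("empty validation set")
  if (abs(sum(weights) - 1) > 1e-9 || any(weights < 0)) {
    stop_btx("weights must be non-negative and sum to 1")
  }
  index <- as.numeric(as.matrix(scores) %*% weights)
  res <- adjusted_decline_model(outcome, index, covariates)
  structure(list(weights = weights, beta = res$beta, se = res$se,
                 ci95 = res$ci95, p_trend = res$p_trend,
                 n = length(outcome)),
            class = "btx_wqs_fit")
}

#' @export
print.btx_wqs_fit <- function(x, ...) {
  cat(sprintf("WQS index effect: beta = %.4g (95%% CI %.4g, %.4g), p = %.4g\n",
              x$beta, x$ci95[1], x$ci95[2], x$p_trend))
  cat("  weights:", paste(sprintf("%s = %.3f", names(x$weights), x$weights),
                          collapse = ", "), "\n")
  invisible(x)
}

#' End-to-end WQS regression for one outcome
#'
#' Convenience wrapper: 40/60 train/validation split, quartile scoring
#' with training-set cut-points, bootstrap weight estimation on the
#' training split, aggregation, and validation-split index regression.
#'
#' @param exposures data frame/matrix of raw exposure values (workers x
#'   components); quartile cut-points are computed on the training split.
#' @param outcome numeric outcome vector.
#' @param covariates data frame or `NULL`.
#' @param B bootstrap count.
#' @param train_frac training fraction.
#' @param seed integer seed (drives both split and bootstrap).
#' @param aggregation weight-aggregation method.
#' @return `btx_wqs_fit` with extra fields `boot` and `split`.
#' @export
wqs_regression <- function(exposures, outcome, covariates = NULL, B = 100L,
                           train_frac = 0.40, seed = 1L,
                           aggregation = "mean") {
  E <- as.matrix(exposures)
  n <- nrow(E)
  sp <- split_train_validation(seq_len(n), train_frac, seed)
  tr <- sp$train
  va <- sp$validation
  Qtr <- vapply(seq_len(ncol(E)), function(j)
    quantile_score(E[tr, j], 4L), integer(length(tr)))
  Qva <- vapply(seq_len(ncol(E)), function(j)
    quantile_score(E[va, j], 4L, ref = E[tr, j]), integer(length(va)))
  colnames(Qtr) <- colnames(Qva) <- colnames(E)
  cov_tr <- if (is.null(covariates)) NULL else covariates[tr, , drop = FALSE]
  cov_va <- if (is.null(covariates)) NULL else covariates[va, , drop = FALSE]
  boot <- fit_bootstrap_weights(Qtr, outcome[tr], cov_tr, B = B, seed = seed)
  w <- aggregate_weights(boot, aggregation)
  fit <- finalize_wqs(w, Qva, outcome[va], cov_va)
  fit$boot <- boot
  fit$split <- sp
  fit$seed <- seed
  fit$B <- B
  fit
}
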