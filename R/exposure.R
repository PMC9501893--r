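# Exposure metrics: from ambient 8h-TWA samples and work histories to
# per-worker cumulative exposure (CE), quantile scores and BMD dose groups.
#
# CE is defined as work years multiplied by the three-year mean 8h-TWA
# concentration in the worker's workplace, in units of mg/m3 x year.

#' Substitute below-LOD concentrations at LOD/2
#'
#' Ambient air samples whose concentration fell below the analytical limit
#' of detection (LOD) carry no usable raw value; the standard occupational
#' hygiene convention replaces them by half the LOD before averaging.
#'
#' @param samples data frame of ambient samples with columns `workplace_id`,
#'   `analyte`, `concentration` (mg/m3, 8h-TWA), `below_lod` (logical) and
#'   `lod` (mg/m3).
#' @return the same data frame with `concentration` set to `lod / 2` for
#'   every flagged sample; unflagged rows are returned unchanged.
#' @examples
#' s <- data.frame(workplace_id = 1, analyte = "benzene",
#'                 concentration = NA_real_, below_lod = TRUE, lod = 0.01)
#' substitute_lod(s)$concentration  # 0.005
#' @export
substitute_lod <- function(samples) {
  check_columns(samples, c("analyte", "concentration", "below_lod", "lod"),
                "ambient sample table")
  flagged <- which(samples$below_lod)
  bad <- flagged[!is.finite(samples$lod[flagged]) | samples$lod[flagged] <= 0]
  if (length(bad)) {
    stop_btx("below-LOD sample(s) without a positive LOD at row(s): %s",
             paste(utils::head(bad, 10L), collapse = ", "))
  }
  samples$concentration[flagged] <- samples$lod[flagged] / 2
  samples
}

#' Mean workplace 8h-TWA concentration per analyte
#'
#' Arithmetic mean of the (post-substitution) 8h-TWA concentrations over
#' all monitoring periods, per (workplace, analyte) pair.
#'
#' @param samples ambient sample table; below-LOD rows must already carry
#'   their LOD/2 substitute (see [substitute_lod()]).
#' @return data frame with columns `workplace_id`, `analyte`, `mean_twa`.
#' @export
workplace_mean_twa <- function(samples) {
  check_columns(samples, c("workplace_id", "analyte", "concentration"),
                "ambient sample table")
  if (any(!is.finite(samples$concentration))) {
    stop_btx("non-finite concentrations present; run substitute_lod() first")
  }
  agg <- stats::aggregate(
    concentration ~ workplace_id + analyte, data = samples, FUN = mean)
  names(agg)[names(agg) == "concentration"] <- "mean_twa"
  agg[order(agg$workplace_id, agg$analyte), , drop = FALSE]
}

#' Cumulative exposure from work years and mean 8h-TWA
#'
#' @param work_years years of employment in the monitored workplace;
#'   eligibility requires at least one year.
#' @param mean_twa mean 8h-TWA concentration, mg/m3.
#' @return cumulative exposure in mg/m3 x year (elementwise product).
#' @examples
#' compute_ce(10, 0.05)  # 0.5
#' @export
compute_ce <- function(work_years, mean_twa) {
  if (any(work_years < 1)) {
    stop_btx("work_years below the one-year eligibility minimum")
  }
  if (any(mean_twa < 0)) stop_btx("mean_twa must be non-negative")
  work_years * mean_twa
}

#' Score values into empirical quantile groups
#'
#' Cut-points are linear-interpolation empirical quantiles of `values`
#' (or of `ref`, e.g. a training split). A value exactly equal to a
#' cut-point falls in the lower group, so tied values always share a score.
#'
#' @param values numeric vector to score.
#' @param q number of groups (4 gives quartile scores 0..3).
#' @param ref optional reference vector from which cut-points are computed;
#'   defaults to `values`.
#' @return integer scores in `0..q-1`.
#' @export
quantile_score <- function(values, q = 4L, ref = values) {
  if (q < 2L) stop_btx("q must be at least 2")
  if (length(ref) < q) stop_btx("need at least q values to form q groups")
  if (diff(range(ref)) == 0) {
    stop_btx("quantile scores undefined for a constant vector")
  }
  cuts <- interp_quantile(ref, probs = seq_len(q - 1L) / q)
  vapply(values, function(v) sum(v > cuts), integer(1L))
}

#' Partition workers into dose groups for benchmark-dose analysis
#'
#' Workers are sorted by cumulative exposure and split into `n_groups`
#' contiguous CE intervals of near-equal size; ties never straddle a
#' boundary (tied CE values stay together in the lower group). Each group's
#' dose is the median CE of its members. When equal-frequency sizes fall
#' outside `[min_n, max_n]` the split is still returned, with a warning —
#' the size window is a design guideline, not a hard constraint.
#'
#' @param ce numeric vector of cumulative exposures (mg/m3 x year).
#' @param cases logical/0-1 vector of case status, same length as `ce`.
#' @param n_groups number of dose groups (7 or 8 in typical use).
#' @param min_n,max_n intended per-group size window.
#' @return data frame of class `btx_dose_groups` with columns `group`,
#'   `ce_low`, `ce_high`, `dose` (group median CE), `n`, `cases`. Intervals
#'   are half-open `[low, high)` except the last, which is closed.
#' @export
assign_dose_groups <- function(ce, cases, n_groups = 8L,
                               min_n = 70L, max_n = 200L) {
  if (n_groups < 2L) stop_btx("n_groups must be at least 2")
  n <- length(ce)
  if (length(cases) != n) stop_btx("ce and cases lengths differ")
  if (n < n_groups) stop_btx("fewer workers than dose groups")
  cases <- as.integer(cases)

  base <- n / n_groups
  if (base < min_n || base > max_n) {
    warning(sprintf(
      "equal-frequency group size %.1f outside [%d, %d]; using equal-frequency split",
      base, min_n, max_n), call. = FALSE)
  }

  ord <- order(ce)
  sorted <- ce[ord]
  # target boundaries at cumulative counts i*n/n_groups, shifted so tied CE
  # values never straddle a boundary (ties go to the lower group)
  bounds <- round(seq_len(n_groups - 1L) * base)
  for (i in seq_along(bounds)) {
    b <- bounds[i]
    while (b < n && sorted[b] == sorted[b + 1L]) b <- b + 1L
    bounds[i] <- b
  }
  bounds <- unique(bounds[bounds < n])
  starts <- c(1L, bounds + 1L)
  ends <- c(bounds, n)
  if (length(starts) < n_groups) {
    warning("ties forced fewer groups than requested", call. = FALSE)
  }

  grp <- lapply(seq_along(starts), function(i) {
    idx <- ord[starts[i]:ends[i]]
    data.frame(
      group = i,
      ce_low = sorted[starts[i]],
      ce_high = if (i < length(starts)) sorted[ends[i] + 1L] else sorted[n],
      dose = stats::median(ce[idx]),
      n = length(idx),
      cases = sum(cases[idx])
    )
  })
  out <- do.call(rbind, grp)
  stopifnot(sum(out$n) == n, sum(out$cases) == sum(cases),
            !is.unsorted(out$dose, strictly = FALSE))
  class(out) <- c("btx_dose_groups", "data.frame")
  out
}

#' Build per-worker exposure profiles
#'
#' Joins worker work histories to workplace mean 8h-TWA concentrations and
#' computes, per analyte, cumulative exposure (CE), its natural logarithm,
#' and quartile scores.
#'
#' @param workers data frame with `worker_id`, `workplace_id`, `work_years`.
#' @param mean_twa output of [workplace_mean_twa()].
#' @return data frame with one row per worker: `worker_id` plus, for each
#'   analyte `a`, `ce_a`, `ln_ce_a` and `q_a` (quartile score 0..3).
#' @export
exposure_profiles <- function(workers, mean_twa) {
  check_columns(workers, c("worker_id", "workplace_id", "work_years"),
                "worker table")
  out <- data.frame(worker_id = workers$worker_id)
  for (a in BTX_ANALYTES) {
    twa <- mean_twa[mean_twa$analyte == a, ]
    m <- twa$mean_twa[match(workers$workplace_id, twa$workplace_id)]
    if (any(is.na(m))) {
      stop_btx("no %s monitoring data for workplace(s): %s", a,
               paste(unique(workers$workplace_id[is.na(m)]), collapse = ", "))
    }
    ce <- compute_ce(workers$work_years, m)
    if (any(ce <= 0)) {
      stop_btx("zero CE encountered for %s; eligibility requires TWA >= LOD/2 > 0", a)
    }
    out[[paste0("ce_", a)]] <- ce
    out[[paste0("ln_ce_", a)]] <- log(ce)
    out[[paste0("q_", a)]] <- quantile_score(ce, 4L)
  }
  out
}
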