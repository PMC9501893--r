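# Hematology endpoints: four-year decline vectors and the two-criteria
# hematological-damage classifier.
#
# Nine parameters are tracked: WBC, neutrophil, monocyte and lymphocyte
# counts (10^9/L), RBC counts (10^12/L), hemoglobin (g/L), hematocrit (%),
# platelet counts (10^9/L) and mean platelet volume (MPV, fL).

#' Default lower reference limits for hematologic parameters
#'
#' Sex-specific lower limits of the adult normal range, derived from the
#' Chinese reference intervals for blood cell analysis (WS/T 405-2012).
#' MPV is deliberately absent: it has no national reference interval and is
#' excluded from the below-limit damage criterion. The table is plain
#' configuration — replace it with locally applicable limits where needed.
#'
#' @return data frame with columns `parameter`, `sex` (`"male"`, `"female"`
#'   or `"any"`) and `lower`.
#' @export
default_reference_limits <- function() {
  data.frame(
    parameter = c("wbc", "neutrophils", "monocytes", "lymphocytes",
                  "rbc", "rbc", "hemoglobin", "hemoglobin",
                  "hematocrit", "hematocrit", "platelets"),
    sex = c("any", "any", "any", "any",
            "male", "female", "male", "female",
            "male", "female", "any"),
    lower = c(3.5, 1.8, 0.1, 1.1,
              4.3, 3.8, 130, 115,
              40, 35, 125),
    stringsAsFactors = FALSE
  )
}

#' Four-year decline in hematologic parameters
#'
#' Decline is baseline minus follow-up, elementwise per parameter, so a
#' positive decline means the parameter decreased over follow-up.
#'
#' @param baseline,follow_up data frames with `worker_id` and the nine
#'   parameter columns (see `HEME_PARAMS`), aligned by `worker_id`.
#' @return data frame with `worker_id` and one decline column per parameter.
#' @export
compute_decline <- function(baseline, follow_up) {
  check_columns(baseline, c("worker_id", HEME_PARAMS), "baseline hemogram")
  check_columns(follow_up, c("worker_id", HEME_PARAMS), "follow-up hemogram")
  idx <- match(baseline$worker_id, follow_up$worker_id)
  if (any(is.na(idx))) stop_btx("follow-up hemogram missing for some workers")
  out <- data.frame(worker_id = baseline$worker_id)
  for (p in HEME_PARAMS) {
    b <- baseline[[p]]
    f <- follow_up[[p]][idx]
    if (any(is.na(b)) || any(is.na(f))) {
      stop_btx("missing values in parameter '%s'", p)
    }
    out[[p]] <- b - f
  }
  out
}

#' Sex-specific 95th-percentile decline thresholds
#'
#' For each sex stratum and parameter, the 95th percentile of the observed
#' declines (linear-interpolation empirical quantile). A worker whose
#' decline exceeds this threshold shows an abnormally large drop relative
#' to same-sex peers.
#'
#' @param decline output of [compute_decline()].
#' @param sex character vector (`"male"`/`"female"`), one per worker.
#' @param percentile percentile defining "abnormally high decline".
#' @param min_per_sex smallest sex stratum for which the empirical
#'   percentile is considered estimable.
#' @return data frame with columns `sex`, `parameter`, `threshold`.
#' @export
decline_thresholds <- function(decline, sex, percentile = 95,
                               min_per_sex = 20L) {
  stopifnot(length(sex) == nrow(decline))
  tab <- table(sex)
  if (any(tab < min_per_sex)) {
    stop_btx("sex stratum below %d workers: %s", min_per_sex,
             paste(names(tab)[tab < min_per_sex], collapse = ", "))
  }
  out <- expand.grid(sex = names(tab), parameter = HEME_PARAMS,
                     stringsAsFactors = FALSE)
  out$threshold <- mapply(function(s, p) {
    interp_quantile(decline[[p]][sex == s], percentile / 100)
  }, out$sex, out$parameter)
  rownames(out) <- NULL
  out
}

#' Classify workers as hematological-damage cases
#'
#' A worker is a case when either criterion holds: (1) at least two
#' parameters (MPV excluded — no reference interval exists for it) are
#' below the lower limit of the normal range at follow-up; or (2) at least
#' two parameters (MPV included) declined by strictly more than the
#' sex-specific 95th-percentile threshold.
#'
#' @param follow_up follow-up hemogram table (`worker_id` + parameters).
#' @param decline output of [compute_decline()], aligned with `follow_up`.
#' @param sex character vector, one per worker in `follow_up` order.
#' @param limits reference-limit table as in [default_reference_limits()].
#' @param thresholds output of [decline_thresholds()].
#' @return data frame of class `btx_damage` with `worker_id`,
#'   `criterion1_count`, `criterion2_count`, `is_case`.
#' @export
classify_damage <- function(follow_up, decline, sex,
                            limits = default_reference_limits(),
                            thresholds) {
  check_columns(limits, c("parameter", "sex", "lower"), "reference limits")
  if ("mpv" %in% limits$parameter) {
    stop_btx("MPV must not appear in the reference-limit table")
  }
  crit1_params <- setdiff(HEME_PARAMS, "mpv")
  missing_lim <- setdiff(crit1_params, limits$parameter)
  if (length(missing_lim)) {
    stop_btx("reference limits missing for: %s",
             paste(missing_lim, collapse = ", "))
  }
  idx <- match(decline$worker_id, follow_up$worker_id)
  stopifnot(!any(is.na(idx)))

  n <- nrow(follow_up)
  c1 <- integer(n)
  for (p in crit1_params) {
    lim <- limits[limits$parameter == p, ]
    low <- if (nrow(lim) == 1L && lim$sex == "any") {
      rep(lim$lower, n)
    } else {
      lim$lower[match(sex, lim$sex)]
    }
    if (any(is.na(low))) stop_btx("no limit for parameter '%s' and some sex", p)
    c1 <- c1 + as.integer(follow_up[[p]] < low)
  }

  c2 <- integer(n)
  for (p in HEME_PARAMS) {
    th <- thresholds$threshold[match(paste(sex, p),
                                     paste(thresholds$sex, thresholds$parameter))]
    if (any(is.na(th))) stop_btx("decline threshold missing for '%s'", p)
    dec <- decline[[p]][match(follow_up$worker_id, decline$worker_id)]
    c2 <- c2 + as.integer(dec > th)
  }

  out <- data.frame(
    worker_id = follow_up$worker_id,
    criterion1_count = c1,
    criterion2_count = c2,
    is_case = c1 >= 2L | c2 >= 2L
  )
  class(out) <- c("btx_damage", "data.frame")
  out
}
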