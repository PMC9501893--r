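# Internal helpers shared across modules.

BTX_ANALYTES <- c("benzene", "toluene", "xylene")

HEME_PARAMS <- c("wbc", "neutrophils", "monocytes", "lymphocytes",
                 "rbc", "hemoglobin", "hematocrit", "platelets", "mpv")

#' Derive a reproducible child seed from a master seed
#'
#' Each simulated table draws from its own RNG stream so that regenerating
#' one table never perturbs another. Streams are derived from the master
#' seed by fixed integer offsets, kept within 32-bit range.
#'
#' @param seed master integer seed.
#' @param offset non-negative integer stream offset.
#' @return an integer seed.
#' @keywords internal
child_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(as.numeric(seed)) + offset * 7919) %% 2147483587L)
}

# Quantile convention used everywhere in the package: linear interpolation
# between order statistics (stats::quantile type 7).
interp_quantile <- function(x, probs) {
  stats::quantile(x, probs = probs, type = 7, names = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_btx <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop_btx("%s is missing required column(s): %s", what,
             paste(missing, collapse = ", "))
  }
  invisible(df)
}
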