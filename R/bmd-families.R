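# Dichotomous dose-response families.
#
# The suite covers the eight standard dichotomous models: Multistage
# (degrees 1 and 2), Gamma, Log-Logistic, Weibull, Logistic, Log-Probit,
# Probit and Dichotomous Hill. Each family is described by a parameter
# vector with named components, box bounds, a response probability
# P(dose), and where available a closed-form benchmark dose for a given
# extra-risk BMR. Conventions:
#   g  — background response probability, in [0, 1]
#   v  — Dichotomous Hill plateau (maximum response fraction), in (0, 1]
#   a  — intercept; b / b1, b2 — slope / stage coefficients
# Log-dose families take natural log of dose and return the background at
# dose 0 by continuity. Slopes of log-dose families and multistage stage
# coefficients are constrained non-negative (monotone response); Logistic
# and Probit slopes are unconstrained.

BMD_FAMILIES <- c("multistage1", "multistage2", "gamma", "log_logistic",
                  "weibull", "logistic", "log_probit", "probit",
                  "dichotomous_hill")

family_par_names <- function(family) {
  switch(family,
    multistage1 = c("g", "b1"),
    multistage2 = c("g", "b1", "b2"),
    gamma = c("g", "shape", "rate"),
    log_logistic = c("g", "a", "b"),
    weibull = c("g", "shape", "rate"),
    logistic = c("a", "b"),
    log_probit = c("g", "a", "b"),
    probit = c("a", "b"),
    dichotomous_hill = c("g", "v", "a", "b"),
    stop_btx("unknown dose-response family '%s'", family)
  )
}

# box bounds on the optimizer scale; shape bounds follow the usual
# dichotomous-suite conventions (shape in [0.2, 18] guards against
# supra-threshold spikes at dose 0)
family_bounds <- function(family) {
  eps <- 1e-8
  switch(family,
    multistage1 = list(lower = c(g = eps, b1 = 0),
                       upper = c(g = 1 - eps, b1 = Inf)),
    multistage2 = list(lower = c(g = eps, b1 = 0, b2 = 0),
                       upper = c(g = 1 - eps, b1 = Inf, b2 = Inf)),
    gamma = list(lower = c(g = eps, shape = 0.2, rate = eps),
                 upper = c(g = 1 - eps, shape = 18, rate = Inf)),
    log_logistic = list(lower = c(g = eps, a = -18, b = eps),
                        upper = c(g = 1 - eps, a = 18, b = 18)),
    weibull = list(lower = c(g = eps, shape = 0.2, rate = eps),
                   upper = c(g = 1 - eps, shape = 18, rate = Inf)),
    logistic = list(lower = c(a = -18, b = -18),
                    upper = c(a = 18, b = 18)),
    log_probit = list(lower = c(g = eps, a = -18, b = eps),
                      upper = c(g = 1 - eps, a = 18, b = 18)),
    probit = list(lower = c(a = -18, b = -18),
                  upper = c(a = 18, b = 18)),
    dichotomous_hill = list(lower = c(g = eps, v = eps, a = -18, b = eps),
                            upper = c(g = 1 - eps, v = 1, a = 18, b = 18))
  )
}

# admissible parameter ranges (wider than the optimizer box): backgrounds
# in [0,1], plateau in (0,1], constrained slopes/shapes non-negative,
# intercepts and Logistic/Probit slopes unbounded
family_admissible_bounds <- function(family) {
  b <- family_bounds(family)
  lo <- b$lower
  hi <- b$upper
  lo[names(lo) %in% c("g", "b", "b1", "b2", "rate")] <- 0
  lo[names(lo) == "shape"] <- 1e-12
  lo[names(lo) == "a"] <- -Inf
  hi[names(hi) %in% c("a", "b", "shape")] <- Inf
  if (family %in% c("logistic", "probit")) lo["b"] <- -Inf
  list(lower = lo, upper = hi)
}

check_family_params <- function(family, params) {
  nm <- family_par_names(family)
  if (!all(nm %in% names(params))) {
    stop_btx("family '%s' needs parameters: %s", family,
             paste(nm, collapse = ", "))
  }
  b <- family_admissible_bounds(family)
  for (p in nm) {
    if (params[[p]] < b$lower[[p]] - 1e-12 || params[[p]] > b$upper[[p]] + 1e-12) {
      stop_btx("parameter '%s' = %g outside bound [%g, %g] for family '%s'",
               p, params[[p]], b$lower[[p]], b$upper[[p]], family)
    }
  }
  invisible(params)
}

#' Response probability of a dichotomous dose-response family
#'
#' Evaluates P(dose) for one of the eight families. Multistage:
#' `g + (1 - g) * (1 - exp(-b1*d - b2*d^2))`. Gamma / Weibull:
#' `g + (1 - g) * F(rate * d)` with the gamma / Weibull CDF in `shape`.
#' Log-Logistic and Log-Probit apply the logistic / normal CDF to
#' `a + b * log(d)`; Logistic and Probit apply it to `a + b * d`.
#' Dichotomous Hill: `g + (v - v * g) / (1 + exp(-a - b * log(d)))` with
#' plateau `v`. Log-dose families return `g` at dose 0 by continuity.
#'
#' @param family one of `BMD_FAMILIES`.
#' @param params named numeric parameter vector (see family conventions).
#' @param dose numeric vector of non-negative doses.
#' @return vector of probabilities in [0, 1].
#' @examples
#' response_probability("probit", c(a = 0, b = 1), 0)  # 0.5
#' @export
response_probability <- function(family, params, dose) {
  check_family_params(family, params)
  if (any(dose < 0)) stop_btx("dose must be non-negative")
  .resp_prob(family, as.list(params), dose)
}

# unchecked evaluator used by the fitting and profiling internals, where
# assembled parameters may legitimately sit outside the optimizer box
.resp_prob <- function(family, p, dose) {
  pr <- switch(family,
    multistage1 = p$g + (1 - p$g) * (1 - exp(-p$b1 * dose)),
    multistage2 = p$g + (1 - p$g) * (1 - exp(-p$b1 * dose - p$b2 * dose^2)),
    gamma = p$g + (1 - p$g) * stats::pgamma(p$rate * dose, shape = p$shape),
    weibull = p$g + (1 - p$g) * (1 - exp(-p$rate * dose^p$shape)),
    logistic = stats::plogis(p$a + p$b * dose),
    probit = stats::pnorm(p$a + p$b * dose),
    log_logistic = {
      out <- rep(p$g, length(dose))
      pos <- dose > 0
      out[pos] <- p$g + (1 - p$g) * stats::plogis(p$a + p$b * log(dose[pos]))
      out
    },
    log_probit = {
      out <- rep(p$g, length(dose))
      pos <- dose > 0
      out[pos] <- p$g + (1 - p$g) * stats::pnorm(p$a + p$b * log(dose[pos]))
      out
    },
    dichotomous_hill = {
      out <- rep(p$g, length(dose))
      pos <- dose > 0
      out[pos] <- p$g + (p$v - p$v * p$g) /
        (1 + exp(-p$a - p$b * log(dose[pos])))
      out
    }
  )
  pmin(pmax(pr, 0), 1)
}

#' Extra risk relative to background
#'
#' Extra risk at dose d is `(P(d) - P(0)) / (1 - P(0))`: the additional
#' response probability expressed as a fraction of the population not
#' already responding at background.
#'
#' @param fit a `btx_drfit` or a list with `family` and `params`.
#' @param dose numeric vector of doses.
#' @return extra-risk fractions.
#' @export
extra_risk <- function(fit, dose) {
  p0 <- response_probability(fit$family, fit$params, 0)
  if (p0 >= 1) stop_btx("background response is 1; extra risk undefined")
  (response_probability(fit$family, fit$params, dose) - p0) / (1 - p0)
}

#' Benchmark dose for a given extra-risk BMR
#'
#' Solves `extra_risk(dose) = bmr` for the fitted family: in closed form
#' for Multistage, Gamma, Weibull, Log-Logistic, Log-Probit and
#' Dichotomous Hill, and by bracketed root-finding for Logistic and Probit
#' (relative tolerance 1e-8). For Dichotomous Hill the plateau `v` caps
#' attainable extra risk; a BMR at or above the cap is an error.
#'
#' @param fit a `btx_drfit` or list with `family` and `params`.
#' @param bmr benchmark response as extra risk, in (0, 1).
#' @return the benchmark dose (same units as the model's dose).
#' @examples
#' solve_bmd(list(family = "multistage1", params = c(g = 0, b1 = 1)), 0.10)
#' @export
solve_bmd <- function(fit, bmr = 0.10) {
  if (bmr <= 0 || bmr >= 1) stop_btx("bmr must be in (0, 1)")
  family <- fit$family
  p <- as.list(fit$params)
  check_family_params(family, fit$params)
  A <- -log(1 - bmr)
  bmd <- switch(family,
    multistage1 = {
      if (p$b1 <= 0) stop_btx("BMR unreachable: zero multistage slope")
      A / p$b1
    },
    multistage2 = {
      if (p$b1 <= 0 && p$b2 <= 0) stop_btx("BMR unreachable: zero multistage slopes")
      if (p$b2 == 0) A / p$b1
      else (-p$b1 + sqrt(p$b1^2 + 4 * p$b2 * A)) / (2 * p$b2)
    },
    gamma = {
      if (p$rate <= 0) stop_btx("BMR unreachable: zero rate")
      stats::qgamma(bmr, shape = p$shape) / p$rate
    },
    weibull = {
      if (p$rate <= 0) stop_btx("BMR unreachable: zero rate")
      (A / p$rate)^(1 / p$shape)
    },
    log_logistic = {
      if (p$b <= 0) stop_btx("BMR unreachable: zero slope")
      exp((stats::qlogis(bmr) - p$a) / p$b)
    },
    log_probit = {
      if (p$b <= 0) stop_btx("BMR unreachable: zero slope")
      exp((stats::qnorm(bmr) - p$a) / p$b)
    },
    dichotomous_hill = {
      if (p$b <= 0) stop_btx("BMR unreachable: zero slope")
      if (p$v <= bmr) stop_btx("BMR unreachable: plateau v = %g <= bmr", p$v)
      exp((-p$a - log(p$v / bmr - 1)) / p$b)
    },
    logistic = ,
    probit = {
      f <- function(d) extra_risk(fit, d) - bmr
      if (f(0) >= 0) stop_btx("BMR already exceeded at dose 0")
      hi <- 1
      while (f(hi) < 0 && hi < 1e12) hi <- hi * 4
      if (f(hi) < 0) stop_btx("BMR unreachable within dose range")
      stats::uniroot(f, c(0, hi), tol = 1e-12)$root
    }
  )
  bmd
}
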