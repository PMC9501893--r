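test_that("response probabilities honor closed-form anchor points", {
  expect_equal(response_probability("multistage1", c(g = 0.07, b1 = 0), 5),
               0.07)
  expect_equal(response_probability("multistage2",
                                    c(g = 0.3, b1 = 0, b2 = 0), 2), 0.3)
  expect_equal(response_probability("probit", c(a = 0, b = 1), 0), 0.5)
  expect_equal(response_probability("dichotomous_hill",
                                    c(g = 0, v = 1, a = 0, b = 1), 1), 0.5)
  # log-dose families return the background at dose zero by continuity
  expect_equal(response_probability("log_logistic",
                                    c(g = 0.1, a = 0, b = 1), 0), 0.1)
  expect_error(response_probability("multistage1", c(g = 1.5, b1 = 1), 1),
               "bound")
  expect_error(response_probability("multistage1", c(g = 0.1, b1 = 1), -1),
               "non-negative")
})

test_that("probabilities stay in [0,1] and monotone families increase", {
  set.seed(11)
  doses <- seq(0, 50, length.out = 200)
  mono <- c("multistage1", "multistage2", "gamma", "weibull",
            "log_logistic", "log_probit")
  for (fam in btxbmd:::BMD_FAMILIES) {
    for (i in 1:10) {
      p <- random_family_params(fam)
      pr <- response_probability(fam, p, doses)
      expect_true(all(pr >= 0 & pr <= 1))
      if (fam %in% mono) expect_true(all(diff(pr) >= -1e-12))
    }
  }
})

test_that("extra risk is background-corrected and zero at dose zero", {
  fit <- list(family = "multistage1", params = c(g = 0.25, b1 = 0.5))
  expect_equal(extra_risk(fit, 0), 0)
  # one-stage extra risk is independent of background
  for (g in c(0, 0.1, 0.4)) {
    f <- list(family = "multistage1", params = c(g = g, b1 = 0.5))
    expect_equal(extra_risk(f, 2), 1 - exp(-1), tolerance = 1e-12)
  }
  f0 <- list(family = "multistage1", params = c(g = 1e-8, b1 = 0.1))
  d <- solve_bmd(f0, 0.1)
  expect_equal(extra_risk(f0, d), 0.1, tolerance = 1e-9)
})

test_that("solve_bmd matches closed forms and scales as expected", {
  f1 <- list(family = "multistage1", params = c(g = 0.05, b1 = 1))
  expect_equal(solve_bmd(f1, 0.10), -log(0.9), tolerance = 1e-12)
  f2 <- list(family = "multistage1", params = c(g = 0.05, b1 = 2))
  expect_equal(solve_bmd(f2, 0.10), solve_bmd(f1, 0.10) / 2,
               tolerance = 1e-12)
  # plateau below the BMR is unreachable
  fh <- list(family = "dichotomous_hill",
             params = c(g = 0.05, v = 0.08, a = 0, b = 1))
  expect_error(solve_bmd(fh, 0.10), "unreachable")
})

test_that("BMD round-trips through extra_risk for every family", {
  set.seed(12)
  for (fam in btxbmd:::BMD_FAMILIES) {
    for (i in 1:10) {
      fit <- list(family = fam, params = random_family_params(fam))
      bmd <- solve_bmd(fit, 0.10)
      expect_gt(bmd, 0)
      expect_equal(extra_risk(fit, bmd), 0.10, tolerance = 1e-6)
    }
  }
})

test_that("maximum-likelihood fits track group incidences at large n", {
  set.seed(13)
  groups <- multistage_groups(g = 0.05, b1 = 0.3, n = 20000)
  fit <- fit_dichotomous(groups, "multistage1", compute_bmdl = FALSE)
  p_hat <- response_probability(fit$family, fit$params, groups$dose)
  expect_true(all(abs(p_hat - groups$cases / groups$n) < 0.01))
  expect_true(fit$converged)
  expect_equal(fit$aic, 2 * fit$k - 2 * fit$loglik)
  expect_equal(fit$gof_df, nrow(groups) - fit$k)
})

test_that("one-stage slope is recovered across simulation replicates", {
  set.seed(14)
  b1_hat <- replicate(20, {
    g <- multistage_groups(g = 0.05, b1 = 0.1, n = 200,
                           seed = sample.int(1e6, 1))
    fit_dichotomous(g, "multistage1", compute_bmdl = FALSE)$params["b1"]
  })
  expect_lt(abs(mean(b1_hat) - 0.1), 3 * sd(b1_hat) / sqrt(20))
})

test_that("all-zero case tables drive the background to its boundary", {
  groups <- data.frame(dose = c(0.5, 1, 2, 4), n = 50, cases = 0L)
  fit <- fit_dichotomous(groups, "multistage1", compute_bmdl = FALSE)
  expect_lt(fit$params["g"], 1e-4)
  expect_true(fit$boundary)
})

test_that("goodness of fit is exact for a perfect fit and df is enforced", {
  params <- c(g = 0.1, b1 = 0.4)
  dose <- c(0.5, 1, 2, 3, 4, 5, 6, 8)
  p <- response_probability("multistage1", params, dose)
  groups <- data.frame(dose = dose, n = 1000, cases = 1000 * p)
  fit <- list(family = "multistage1", params = params, k = 2L)
  gof <- goodness_of_fit(fit, groups)
  expect_equal(gof$chi2, 0, tolerance = 1e-18)
  expect_equal(gof$p, 1)
  expect_equal(gof$df, 6L)
})

test_that("goodness-of-fit p-values are near-uniform under the null", {
  set.seed(15)
  pvals <- replicate(200, {
    g <- multistage_groups(g = 0.1, b1 = 0.3, n = 150,
                           seed = sample.int(1e6, 1))
    fit_dichotomous(g, "multistage1", compute_bmdl = FALSE)$gof_p
  })
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("model selection applies the adequacy filters then lowest AIC", {
  mk_fit <- function(family, aic, gof_p, bmd, bmdl) {
    structure(list(family = family, aic = aic, gof_p = gof_p, bmd = bmd,
                   bmdl = bmdl, groups = data.frame(dose = c(1, 2, 3))),
              class = "btx_drfit")
  }
  a <- mk_fit("multistage1", 700, 0.4, 1.5, 1.0)
  b <- mk_fit("probit", 705, 0.5, 1.4, 1.1)
  sel <- select_best(list(a = a, b = b), max_dose = 3)
  expect_equal(sel$chosen$family, "multistage1")
  # adequacy filters: poor GOF, BMD above max dose, wide BMD/BMDL
  bad_gof <- mk_fit("gamma", 600, 0.05, 1.5, 1.0)
  bad_bmd <- mk_fit("weibull", 600, 0.5, 9, 8)
  bad_ratio <- mk_fit("logistic", 600, 0.5, 1.5, 0.2)
  sel2 <- select_best(list(bad_gof, bad_bmd, bad_ratio, b), max_dose = 3)
  expect_equal(sel2$chosen$family, "probit")
  sel3 <- select_best(list(bad_gof), max_dose = 3)
  expect_null(sel3$chosen)
  expect_equal(sel3$reason, "no adequate model")
})

test_that("profile BMDL sits below the BMD and tightens with information", {
  groups <- multistage_groups(g = 0.05, b1 = 0.3, n = 100, seed = 31)
  fit <- fit_dichotomous(groups, "multistage1")
  expect_lte(fit$bmdl, fit$bmd)
  big <- groups
  big$n <- big$n * 10
  big$cases <- big$cases * 10
  fit_big <- fit_dichotomous(big, "multistage1")
  expect_lt(fit_big$bmd - fit_big$bmdl, fit$bmd - fit$bmdl)
})

test_that("profile BMDL works across model families on a common table", {
  set.seed(16)
  groups <- multistage_groups(g = 0.08, b1 = 0.25, n = 300, seed = 77)
  for (fam in c("multistage1", "weibull", "log_logistic", "logistic",
                "probit")) {
    fit <- fit_dichotomous(groups, fam)
    expect_true(is.finite(fit$bmd), info = fam)
    expect_true(is.finite(fit$bmdl), info = fam)
    expect_lte(fit$bmdl, fit$bmd)
    expect_gt(fit$bmdl, 0)
  }
})

test_that("REL derivation divides the POD by the working duration", {
  mw <- btx_molecular_weights()
  rel <- derive_rel(1.559, 40, mw["benzene"])
  expect_equal(rel$rel_mgm3, 1.559 / 40)
  expect_equal(rel$rel_ppm, 1.559 / 40 * 24.45 / 78.11)
  expect_error(derive_rel(-1, 40), "positive")
  expect_error(derive_rel(1, 0), "positive")
})
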