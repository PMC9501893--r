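test_that("decline is baseline minus follow-up, elementwise", {
  b <- hemogram_row(1, hemoglobin = 152.10, monocytes = 0.47)
  f <- hemogram_row(1, hemoglobin = 143.76, monocytes = 0.32)
  d <- compute_decline(b, f)
  expect_equal(d$hemoglobin, 8.34)
  expect_equal(d$monocytes, 0.15)
  # identical hemograms give all-zero decline
  d0 <- compute_decline(b, b)
  expect_true(all(as.matrix(d0[-1]) == 0))
  # missing parameter is named in the error
  f$wbc <- NULL
  expect_error(compute_decline(b, f), "wbc")
})

test_that("decline thresholds use the interpolation percentile per sex", {
  dec <- data.frame(worker_id = 1:40)
  for (p in btxbmd:::HEME_PARAMS) dec[[p]] <- c(1:20, 1:20)
  sex <- rep(c("male", "female"), each = 20)
  th <- decline_thresholds(dec, sex)
  expect_equal(unique(th$threshold), 19.05)
  # all-equal declines give that constant as threshold
  dec2 <- dec
  dec2$wbc <- rep(2, 40)
  th2 <- decline_thresholds(dec2, sex)
  expect_equal(th2$threshold[th2$parameter == "wbc"], c(2, 2))
  # an added large outlier can only raise the threshold
  dec3 <- dec
  dec3$wbc[20] <- 1000
  th3 <- decline_thresholds(dec3, sex)
  expect_true(all(th3$threshold[th3$parameter == "wbc"] >=
                    th$threshold[th$parameter == "wbc"]))
  expect_error(decline_thresholds(dec[1:25, ], sex[1:25]), "stratum")
})

test_that("damage classification implements the two-criteria disjunction", {
  limits <- default_reference_limits()
  params <- btxbmd:::HEME_PARAMS
  # thresholds far above any decline below; then selectively lowered
  mk_thresholds <- function(value = 1e6) {
    expand.grid(sex = c("male", "female"), parameter = params,
                stringsAsFactors = FALSE) |>
      transform(threshold = value)
  }

  # case via criterion 1: three follow-up parameters below limits
  f1 <- hemogram_row(1, wbc = 3.0, rbc = 4.0, platelets = 100)
  d1 <- compute_decline(hemogram_row(1), f1)
  call1 <- classify_damage(f1, d1, "male", limits, mk_thresholds())
  expect_equal(call1$criterion1_count, 3L)
  expect_true(call1$is_case)

  # one low parameter plus one extreme decline: neither criterion reaches 2
  f2 <- hemogram_row(2, wbc = 3.0)
  d2 <- compute_decline(hemogram_row(2, monocytes = 0.9), f2)
  th2 <- mk_thresholds()
  th2$threshold[th2$parameter == "monocytes"] <- 0.1
  call2 <- classify_damage(f2, d2, "male", limits, th2)
  expect_equal(call2$criterion1_count, 1L)
  expect_equal(call2$criterion2_count, 1L)
  expect_false(call2$is_case)

  # case via criterion 2 alone, with MPV participating
  f3 <- hemogram_row(3)
  d3 <- compute_decline(hemogram_row(3, mpv = 11, monocytes = 0.9), f3)
  th3 <- mk_thresholds()
  th3$threshold[th3$parameter %in% c("mpv", "monocytes")] <- 0.05
  call3 <- classify_damage(f3, d3, "male", limits, th3)
  expect_equal(call3$criterion1_count, 0L)
  expect_equal(call3$criterion2_count, 2L)
  expect_true(call3$is_case)

  # MPV may not appear in the reference-limit table (criterion 1 excludes it)
  bad_limits <- rbind(limits, data.frame(parameter = "mpv", sex = "any",
                                         lower = 8))
  expect_error(classify_damage(f3, d3, "male", bad_limits, th3), "MPV")
})

test_that("criterion-2 prevalence behaves as the 95th-percentile rule implies", {
  set.seed(10)
  n <- 4000
  dec <- data.frame(worker_id = seq_len(n))
  for (p in btxbmd:::HEME_PARAMS) dec[[p]] <- rnorm(n)
  sex <- rep(c("male", "female"), length.out = n)
  th <- decline_thresholds(dec, sex)
  # per parameter, about 5% exceed their own sex's threshold
  exceed <- sapply(btxbmd:::HEME_PARAMS, function(p) {
    t_ <- th$threshold[match(paste(sex, p), paste(th$sex, th$parameter))]
    mean(dec[[p]] > t_)
  })
  expect_true(all(abs(exceed - 0.05) < 0.012))
  # requiring >= 2 exceedances cuts the case rate well below the
  # any-parameter rate; with 9 independent parameters at 5% each the
  # rate tracks the binomial(9, 0.05) tail P(>=2) ~ 0.071
  count2 <- rowSums(sapply(btxbmd:::HEME_PARAMS, function(p) {
    t_ <- th$threshold[match(paste(sex, p), paste(th$sex, th$parameter))]
    dec[[p]] > t_
  }))
  expect_lt(mean(count2 >= 2), mean(count2 >= 1) / 2)
  expect_lt(abs(mean(count2 >= 2) - (1 - pbinom(1, 9, 0.05))), 0.03)
})

test_that("classification is invariant to parameter ordering", {
  f <- hemogram_row(1, wbc = 3.0, rbc = 4.0)
  d <- compute_decline(hemogram_row(1), f)
  th <- expand.grid(sex = c("male", "female"),
                    parameter = btxbmd:::HEME_PARAMS,
                    stringsAsFactors = FALSE)
  th$threshold <- 1e6
  a <- classify_damage(f, d, "male", thresholds = th)
  perm <- c("worker_id", rev(btxbmd:::HEME_PARAMS))
  b <- classify_damage(f[perm], d[perm], "male", thresholds = th)
  expect_equal(a$is_case, b$is_case)
  expect_equal(a$criterion1_count, b$criterion1_count)
})
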