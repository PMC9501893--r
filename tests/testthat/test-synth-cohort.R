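test_that("same seed gives identical cohorts", {
  spec <- cohort_spec(n_workers = 200, seed = 7)
  a <- suppressMessages(generate_cohort(spec))
  b <- suppressMessages(generate_cohort(spec))
  expect_identical(a, b)
  s1 <- generate_ambient_samples(workplaces = 5, per_workplace = 4, seed = 3)
  s2 <- generate_ambient_samples(workplaces = 5, per_workplace = 4, seed = 3)
  expect_identical(s1, s2)
})

test_that("null effects and zero noise reproduce baseline at follow-up", {
  spec <- cohort_spec(
    n_workers = 100, seed = 2,
    decline_effect_beta = list(),
    decline_noise_sd = setNames(rep(0, 9), btxbmd:::HEME_PARAMS),
    damage_mechanism = NULL)
  co <- generate_cohort(spec)
  expect_equal(co$follow_up, co$baseline)
  expect_true(all(as.matrix(co$decline[-1]) == 0))
})

test_that("cross-analyte rank correlations hit the copula target", {
  spec <- cohort_spec(n_workers = 2000, seed = 1)
  co <- suppressMessages(generate_cohort(spec))
  for (pair in list(c("benzene", "toluene"), c("benzene", "xylene"),
                    c("toluene", "xylene"))) {
    r <- cor(co$exposure[[paste0("ce_", pair[1])]],
             co$exposure[[paste0("ce_", pair[2])]], method = "spearman")
    expect_gte(r, 0.42)
    expect_lte(r, 0.52)
  }
})

test_that("baseline hemogram marginals converge to the calibrated moments", {
  spec <- cohort_spec(n_workers = 5000, seed = 5)
  co <- suppressMessages(generate_cohort(spec))
  # monocytes calibrated to mean 0.47, sd 0.23
  expect_lt(abs(mean(co$baseline$monocytes) - 0.47), 3 * 0.23 / sqrt(5000))
  expect_lt(abs(sd(co$baseline$monocytes) - 0.23), 0.02)
  expect_lt(abs(mean(co$workers$age) - 39.91), 3 * 6.57 / sqrt(5000))
  # cell counts never negative
  expect_true(all(as.matrix(co$follow_up[-1]) >= 0))
})

test_that("regressing generated decline on ln-CE recovers the effect size", {
  spec <- cohort_spec(
    n_workers = 4000, seed = 9,
    decline_effect_beta = list(benzene = c(monocytes = 0.012)),
    damage_mechanism = NULL)
  co <- suppressMessages(generate_cohort(spec))
  fit <- adjusted_decline_model(co$decline$monocytes,
                                co$exposure$ln_ce_benzene, NULL)
  expect_lt(abs(fit$beta - 0.012), 3 * fit$se)
})

test_that("ambient sampler flags below-LOD values and is calibrated", {
  # LOD above everything: all samples flagged, raw values withheld
  s <- generate_ambient_samples(workplaces = 3, per_workplace = 5,
                                lod = c(benzene = 100, toluene = 100,
                                        xylene = 100), seed = 1)
  expect_true(all(s$below_lod))
  expect_true(all(is.na(s$concentration)))
  expect_error(generate_ambient_samples(lod = c(benzene = 0, toluene = 0.02,
                                                xylene = 0.02)), "positive")
  # benzene median near its configured 0.012 mg/m3 at large n
  big <- generate_ambient_samples(workplaces = 200, per_workplace = 12,
                                  seed = 2)
  benz <- substitute_lod(big)
  med <- median(benz$concentration[benz$analyte == "benzene"])
  expect_lt(abs(med - 0.012) / 0.012, 0.2)
})

test_that("damage outcomes follow the mechanism's probability law", {
  ce <- data.frame(worker_id = 1:10000, ce_benzene = rep(2, 10000))
  # background only
  out0 <- generate_damage_outcomes(
    ce, list(analyte = "benzene", family = "multistage1",
             params = c(g = 0.05, b1 = 0)), seed = 3)
  expect_lt(abs(mean(out0$is_case) - 0.05), 3 * sqrt(0.05 * 0.95 / 10000))
  # one-stage law at CE = 2: P = 1 - exp(-0.2) = 0.181
  out1 <- generate_damage_outcomes(
    ce, list(analyte = "benzene", family = "multistage1",
             params = c(g = 0, b1 = 0.1)), seed = 4)
  p_true <- 1 - exp(-0.2)
  expect_equal(unique(out1$p_true), p_true)
  expect_lt(abs(mean(out1$is_case) - p_true),
            3 * sqrt(p_true * (1 - p_true) / 10000))
  expect_error(generate_damage_outcomes(
    ce, list(analyte = "benzene", family = "multistage1",
             params = c(g = 1.5, b1 = 0.1)), seed = 5), "bound")
})

test_that("invalid cohort specs are rejected", {
  expect_error(cohort_spec(n_workers = 5), "at least 10")
  expect_error(cohort_spec(sex_male_frac = 1.2), "proportions")
  R <- default_ce_rank_correlation()
  R[1, 2] <- 0.9
  expect_error(cohort_spec(ce_rank_correlation = R), "symmetric")
  R[2, 1] <- 0.9
  R[1, 3] <- R[3, 1] <- -0.9
  R[2, 3] <- R[3, 2] <- 0.9
  expect_error(suppressMessages(generate_cohort(
    cohort_spec(ce_rank_correlation = R))), "positive definite")
})

test_that("cohort CSV writers persist every table", {
  spec <- cohort_spec(n_workers = 50, seed = 3)
  co <- suppressMessages(generate_cohort(spec))
  dir <- tempfile()
  paths <- write_cohort_csvs(co, dir)
  expect_true(all(file.exists(paths)))
  back <- read.csv(file.path(dir, "exposure.csv"))
  expect_equal(back$ce_benzene, co$exposure$ce_benzene, tolerance = 1e-12)
})
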