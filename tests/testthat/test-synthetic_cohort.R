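test_that("first-stage calibration matches the printed per-SD effects", {
  expect_equal(round(calibrate_first_stage(0.048, 4.8), 2), 1.05)
  expect_equal(round(calibrate_first_stage(0.034, 4.4), 2), 0.81)
  # (R^2 4.6%, SD 19.7) brackets the printed 4.22 nmol/l per SD
  v <- calibrate_first_stage(0.046, 19.7)
  expect_gt(v, 4.20)
  expect_lt(v, 4.25)
  expect_equal(calibrate_first_stage(0, 7), 0)
  expect_error(calibrate_first_stage(1.2, 4.8), "\\[0, 1\\)")
  expect_error(calibrate_first_stage(0.05, -1), "positive")
})

test_that("group odds factors implement the three outcome modes", {
  f <- factorial_group_ors(1.08, 1.05, "additive_null")
  expect_equal(unname(f), c(1, 1.05, 1.08, 1.13))
  expect_equal(reri_from_ors(f[["group3"]], f[["group2"]], f[["group1"]]), 0)
  expect_equal(
    factorial_group_ors(1.2, 1.2, "specified_reri", reri_true = 0.5)[["group3"]],
    1.9
  )
  fm <- factorial_group_ors(1.19, 1.03, "multiplicative")
  expect_equal(reri_from_ors(fm[["group3"]], fm[["group2"]], fm[["group1"]]),
               0.0057, tolerance = 1e-12)
  expect_error(factorial_group_ors(0.2, 0.2, "additive_null"), "non-positive")
})

test_that("a fixed seed gives identical cohorts and different seeds differ", {
  cfg <- sim_config(n = 500, seed = 99)
  s1 <- generate_cohort(cfg)
  s2 <- generate_cohort(cfg)
  expect_identical(s1$cohort, s2$cohort)
  expect_identical(s1$genotypes$dosage, s2$genotypes$dosage)
  expect_identical(s1$weights$bmi$weight, s2$weights$bmi$weight)
  s3 <- generate_cohort(sim_config(n = 500, seed = 100))
  expect_false(identical(s1$cohort$psoriasis, s3$cohort$psoriasis))
})

test_that("generator closure: realized prevalence, R^2 and first stage match the configuration", {
  # full genotype simulation at the default 941/21 variant panels
  cfg <- sim_config(n = 20000, seed = 101)
  sim <- generate_cohort(cfg)
  expect_equal(prs_n_variants(sim$scores$bmi)[["used"]], 941L)
  expect_equal(prs_n_variants(sim$scores$vitd)[["used"]], 21L)
  expect_equal(sim$truth$prevalence_realized, 0.031, tolerance = 0.15)

  db <- run_diagnostics(sim$cohort, sim$scores$bmi, "bmi")
  expect_lt(abs(db$r.squared[db$role == "strength"] - 0.048), 0.012)
  expect_lt(abs(db$beta_per_sd[db$role == "strength"] -
                  calibrate_first_stage(0.048, 4.8)), 0.12)
  dv <- run_diagnostics(sim$cohort, sim$scores$vitd, "vitd")
  expect_lt(abs(dv$r.squared[dv$role == "strength"] - 0.046), 0.012)

  expect_lt(abs(mean(sim$cohort$bmi, na.rm = TRUE) - 27.4), 0.15)
  expect_lt(abs(sd(sim$cohort$bmi, na.rm = TRUE) - 4.8), 0.15)
})

test_that("season offsets cancel exactly after season adjustment", {
  sim <- quick_sim(n = 20000, seed = 102)
  co <- add_season_adjusted(sim$cohort)
  post <- tapply(co$vitd_adj, season_of_month(co$draw_month),
                 mean, na.rm = TRUE)
  expect_true(max(abs(post - post[["autumn"]])) < 1e-10)
  # adjusted 25(OH)D carries the configured season-free distribution
  expect_equal(mean(co$vitd_adj, na.rm = TRUE), 54.8, tolerance = 0.5)
  expect_equal(sd(co$vitd_adj, na.rm = TRUE), 19.7, tolerance = 0.5)
})

test_that("zero genetic effect yields null instrument strength and MR ORs near 1", {
  sim <- quick_sim(n = 20000, seed = 103, r2_bmi = 0, r2_vitd = 0,
                   or_bmi = 1, or_vitd = 1)
  d <- run_diagnostics(sim$cohort, sim$scores$bmi, "bmi")
  expect_lt(d$r.squared[d$role == "strength"], 0.001)
  m <- run_2x2_factorial(sim$cohort, sim$scores$bmi, sim$scores$vitd,
                         covariates = NULL)
  expect_true(all(abs(log(m$estimates$or[-1])) < 0.3))
})

test_that("infeasible configurations error", {
  expect_error(sim_config(n = 100, prevalence = 1.2), "prevalence")
  expect_error(sim_config(n = 100, maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(n = 100, r2_bmi = 1), "r2_bmi")
  expect_error(
    sim_config(n = 100, seed = 1, or_bmi = 1.05, or_vitd = 1.05,
               outcome_mode = "specified_reri", reri_true = -1.2),
    "non-positive"
  )
  expect_error(sim_config(n = 100, nonsense_field = 2), "Unknown")
})

test_that("HUNT-like preset carries its calibration and no measured 25(OH)D", {
  cfg <- sim_config(n = 5000, preset = "hunt", seed = 104)
  expect_equal(cfg$prevalence, 0.090)
  expect_equal(cfg$bmi_mean, 26.4)
  expect_equal(cfg$r2_bmi, 0.034)
  sim <- generate_cohort(cfg, genotypes = FALSE)
  expect_true(all(is.na(sim$cohort$vitd)))
  expect_equal(mean(sim$cohort$psoriasis), 0.09, tolerance = 0.15)
})

test_that("generate_outcome errors on out-of-range groups and returns the odds structure", {
  cfg <- sim_config(n = 100, seed = 105)
  y <- generate_outcome(cfg, groups = rep(0:3, 25))
  expect_true(is_binary <- all(y %in% 0:1))
  expect_equal(unname(attr(y, "odds_factors")), c(1, 1.05, 1.08, 1.13))
  expect_error(generate_outcome(cfg, groups = c(0, 5)), "0..3")
  expect_error(generate_outcome(cfg), "Provide either")
})
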