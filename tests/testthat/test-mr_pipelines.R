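test_that("2x2 factorial MR report is internally consistent on an additive-null cohort", {
  sim <- quick_sim(n = 30000, seed = 51, or_bmi = 1.4, or_vitd = 1.3)
  m <- run_2x2_factorial(sim$cohort, sim$scores$bmi, sim$scores$vitd,
                         covariates = NULL)
  expect_s3_class(m, "factorial_mr")
  expect_equal(m$estimates$or[m$estimates$term == "group0"], 1)
  ors <- m$reri$component_ors
  expect_equal(m$reri$estimate,
               reri_from_ors(ors[["or11"]], ors[["or10"]], ors[["or01"]]),
               tolerance = 1e-10)
  # generator truth: RERI 0
  expect_lt(m$reri$ci_low, 0)
  expect_gt(m$reri$ci_high, 0)
  expect_equal(sum(m$group_counts$n), m$n)
})

test_that("adjusted and unadjusted group ORs agree when covariates have no true effect", {
  sim <- quick_sim(n = 30000, seed = 52, or_bmi = 1.3, or_vitd = 1.2)
  m0 <- run_2x2_factorial(sim$cohort, sim$scores$bmi, sim$scores$vitd,
                          covariates = NULL)
  m1 <- run_2x2_factorial(sim$cohort, sim$scores$bmi, sim$scores$vitd)
  expect_equal(log(m1$estimates$or[-1]), log(m0$estimates$or[-1]),
               tolerance = 0.05)
})

test_that("continuous factorial MR recovers per-SD ORs and the additive-term identity", {
  sim <- quick_sim(n = 50000, seed = 53, exposure_form = "prs_continuous",
                   outcome_mode = "multiplicative", or_bmi = 1.04,
                   or_vitd = 1.02)
  m <- run_continuous_factorial(sim$cohort, sim$scores$bmi, sim$scores$vitd,
                                covariates = NULL)
  est <- m$estimates
  # per-SD ORs recovered within their own 95% CIs
  expect_lt(est$ci_low[est$term == "bmi_score"], 1.04)
  expect_gt(est$ci_high[est$term == "bmi_score"], 1.04)
  expect_lt(est$ci_low[est$term == "vitd_score_decrease"], 1.02)
  expect_gt(est$ci_high[est$term == "vitd_score_decrease"], 1.02)
  expect_equal(m$additive$or, prod(est$or), tolerance = 1e-10)
  # null cross-product truth: RERI ~ (1.04-1)(1.02-1) ~ 0.0008, CI covers it
  expect_lt(m$reri$ci_low, 0.0008)
  expect_gt(m$reri$ci_high, 0.0008)

  # b3 = 0 identity: RERI = (exp(b1)-1)(exp(b2)-1)
  b <- coef(m$fit)
  rv <- factorialmr:::reri_value(
    c(b[["bmi_score"]], b[["vitd_score_decrease"]], 0), "continuous", c(1, 1)
  )
  expect_equal(rv$estimate,
               (exp(b[["bmi_score"]]) - 1) *
                 (exp(b[["vitd_score_decrease"]]) - 1),
               tolerance = 1e-12)
})

test_that("flipping the vitamin D score twice returns the original report", {
  sim <- quick_sim(n = 8000, seed = 54)
  m1 <- run_continuous_factorial(sim$cohort, sim$scores$bmi, sim$scores$vitd,
                                 covariates = NULL)
  twice <- standardize_prs(standardize_prs(sim$scores$vitd, flip = TRUE),
                           flip = TRUE)
  m2 <- run_continuous_factorial(sim$cohort, sim$scores$bmi, twice,
                                 covariates = NULL)
  expect_equal(m2$estimates, m1$estimates)
  expect_equal(m2$reri$estimate, m1$reri$estimate)
})

test_that("scaling to phenotype units is a Wald-ratio rescale with order invariance", {
  # arithmetic contract: log-OR 0.0296 per SD, first stage 1.05 kg/m^2 per
  # SD, target 5 kg/m^2 -> scaled log-OR 0.0296 * 5 / 1.05
  sim <- quick_sim(n = 20000, seed = 55, exposure_form = "prs_continuous",
                   outcome_mode = "multiplicative", or_bmi = 1.06,
                   or_vitd = 1.03)
  m <- run_continuous_factorial(sim$cohort, sim$scores$bmi, sim$scores$vitd,
                                covariates = NULL)
  sc <- scale_estimates(m, first_stage_bmi = 1.05, first_stage_vitd = 4.22)
  b <- coef(m$fit)
  expect_equal(log(sc$estimates$or[1]),
               b[["bmi_score"]] * 5 / 1.05, tolerance = 1e-12)
  expect_equal(log(sc$estimates$or[3]),
               b[["cross_product"]] * (5 / 1.05) * (10 / 4.22),
               tolerance = 1e-12)

  # targets equal to the first-stage effects leave the report unchanged
  id <- scale_estimates(m, 5, 10)
  expect_equal(id$estimates$or, m$estimates$or, tolerance = 1e-12)
  expect_equal(id$reri$estimate, m$reri$estimate, tolerance = 1e-12)

  # order invariance: scaling then RERI equals RERI of a refit on scaled
  # exposures (coefficients of ML logistic scale exactly with 1/column scale)
  s1 <- 5 / 1.05
  s2 <- 10 / 4.22
  X <- m$fit$X
  X2 <- X
  X2[, "bmi_score"] <- X[, "bmi_score"] / s1
  X2[, "vitd_score_decrease"] <- X[, "vitd_score_decrease"] / s2
  X2[, "cross_product"] <- X[, "cross_product"] / (s1 * s2)
  f2 <- fit_logistic(X2, m$fit$y)
  r2 <- reri_from_fit(f2, c("bmi_score", "vitd_score_decrease",
                            "cross_product"), type = "continuous")
  expect_equal(sc$reri$estimate, r2$estimate, tolerance = 1e-6)
  expect_equal(sc$reri$se, r2$se, tolerance = 1e-4)

  expect_error(scale_estimates(m, -1, 4.22), "positive")
  m2x2 <- run_2x2_factorial(sim$cohort, sim$scores$bmi, sim$scores$vitd,
                            covariates = NULL)
  expect_error(scale_estimates(m2x2, 1.05, 4.22), "continuous")
})

test_that("instrument diagnostics recover the configured strength", {
  sim <- quick_sim(n = 20000, seed = 56)
  d <- run_diagnostics(sim$cohort, sim$scores$bmi, "bmi")
  strength <- d[d$role == "strength", ]
  expect_lt(abs(strength$r.squared - 0.048), 0.01)
  expect_lt(abs(strength$beta_per_sd - sim$truth$first_stage[["bmi"]]), 0.1)
  expect_equal(strength$fstat,
               (strength$n - 2) * strength$r.squared /
                 (1 - strength$r.squared), tolerance = 1e-8)
  # score independent of age by construction: CI covers 0
  age_row <- d[d$dependent == "age", ]
  expect_lt(age_row$ci_low, 0)
  expect_gt(age_row$ci_high, 0)
})

test_that("a PRS-version sensitivity grid yields one uniformly-shaped report per pair", {
  sim <- quick_sim(n = 6000, seed = 57)
  sizes <- list(c(1, 1), c(1, 2), c(2, 1))
  reports <- lapply(sizes, function(sz) {
    run_2x2_factorial(sim$cohort, sim$scores$bmi, sim$scores$vitd,
                      covariates = NULL)
  })
  for (r in reports) {
    expect_equal(names(tidy(r)),
                 names(tidy(reports[[1]])))
    expect_equal(r$estimates$term, c("group0", "group1", "group2", "group3"))
  }
})

test_that("autoplot methods return ggplot objects", {
  sim <- quick_sim(n = 6000, seed = 58)
  m <- run_2x2_factorial(sim$cohort, sim$scores$bmi, sim$scores$vitd,
                         covariates = NULL)
  expect_s3_class(autoplot(m), "ggplot")
  d <- run_diagnostics(sim$cohort, sim$scores$bmi, "bmi")
  expect_s3_class(autoplot(d), "ggplot")
  mt <- meta_fixed(c(0.1, -0.1), c(0.2, 0.3))
  expect_s3_class(autoplot(mt), "ggplot")
})
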