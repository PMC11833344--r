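# Printed-table worked examples used here: low-vitamin-D single association
# 435/11,666 exposed vs 10,669/339,125 reference; combined four-group counts
# 5,287/196,501 (reference), 162/5,255 (low vitD only), 5,382/142,624 (high
# BMI only), 273/6,411 (both exposed).

test_that("2x2 odds ratios reproduce the printed worked examples at 2 dp", {
  o1 <- odds_ratio_2x2(435, 11666, 10669, 339125)
  expect_equal(round(o1$or, 2), 1.19)
  o2 <- odds_ratio_2x2(273, 6411, 5287, 196501)
  expect_equal(round(o2$or, 2), 1.58)
  expect_equal(o2$se_log_or,
               sqrt(1 / 273 + 1 / 6411 + 1 / 5287 + 1 / 196501))
  # equal case proportions in both arms -> OR exactly 1
  expect_equal(odds_ratio_2x2(10, 90, 20, 180)$or, 1)
  expect_error(odds_ratio_2x2(0, 10, 10, 10), "Zero cell")
})

test_that("RERI from ORs: additivity at null, arithmetic, and the combined-group example", {
  expect_equal(reri_from_ors(1, 1, 1), 0)
  expect_equal(reri_from_ors(2.0, 1.5, 1.3), 0.2)
  or11 <- odds_ratio_2x2(273, 6411, 5287, 196501)$or
  or10 <- odds_ratio_2x2(5382, 142624, 5287, 196501)$or
  or01 <- odds_ratio_2x2(162, 5255, 5287, 196501)$or
  expect_equal(round(or10, 2), 1.40)
  expect_equal(round(reri_from_ors(or11, or10, or01), 2), 0.03)
  expect_error(reri_from_ors(-1, 1, 1), "positive")
})

test_that("RERI is strictly increasing in OR11 with the other ORs fixed", {
  grid <- seq(1.1, 3, by = 0.1)
  vals <- vapply(grid, reri_from_ors, numeric(1), or10 = 1.4, or01 = 1.2)
  expect_true(all(diff(vals) > 0))
})

test_that("additive term is the product of the component ORs", {
  expect_equal(round(additive_term(log(1.03), log(1.18), log(1.00)), 2), 1.22)
  expect_equal(additive_term(0, 0, 0), 1)
  expect_equal(additive_term(log(2), log(3), log(0.5)), 3.0)
  # multiplicativity at null cross-product
  b1 <- 0.21; b2 <- -0.4
  expect_equal(additive_term(b1, b2, 0), exp(b1) * exp(b2))
})

test_that("validity rule requires all component ORs strictly above 1", {
  expect_true(check_validity(c(1.05, 1.07, 1.12)))
  expect_false(check_validity(c(0.96, 1.07, 1.06)))
  expect_false(check_validity(c(1.0, 1.2, 1.3))) # boundary: strict
  expect_error(check_validity(c(-1, 1, 1)), "positive")
})

test_that("reri_from_fit matches reri_from_ors on its own component ORs to 1e-10", {
  sim <- quick_sim(n = 15000, seed = 31, or_bmi = 1.3, or_vitd = 1.2,
                   outcome_mode = "multiplicative")
  m <- run_2x2_factorial(sim$cohort, sim$scores$bmi, sim$scores$vitd,
                         covariates = NULL)
  ors <- m$reri$component_ors
  expect_equal(
    m$reri$estimate,
    reri_from_ors(ors[["or11"]], ors[["or10"]], ors[["or01"]]),
    tolerance = 1e-10
  )

  # continuous design at the unit contrast obeys the same identity
  mc <- run_continuous_factorial(sim$cohort, sim$scores$bmi, sim$scores$vitd,
                                 covariates = NULL)
  orsc <- mc$reri$component_ors
  expect_equal(
    mc$reri$estimate,
    reri_from_ors(orsc[["or11"]], orsc[["or10"]], orsc[["or01"]]),
    tolerance = 1e-10
  )
})

test_that("null coefficients give RERI 0 with a symmetric CI", {
  X <- cbind(`(Intercept)` = 1, g1 = c(1, 0, 0, 0), g2 = c(0, 1, 0, 0),
             g3 = c(0, 0, 1, 0))
  X <- X[rep(1:4, each = 50), ]
  y <- rep(rep(c(0, 1), 2), 50)
  f <- fit_logistic(X, y) # every group has prevalence 1/2: all b = 0
  r <- reri_from_fit(f, c("g1", "g2", "g3"), type = "2x2")
  expect_equal(r$estimate, 0, tolerance = 1e-8)
  expect_equal(r$ci_low + r$ci_high, 0, tolerance = 1e-8)
  expect_false(r$valid) # ORs are exactly 1, not above
  expect_error(reri_from_fit(f, c("g1", "g2", "nope"), type = "2x2"), "nope")
})

test_that("fixed-effect meta pools by inverse variance", {
  m <- meta_fixed(c(0.4, 0.4), c(0.1, 0.1))
  expect_equal(m$estimate, 0.4)
  expect_equal(m$se, 0.1 / sqrt(2))
  expect_equal(sum(m$weights), 1)

  expect_equal(meta_fixed(c(0, 2), c(0.3, 0.3))$estimate, 1) # symmetry

  # three-study brute-force oracle
  est <- c(-0.1, 0.25, 0.05)
  se <- c(0.12, 0.2, 0.07)
  w <- 1 / se^2
  m3 <- meta_fixed(est, se)
  expect_equal(m3$estimate, (w[1] * est[1] + w[2] * est[2] + w[3] * est[3]) /
                 (w[1] + w[2] + w[3]), tolerance = 1e-12)
  expect_equal(m3$se, sqrt(1 / (w[1] + w[2] + w[3])), tolerance = 1e-12)
  expect_lte(m3$se, min(se))

  expect_error(meta_fixed(c(1, 2), 0.1), "same length")
  expect_error(meta_fixed(1, 0.1), "at least 2")
})
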