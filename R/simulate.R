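# Calibrated synthetic biobank cohort generator. Emulates the statistical
# structure the factorial MR analyses assume — genotype dosages behind two
# polygenic scores, traits with a configurable score-explained variance
# fraction, season-structured 25(OH)D, covariates, and a binary outcome whose
# group-wise odds structure is set directly (including an additive-null mode
# with true RERI exactly zero, which a product-free logistic model does NOT
# give) — and returns the ground truth for recovery tests.

#' First-stage slope implied by a target R-squared
#'
#' The slope of a trait on a unit-variance score explaining `target_r2` of
#' the trait's variance: `sqrt(target_r2) * trait_sd` (trait units per 1 SD
#' of score). E.g. R^2 = 4.8% with trait SD 4.8 kg/m^2 gives 1.05 kg/m^2 per
#' SD.
#'
#' @param target_r2 Fraction of trait variance explained, in `[0, 1)`.
#' @param trait_sd Trait standard deviation (positive).
#' @return Slope in trait units per 1 SD of score.
#' @examples
#' calibrate_first_stage(0.048, 4.8)
#' @export
calibrate_first_stage <- function(target_r2, trait_sd) {
  check_scalar_number(target_r2, "target_r2")
  check_scalar_number(trait_sd, "trait_sd")
  if (target_r2 < 0 || target_r2 >= 1) abort("target_r2 must be in [0, 1).")
  if (trait_sd <= 0) abort("trait_sd must be positive.")
  sqrt(target_r2) * trait_sd
}

#' Group odds factors of the factorial outcome model
#'
#' Odds multipliers of the four factorial groups relative to the reference
#' (group 0), given the two single-exposure odds ratios and the outcome
#' mode: `additive_null` sets the doubly-exposed factor to
#' `or_bmi + or_vitd - 1` (true RERI exactly 0), `specified_reri` adds
#' `reri_true` on top, and `multiplicative` uses `or_bmi * or_vitd` (true
#' RERI `(or_bmi - 1)(or_vitd - 1)`).
#'
#' @param or_bmi Odds ratio of the BMI-only exposed group (group 2).
#' @param or_vitd Odds ratio of the low-vitamin-D-only group (group 1).
#' @param outcome_mode One of `"additive_null"`, `"specified_reri"`,
#'   `"multiplicative"`.
#' @param reri_true Injected RERI for `"specified_reri"`.
#' @return Named numeric vector `c(group0, group1, group2, group3)`.
#' @examples
#' factorial_group_ors(1.08, 1.05, "additive_null") # group3 = 1.13
#' @export
factorial_group_ors <- function(or_bmi, or_vitd,
                                outcome_mode = c("additive_null",
                                                 "specified_reri",
                                                 "multiplicative"),
                                reri_true = 0) {
  outcome_mode <- match.arg(outcome_mode)
  check_scalar_number(or_bmi, "or_bmi")
  check_scalar_number(or_vitd, "or_vitd")
  if (or_bmi <= 0 || or_vitd <= 0) abort("Odds ratios must be positive.")
  g3 <- switch(outcome_mode,
    additive_null = or_bmi + or_vitd - 1,
    specified_reri = or_bmi + or_vitd - 1 + reri_true,
    multiplicative = or_bmi * or_vitd
  )
  out <- c(group0 = 1, group1 = or_vitd, group2 = or_bmi, group3 = g3)
  if (any(out <= 0)) {
    abort("Implied group odds factor is non-positive; adjust the odds ratios / reri_true.")
  }
  out
}

true_reri <- function(config) {
  switch(config$outcome_mode,
    additive_null = 0,
    specified_reri = config$reri_true,
    multiplicative = (config$or_bmi - 1) * (config$or_vitd - 1)
  )
}

#' Simulation configuration
#'
#' Bundles every generator parameter with validation. The `"ukb"` preset is
#' a 398k-biobank-like cohort scaled to `n`: psoriasis prevalence 3.1%, BMI
#' mean 27.4 SD 4.8 kg/m^2, season-adjusted 25(OH)D mean 54.8 SD 19.7
#' nmol/l, score-explained variance R^2 = 4.8% (BMI) and 4.6% (25(OH)D),
#' age 56.9 (7.9), 53.8% female, BMI/25(OH)D missingness 0.32%/8.85%. The
#' `"hunt"` preset: prevalence 9.0%, BMI 26.4 (4.4), R^2 = 3.4%, age 46.1
#' (16.9), 53.0% female, no measured 25(OH)D (`vitd_available = FALSE`).
#' Any field can be overridden through `...`.
#'
#' @param n Number of participants (default 50,000).
#' @param preset `"ukb"` (default) or `"hunt"`.
#' @param seed Seed driving all randomness of [generate_cohort()].
#' @param ... Overrides: `n_variants` (named c(bmi=, vitd=)), `maf_range`,
#'   `r2_bmi`, `r2_vitd`, `bmi_mean`, `bmi_sd`, `vitd_mean`, `vitd_sd`,
#'   `season_offsets` (named winter/spring/summer/autumn, nmol/l),
#'   `prevalence`, `exposure_form` (`"group"`, `"prs_continuous"`,
#'   `"trait_continuous"`), `outcome_mode`, `or_bmi`, `or_vitd`,
#'   `reri_true`, `missing_bmi`, `missing_vitd`, `age_mean`, `age_sd`,
#'   `p_female`, `n_batches`, `n_pcs`, `vitd_available`.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n = 50000L, preset = c("ukb", "hunt"), seed = NULL,
                       ...) {
  preset <- match.arg(preset)
  cfg <- list(
    n = as.integer(n), preset = preset, seed = seed,
    n_variants = c(bmi = 941L, vitd = 21L),
    maf_range = c(0.05, 0.5),
    r2_bmi = 0.048, r2_vitd = 0.046,
    bmi_mean = 27.4, bmi_sd = 4.8,
    vitd_mean = 54.8, vitd_sd = 19.7,
    season_offsets = c(winter = -7, spring = -2, summer = 9, autumn = 0),
    prevalence = 0.031,
    exposure_form = "group",
    outcome_mode = "additive_null",
    or_bmi = 1.08, or_vitd = 1.05, reri_true = 0,
    missing_bmi = 1262 / 398404, missing_vitd = 35247 / 398404,
    age_mean = 56.9, age_sd = 7.9, p_female = 0.538,
    n_batches = 5L, n_pcs = 20L,
    vitd_available = TRUE
  )
  if (preset == "hunt") {
    cfg$prevalence <- 0.090
    cfg$bmi_mean <- 26.4
    cfg$bmi_sd <- 4.4
    cfg$r2_bmi <- 0.034
    cfg$age_mean <- 46.1
    cfg$age_sd <- 16.9
    cfg$p_female <- 0.530
    cfg$n_variants <- c(bmi = 941L, vitd = 19L)
    cfg$vitd_available <- FALSE
    cfg$missing_bmi <- 638 / 86648
  }
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0L) {
    abort(sprintf("Unknown sim_config field(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  cfg[names(dots)] <- dots
  cfg$exposure_form <- match.arg(cfg$exposure_form,
                                 c("group", "prs_continuous",
                                   "trait_continuous"))
  cfg$outcome_mode <- match.arg(cfg$outcome_mode,
                                c("additive_null", "specified_reri",
                                  "multiplicative"))
  if (cfg$prevalence <= 0 || cfg$prevalence >= 1) {
    abort("prevalence must be in (0, 1).")
  }
  for (r2 in c("r2_bmi", "r2_vitd")) {
    if (cfg[[r2]] < 0 || cfg[[r2]] >= 1) abort(sprintf("%s must be in [0, 1).", r2))
  }
  if (any(cfg$maf_range <= 0) || any(cfg$maf_range > 0.5)) {
    abort("maf_range must lie in (0, 0.5].")
  }
  factorial_group_ors(cfg$or_bmi, cfg$or_vitd, cfg$outcome_mode, cfg$reri_true)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %s-like, n = %d, prevalence = %.3f, %s/%s outcome (OR_bmi %.3g, OR_vitd %.3g, true RERI %.4g)\n",
    x$preset, x$n, x$prevalence, x$exposure_form, x$outcome_mode,
    x$or_bmi, x$or_vitd, true_reri(x)
  ))
  invisible(x)
}

# continuous odds multiplier at exposures (x1, x2), both risk-increasing,
# per-unit odds ratios or1/or2; same constructions as the group modes
odds_factor_continuous <- function(x1, x2, or1, or2, outcome_mode, reri_true) {
  f <- switch(outcome_mode,
    multiplicative = or1^x1 * or2^x2,
    additive_null = or1^x1 + or2^x2 - 1,
    specified_reri = or1^x1 + or2^x2 - 1 + reri_true * x1 * x2
  )
  if (any(f <= 0)) {
    abort("Implied odds factor non-positive for some individuals; reduce the effect sizes or use the multiplicative mode.")
  }
  f
}

# baseline odds o0 such that mean(plogis(log(o0) + log(f))) = prevalence
solve_baseline_odds <- function(f, prevalence) {
  root <- uniroot(
    function(lo) mean(plogis(lo + log(f))) - prevalence,
    interval = c(-30, 10), tol = 1e-12
  )
  exp(root$root)
}

#' Generate the binary outcome from the configured odds structure
#'
#' Given either factorial group labels or two continuous risk-increasing
#' exposures, assigns per-individual odds `o0 * f_i` where the factor `f_i`
#' follows the configured outcome mode ([factorial_group_ors()] for groups;
#' the analogous construction per exposure unit for continuous exposures)
#' and the baseline odds `o0` is solved so the expected prevalence matches
#' the configuration.
#'
#' @param config A `sim_config`.
#' @param groups Integer vector in 0..3 (group-based outcome), or `NULL`.
#' @param x_bmi,x_vitd Continuous risk-increasing exposures (used when
#'   `groups` is `NULL`); `config$or_bmi` / `config$or_vitd` are then
#'   interpreted per unit of these.
#' @return Integer 0/1 vector with attributes `odds_factors` (the group
#'   factor vector, for group mode) and `baseline_odds`.
#' @export
generate_outcome <- function(config, groups = NULL, x_bmi = NULL,
                             x_vitd = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(groups)) {
    if (any(!(groups %in% 0:3))) abort("groups must be in 0..3.")
    fac <- factorial_group_ors(config$or_bmi, config$or_vitd,
                               config$outcome_mode, config$reri_true)
    f <- fac[groups + 1L]
  } else {
    if (is.null(x_bmi) || is.null(x_vitd)) {
      abort("Provide either `groups` or both `x_bmi` and `x_vitd`.")
    }
    fac <- NULL
    f <- odds_factor_continuous(x_bmi, x_vitd, config$or_bmi, config$or_vitd,
                                config$outcome_mode, config$reri_true)
  }
  o0 <- solve_baseline_odds(f, config$prevalence)
  p <- plogis(log(o0) + log(f))
  if (any(p <= 0 | p >= 1)) abort("Implied outcome probability outside (0, 1).")
  y <- rbinom(length(f), 1L, p)
  attr(y, "odds_factors") <- fac
  attr(y, "baseline_odds") <- o0
  y
}

random_alleles <- function(m) {
  bases <- c("A", "C", "G", "T")
  ea <- sample(bases, m, replace = TRUE)
  oa <- vapply(ea, function(e) sample(setdiff(bases, e), 1L), "")
  list(effect = ea, other = unname(oa))
}

simulate_score_panel <- function(n, m, maf_range, trait, id_prefix,
                                 sample_ids) {
  maf <- runif(m, maf_range[1L], maf_range[2L])
  w <- rnorm(m)
  # rescale so the raw score has (theoretical) unit variance under HWE
  w <- w / sqrt(sum(w^2 * 2 * maf * (1 - maf)))
  G <- matrix(
    rbinom(n * m, 2L, rep(maf, each = n)),
    nrow = n, dimnames = list(sample_ids, paste0(id_prefix, seq_len(m)))
  )
  al <- random_alleles(m)
  weights <- new_weight_tbl(
    tibble(variant_id = colnames(G), effect_allele = al$effect,
           other_allele = al$other, weight = w),
    trait = trait
  )
  alleles <- tibble(variant_id = colnames(G), counted_allele = al$effect,
                    other_allele = al$other)
  list(G = G, alleles = alleles, weights = weights)
}

#' Generate a synthetic factorial MR cohort
#'
#' Draws genotype dosages (`Binomial(2, MAF)` per variant, MAF ~
#' `U(maf_range)`), fixed per-variant weights, polygenic scores computed
#' through the package's own PRS engine, traits `mean + slope * z + noise`
#' with the slope calibrated so the score explains the configured `R^2`
#' ([calibrate_first_stage()]), season-offset 25(OH)D by simulated draw
#' month, covariates (age, sex, genotyping batch, standard-normal PCs), and
#' the binary psoriasis outcome from the configured group-odds structure
#' ([generate_outcome()]). Missingness masks are applied to the measured
#' traits last. All randomness derives from `config$seed`, so a fixed seed
#' gives identical output.
#'
#' With `genotypes = FALSE`, the genotype stage is skipped and the
#' standardized scores are drawn directly as N(0, 1) — the large-panel limit
#' of a standardized PRS — which is the fast path for replicate-heavy
#' experiments (CI coverage, parameter recovery).
#'
#' @param config A [sim_config()].
#' @param genotypes Simulate the genotype panels (default `TRUE`)?
#' @return A `sim_cohort` list: `cohort` (tibble), `genotypes`
#'   (`geno_matrix` of both panels, or `NULL`), `weights` (list of the two
#'   `weight_tbl`s, or `NULL`), `scores` (list of standardized `prs_tbl`s,
#'   trait-increasing orientation), and `truth` (`sim_truth`: first-stage
#'   slopes, group odds factors, true RERI, realized prevalence, seed).
#' @export
generate_cohort <- function(config, genotypes = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n
  ids <- sprintf("S%07d", seq_len(n))

  slope_bmi <- calibrate_first_stage(config$r2_bmi, config$bmi_sd)
  slope_vitd <- calibrate_first_stage(config$r2_vitd, config$vitd_sd)
  for (tr in c("bmi", "vitd")) {
    sl <- if (tr == "bmi") slope_bmi else slope_vitd
    sdv <- if (tr == "bmi") config$bmi_sd else config$vitd_sd
    if (sl^2 > sdv^2) {
      abort(sprintf("Infeasible variance decomposition for %s.", tr))
    }
  }

  geno <- NULL
  weights <- NULL
  if (genotypes) {
    pb <- simulate_score_panel(n, config$n_variants[["bmi"]],
                               config$maf_range, "BMI", "rsB", ids)
    pv <- simulate_score_panel(n, config$n_variants[["vitd"]],
                               config$maf_range, "25OHD", "rsV", ids)
    geno <- new_geno_matrix(cbind(pb$G, pv$G),
                            dplyr::bind_rows(pb$alleles, pv$alleles))
    weights <- list(bmi = pb$weights, vitd = pv$weights)
    bmi_prs <- standardize_prs(compute_prs(geno, pb$weights))
    vitd_prs <- standardize_prs(compute_prs(geno, pv$weights))
  } else {
    mk <- function(trait) {
      z <- rnorm(n)
      new_prs_tbl(
        tibble(sample_id = ids, raw = z,
               standardized = (z - mean(z)) / pop_sd(z)),
        trait = trait, n_requested = 0L, n_used = 0L,
        variants_used = character(0)
      )
    }
    bmi_prs <- mk("BMI")
    vitd_prs <- mk("25OHD")
  }
  z_bmi <- bmi_prs$standardized
  z_vitd <- vitd_prs$standardized

  bmi <- config$bmi_mean + slope_bmi * z_bmi +
    rnorm(n, 0, sqrt(config$bmi_sd^2 - slope_bmi^2))
  draw_month <- sample.int(12L, n, replace = TRUE)
  if (config$vitd_available) {
    vitd_adj_true <- config$vitd_mean + slope_vitd * z_vitd +
      rnorm(n, 0, sqrt(config$vitd_sd^2 - slope_vitd^2))
    vitd_adj_true <- pmax(vitd_adj_true, 0.1)
    offsets <- config$season_offsets[
      as.character(season_of_month(draw_month))
    ]
    vitd <- pmax(vitd_adj_true + unname(offsets), 0.1)
  } else {
    vitd_adj_true <- rep(NA_real_, n)
    vitd <- rep(NA_real_, n)
    draw_month <- rep(NA_integer_, n)
  }

  age <- pmax(rnorm(n, config$age_mean, config$age_sd), 18)
  sex <- rbinom(n, 1L, config$p_female) # 1 = female
  batch <- paste0("b", sample.int(config$n_batches, n, replace = TRUE))
  pcs <- matrix(rnorm(n * config$n_pcs), nrow = n,
                dimnames = list(NULL, paste0("pc", seq_len(config$n_pcs))))

  bl <- z_bmi <= median(z_bmi)
  vl <- z_vitd <= median(z_vitd)
  group <- ifelse(bl & !vl, 0L, ifelse(bl & vl, 1L, ifelse(!bl & !vl, 2L, 3L)))

  y <- switch(config$exposure_form,
    group = generate_outcome(config, groups = group),
    prs_continuous = generate_outcome(config, x_bmi = z_bmi,
                                      x_vitd = -z_vitd),
    trait_continuous = {
      if (!config$vitd_available) {
        abort("trait_continuous outcome requires vitd_available = TRUE.")
      }
      generate_outcome(
        config,
        x_bmi = (bmi - config$bmi_mean) / 5,
        x_vitd = -(vitd_adj_true - config$vitd_mean) / 10
      )
    }
  )

  if (config$missing_bmi > 0) {
    bmi[runif(n) < config$missing_bmi] <- NA_real_
  }
  if (config$vitd_available && config$missing_vitd > 0) {
    vitd[runif(n) < config$missing_vitd] <- NA_real_
  }

  cohort <- tibble(
    sample_id = ids, age = age, sex = sex, batch = batch,
    as_tibble(pcs), bmi = bmi, vitd = vitd, draw_month = draw_month,
    psoriasis = as.integer(y)
  )
  truth <- structure(
    list(
      first_stage = c(bmi = slope_bmi, vitd = slope_vitd),
      group_ors = factorial_group_ors(config$or_bmi, config$or_vitd,
                                      config$outcome_mode, config$reri_true),
      reri_true = true_reri(config),
      baseline_odds = attr(y, "baseline_odds"),
      prevalence_target = config$prevalence,
      prevalence_realized = mean(y),
      seed = config$seed
    ),
    class = "sim_truth"
  )
  structure(
    list(cohort = cohort, genotypes = geno, weights = weights,
         scores = list(bmi = bmi_prs, vitd = vitd_prs),
         truth = truth, config = config),
    class = "sim_cohort"
  )
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf(
    "<sim_cohort> n = %d (%s-like), realized prevalence %.4f, true RERI %.4g\n",
    nrow(x$cohort), x$config$preset, x$truth$prevalence_realized,
    x$truth$reri_true
  ))
  invisible(x)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf(
    "<sim_truth> first stage: %.4g (BMI), %.4g (25OHD) per SD; group ORs %s; true RERI %.4g\n",
    x$first_stage[["bmi"]], x$first_stage[["vitd"]],
    paste(format(x$group_ors, digits = 3), collapse = "/"), x$reri_true
  ))
  invisible(x)
}
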