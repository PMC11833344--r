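# Factorial MR orchestration: the 2x2 and continuous factorial analyses,
# Wald-ratio scaling of continuous estimates to phenotype units, and
# instrument diagnostics (strength and PRS-confounder associations).

#' Default factorial MR adjustment covariates
#'
#' Age, sex, genotyping batch and principal components 1-20 — the covariate
#' set used to control for population stratification and batch effects.
#'
#' @param n_pcs Number of principal components (default 20).
#' @return Character vector of covariate names.
#' @export
mr_covariates <- function(n_pcs = 20L) {
  c("age", "sex", "batch", paste0("pc", seq_len(n_pcs)))
}

new_factorial_mr <- function(type, estimates, reri, fit, covariates,
                             additive = NULL, scaled = FALSE,
                             prs_versions = NULL, group_counts = NULL) {
  structure(
    list(type = type, estimates = estimates, additive = additive,
         reri = reri, fit = fit, covariates = covariates, scaled = scaled,
         prs_versions = prs_versions, group_counts = group_counts,
         n = if (is.null(fit)) NA_integer_ else fit$n),
    class = "factorial_mr"
  )
}

#' @export
print.factorial_mr <- function(x, ...) {
  cat(sprintf("<factorial_mr> %s design%s, n = %d, covariates: %s\n",
              x$type, if (x$scaled) " (scaled to phenotype units)" else "",
              x$n,
              if (length(x$covariates)) paste(x$covariates, collapse = ", ")
              else "none"))
  if (!is.null(x$prs_versions)) {
    cat(sprintf("PRS versions: %s\n", paste(x$prs_versions, collapse = " / ")))
  }
  print(x$estimates)
  if (!is.null(x$additive)) {
    cat(sprintf("Additive term exp(b1+b2+b3) = %.4f (95%% CI %.4f to %.4f)\n",
                x$additive$or, x$additive$ci_low, x$additive$ci_high))
  }
  print(x$reri)
  invisible(x)
}

#' @method tidy factorial_mr
#' @export
tidy.factorial_mr <- function(x, ...) {
  out <- x$estimates
  if (!is.null(x$additive)) {
    out <- dplyr::bind_rows(out, tibble(
      term = "additive_term", or = x$additive$or,
      ci_low = x$additive$ci_low, ci_high = x$additive$ci_high
    ))
  }
  dplyr::bind_rows(out, tibble(
    term = "RERI", or = NA_real_, estimate = x$reri$estimate,
    std.error = x$reri$se, ci_low = x$reri$ci_low, ci_high = x$reri$ci_high,
    valid = x$reri$valid
  ))
}

#' @method glance factorial_mr
#' @export
glance.factorial_mr <- function(x, ...) {
  tibble(
    type = x$type, nobs = x$n, scaled = x$scaled,
    reri = x$reri$estimate, reri.conf.low = x$reri$ci_low,
    reri.conf.high = x$reri$ci_high, reri.valid = x$reri$valid
  )
}

prs_version_label <- function(prs) {
  nv <- prs_n_variants(prs)
  sprintf("%s:%d/%d", attr(prs, "trait") %||% "?", nv[["used"]],
          nv[["requested"]])
}

#' 2x2 factorial Mendelian randomization analysis
#'
#' Fits psoriasis on the three factorial-group indicators (groups from
#' [assign_factorial_groups()]; the expected-lowest-risk group 0 is the
#' reference) plus the adjustment covariates, and derives the RERI from the
#' three group coefficients with its validity flag (all component ORs > 1).
#'
#' @param cohort Cohort tibble (must contain `sample_id`, `psoriasis` and
#'   the covariates).
#' @param bmi_prs,vitd_prs `prs_tbl` scores on the same samples; the
#'   25(OH)D score in trait-increasing orientation.
#' @param covariates Adjustment covariates; default [mr_covariates()]. Use
#'   `NULL` for an unadjusted fit.
#' @param ci_method,n_boot,seed Passed to [reri_from_fit()].
#' @return A `factorial_mr` report: per-group ORs with 95% CIs, the
#'   `reri_result`, group counts, and the underlying `logit_fit`.
#' @export
run_2x2_factorial <- function(cohort, bmi_prs, vitd_prs,
                              covariates = mr_covariates(),
                              ci_method = c("delta", "bootstrap"),
                              n_boot = 2000L, seed = NULL) {
  ci_method <- match.arg(ci_method)
  groups <- assign_factorial_groups(bmi_prs, vitd_prs)
  use <- dplyr::inner_join(as_tibble(cohort), groups, by = "sample_id")
  if (nrow(use) == 0L) abort("No samples shared between cohort and PRS tables.")
  keep <- complete.cases(use[, c("psoriasis", covariates)])
  use <- use[keep, , drop = FALSE]
  tabg <- table(factor(use$group, levels = 0:3))
  if (any(tabg == 0L)) {
    abort(sprintf("Empty factorial group(s): %s",
                  paste(names(tabg)[tabg == 0L], collapse = ", ")))
  }
  ind <- function(g) as.numeric(use$group == g)
  X <- cbind(
    `(Intercept)` = 1, group1 = ind(1L), group2 = ind(2L), group3 = ind(3L),
    covariate_design(use, covariates)
  )
  fit <- fit_logistic(X, use$psoriasis)
  trm <- c("group1", "group2", "group3")
  td <- tidy(fit, exponentiate = TRUE)
  est <- td[match(trm, td$term), c("term", "estimate", "conf.low", "conf.high")]
  names(est) <- c("term", "or", "ci_low", "ci_high")
  est <- dplyr::bind_rows(
    tibble(term = "group0", or = 1, ci_low = NA_real_, ci_high = NA_real_),
    est
  )
  reri <- reri_from_fit(fit, trm, type = "2x2", method = ci_method,
                        n_boot = n_boot, seed = seed)
  new_factorial_mr(
    "2x2", est, reri, fit, covariates,
    prs_versions = c(prs_version_label(bmi_prs), prs_version_label(vitd_prs)),
    group_counts = tibble(group = 0:3, n = as.integer(tabg))
  )
}

#' Continuous factorial Mendelian randomization analysis
#'
#' Fits psoriasis on the standardized BMI score (per 1 SD increase), the
#' standardized 25(OH)D score in risk-increasing orientation (per 1 SD
#' *decrease*; the score is flipped here if passed unflipped), their
#' cross-product (computed after flipping) and the covariates. Reports
#' per-SD ORs, the cross-product OR, the additive term `exp(b1 + b2 + b3)`
#' and the RERI at the (+1, +1) contrast.
#'
#' @inheritParams run_2x2_factorial
#' @param contrast RERI contrast in SD units of the two risk-increasing
#'   scores (default `c(1, 1)`).
#' @return A `factorial_mr` report (type `"continuous"`).
#' @export
run_continuous_factorial <- function(cohort, bmi_prs, vitd_prs,
                                     covariates = mr_covariates(),
                                     contrast = c(1, 1),
                                     ci_method = c("delta", "bootstrap"),
                                     n_boot = 2000L, seed = NULL) {
  ci_method <- match.arg(ci_method)
  bmi_prs <- standardize_prs(bmi_prs)
  vitd_prs <- standardize_prs(vitd_prs)
  if ((attr(vitd_prs, "orientation") %||% 1L) == 1L) {
    vitd_prs <- standardize_prs(vitd_prs, flip = TRUE)
  }
  scores <- dplyr::inner_join(
    dplyr::select(bmi_prs, "sample_id", bmi_score = "standardized"),
    dplyr::select(vitd_prs, "sample_id", vitd_score_dec = "standardized"),
    by = "sample_id"
  )
  use <- dplyr::inner_join(as_tibble(cohort), scores, by = "sample_id")
  if (nrow(use) == 0L) abort("No samples shared between cohort and PRS tables.")
  keep <- complete.cases(use[, c("psoriasis", covariates)])
  use <- use[keep, , drop = FALSE]
  X <- cbind(
    `(Intercept)` = 1,
    bmi_score = use$bmi_score,
    vitd_score_decrease = use$vitd_score_dec,
    cross_product = use$bmi_score * use$vitd_score_dec,
    covariate_design(use, covariates)
  )
  fit <- fit_logistic(X, use$psoriasis)
  trm <- c("bmi_score", "vitd_score_decrease", "cross_product")
  td <- tidy(fit, exponentiate = TRUE)
  est <- td[match(trm, td$term), c("term", "estimate", "conf.low", "conf.high")]
  names(est) <- c("term", "or", "ci_low", "ci_high")
  reri <- reri_from_fit(fit, trm, type = "continuous", contrast = contrast,
                        method = ci_method, n_boot = n_boot, seed = seed)
  new_factorial_mr(
    "continuous", est, reri, fit, covariates,
    additive = additive_term_ci(fit, trm),
    prs_versions = c(prs_version_label(bmi_prs), prs_version_label(vitd_prs))
  )
}

#' Scale continuous factorial MR estimates to phenotype units
#'
#' Wald-ratio rescaling: each exposure log-OR is multiplied by
#' `target / first_stage` (e.g. 5 kg/m^2 divided by the kg/m^2-per-SD
#' first-stage effect of the BMI score), the cross-product log-OR by both
#' factors, and the covariance block is scaled conformably
#' (`Sigma' = D Sigma D`). The RERI is then *recomputed* from the scaled
#' coefficients with a delta CI — RERI is non-linear in the coefficients, so
#' it cannot be rescaled directly. Only continuous reports can be scaled.
#'
#' @param report A continuous `factorial_mr` report.
#' @param first_stage_bmi First-stage effect of the BMI score (kg/m^2 per
#'   1 SD of score; must be positive).
#' @param first_stage_vitd First-stage effect of the 25(OH)D score (nmol/l
#'   per 1 SD of score; positive).
#' @param targets Phenotype contrasts to scale to, default `c(bmi = 5,
#'   vitd = 10)` (5 kg/m^2 increase, 10 nmol/l decrease).
#' @return A new `factorial_mr` report with `scaled = TRUE`.
#' @export
scale_estimates <- function(report, first_stage_bmi, first_stage_vitd,
                            targets = c(bmi = 5, vitd = 10)) {
  stopifnot(inherits(report, "factorial_mr"))
  if (report$type != "continuous") {
    abort("Only continuous factorial reports can be scaled to phenotype units.")
  }
  check_scalar_number(first_stage_bmi, "first_stage_bmi")
  check_scalar_number(first_stage_vitd, "first_stage_vitd")
  if (first_stage_bmi <= 0 || first_stage_vitd <= 0) {
    abort("First-stage effects must be positive.")
  }
  s1 <- targets[["bmi"]] / first_stage_bmi
  s2 <- targets[["vitd"]] / first_stage_vitd
  trm <- c("bmi_score", "vitd_score_decrease", "cross_product")
  D <- diag(c(s1, s2, s1 * s2))
  fit <- report$fit
  b <- drop(D %*% fit$coefficients[trm])
  Sigma <- D %*% fit$vcov[trm, trm] %*% D
  se <- sqrt(diag(Sigma))
  est <- tibble(
    term = c(sprintf("bmi_per%g_kgm2", targets[["bmi"]]),
             sprintf("vitd_per%g_nmoll_decrease", targets[["vitd"]]),
             "cross_product"),
    or = exp(b),
    ci_low = exp(b - Z95 * se),
    ci_high = exp(b + Z95 * se)
  )
  rv <- reri_value(setNames(b, trm), "continuous", c(1, 1))
  se_reri <- sqrt(drop(crossprod(rv$gradient, Sigma %*% rv$gradient)))
  reri <- new_reri_result(
    rv$estimate, se_reri, rv$estimate - Z95 * se_reri,
    rv$estimate + Z95 * se_reri, method = "delta",
    component_ors = rv$component_ors, contrast = c(1, 1), n = fit$n
  )
  additive <- list(
    or = exp(sum(b)),
    ci_low = exp(sum(b) - Z95 * sqrt(sum(Sigma))),
    ci_high = exp(sum(b) + Z95 * sqrt(sum(Sigma)))
  )
  out <- new_factorial_mr(
    "continuous", est, reri, fit, report$covariates,
    additive = additive, scaled = TRUE, prs_versions = report$prs_versions
  )
  out$scale_factors <- c(bmi = s1, vitd = s2)
  out
}

#' Instrument diagnostics for one PRS
#'
#' Instrument strength — the univariable regression of the measured trait on
#' the standardized score (beta per 1 SD with CI, R^2, F) — plus the
#' PRS-confounder association table: each candidate confounder regressed on
#' the score.
#'
#' @param cohort Cohort tibble.
#' @param prs `prs_tbl` for the instrument.
#' @param trait Name of the measured trait column the score instruments
#'   (`"bmi"` or `"vitd"`).
#' @param confounders Candidate confounder columns; defaults to the other
#'   trait (when present) plus age and sex.
#' @return An `instrument_diag` tibble: one row per dependent variable with
#'   `beta_per_sd`, CI, `r.squared`, `fstat`, `n` and a `role` column
#'   (`"strength"` or `"confounder"`).
#' @export
run_diagnostics <- function(cohort, prs, trait = c("bmi", "vitd"),
                            confounders = NULL) {
  trait <- match.arg(trait)
  prs <- standardize_prs(prs)
  if (is.null(confounders)) {
    # default candidates: the other trait plus age and sex, restricted to
    # columns with enough observed values to regress on
    confounders <- intersect(
      c(setdiff(c("bmi", "vitd"), trait), "age", "sex"), names(cohort)
    )
    confounders <- confounders[
      vapply(confounders, function(cl) sum(!is.na(cohort[[cl]])) >= 3L,
             logical(1))
    ]
  }
  use <- dplyr::inner_join(
    as_tibble(cohort),
    dplyr::select(prs, "sample_id", score = "standardized"),
    by = "sample_id"
  )
  one <- function(dep, role) {
    f <- fit_linear_univariable(use$score, use[[dep]])
    tibble(
      dependent = dep, role = role, beta_per_sd = f$slope,
      ci_low = f$ci[["lower"]], ci_high = f$ci[["upper"]],
      r.squared = f$r.squared, fstat = f$fstat, n = f$n
    )
  }
  out <- dplyr::bind_rows(
    one(trait, "strength"),
    purrr::map_dfr(confounders, one, role = "confounder")
  )
  attr(out, "trait") <- attr(prs, "trait")
  class(out) <- c("instrument_diag", class(out))
  out
}
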