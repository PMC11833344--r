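# Traditional cross-sectional analyses: season adjustment of serum 25(OH)D,
# threshold dichotomization of the measured exposures, and the continuous and
# 2x2 observational interaction models that mirror the factorial MR design.

#' Season of a calendar month
#'
#' December-February = winter, March-May = spring, June-August = summer,
#' September-November = autumn (the reference season).
#'
#' @param month Integer vector in 1..12 (NA allowed).
#' @return Factor with levels winter, spring, summer, autumn.
#' @export
season_of_month <- function(month) {
  if (any(!(month %in% 1:12), na.rm = TRUE)) {
    abort("month must be in 1..12.")
  }
  map <- c("winter", "winter", "spring", "spring", "spring",
           "summer", "summer", "summer", "autumn", "autumn", "autumn",
           "winter")
  factor(map[month], levels = c("winter", "spring", "summer", "autumn"))
}

#' Season-adjust serum 25(OH)D values
#'
#' Converts every measurement to an autumn-equivalent value by subtracting
#' the mean of its draw season and adding the autumn mean (e.g. a summer
#' value of 80 with summer mean 60 and autumn mean 50 becomes 70). Season
#' means are estimated from the non-missing values of the sample itself.
#' After adjustment every season's mean equals the autumn mean, so the
#' operation is idempotent. Missing values stay missing.
#'
#' @param vitd Numeric vector of 25(OH)D (nmol/l), NA allowed.
#' @param draw_month Matching vector of draw months (1-12); must be present
#'   wherever `vitd` is.
#' @return List with `adjusted` (same length as `vitd`) and `season_means`
#'   (tibble: season, mean, n).
#' @export
season_adjust <- function(vitd, draw_month) {
  if (length(vitd) != length(draw_month)) {
    abort("vitd and draw_month must have the same length.")
  }
  obs <- !is.na(vitd)
  if (any(obs & is.na(draw_month))) {
    abort("draw_month must be present wherever vitd is measured.")
  }
  season <- season_of_month(draw_month)
  tab <- tibble(season = season[obs], vitd = vitd[obs]) |>
    dplyr::group_by(.data$season, .drop = FALSE) |>
    dplyr::summarise(mean = mean(.data$vitd), n = dplyr::n(), .groups = "drop")
  empty <- tab$season[tab$n == 0L]
  if (length(empty) > 0L) {
    abort(sprintf("No 25(OH)D observations in season(s): %s",
                  paste(as.character(empty), collapse = ", ")))
  }
  means <- setNames(tab$mean, as.character(tab$season))
  adjusted <- vitd - means[as.character(season)] + means[["autumn"]]
  list(adjusted = unname(adjusted), season_means = tab)
}

#' Add a season-adjusted 25(OH)D column to a cohort table
#'
#' Data-frame-first wrapper around [season_adjust()]; adds `vitd_adj`.
#'
#' @param cohort Cohort tibble with `vitd` and `draw_month`.
#' @return The cohort with a `vitd_adj` column (season means stored in the
#'   `season_means` attribute).
#' @export
add_season_adjusted <- function(cohort) {
  if (!all(c("vitd", "draw_month") %in% names(cohort))) {
    abort("cohort needs `vitd` and `draw_month` columns.")
  }
  sa <- season_adjust(cohort$vitd, cohort$draw_month)
  out <- dplyr::mutate(as_tibble(cohort), vitd_adj = sa$adjusted)
  attr(out, "season_means") <- sa$season_means
  out
}

#' Dichotomize the measured exposures
#'
#' Adds indicator columns for the observational 2x2 design: `low_vitd`
#' (season-adjusted 25(OH)D strictly below 25 nmol/l) and `high_bmi`
#' (BMI strictly above 27.5 kg/m^2, the WHO public-health action threshold),
#' plus the combined `obs_group` mirroring the factorial coding: 0 = neither
#' (reference), 1 = low 25(OH)D only, 2 = high BMI only, 3 = both.
#' `obs_group` is `NA` where either measure is missing (complete-case in the
#' 2x2 analysis).
#'
#' @param cohort Cohort tibble with `bmi`; `vitd_adj` is computed via
#'   [add_season_adjusted()] if absent.
#' @param vitd_threshold 25(OH)D cutoff in nmol/l (default 25; `< threshold`
#'   counts as exposed).
#' @param bmi_threshold BMI cutoff in kg/m^2 (default 27.5; `> threshold`
#'   counts as exposed).
#' @return The cohort with `low_vitd`, `high_bmi` and `obs_group` columns.
#' @export
dichotomize_exposures <- function(cohort, vitd_threshold = 25,
                                  bmi_threshold = 27.5) {
  if (!"vitd_adj" %in% names(cohort)) {
    cohort <- add_season_adjusted(cohort)
  }
  dplyr::mutate(
    as_tibble(cohort),
    low_vitd = .data$vitd_adj < vitd_threshold,
    high_bmi = .data$bmi > bmi_threshold,
    obs_group = dplyr::case_when(
      !.data$high_bmi & !.data$low_vitd ~ 0L,
      !.data$high_bmi & .data$low_vitd ~ 1L,
      .data$high_bmi & !.data$low_vitd ~ 2L,
      .data$high_bmi & .data$low_vitd ~ 3L
    )
  )
}

covariate_design <- function(cohort, covariates) {
  if (length(covariates) == 0L) {
    return(matrix(numeric(0), nrow = nrow(cohort), ncol = 0L))
  }
  missing_cov <- setdiff(covariates, names(cohort))
  if (length(missing_cov) > 0L) {
    abort(sprintf("Covariate(s) not in cohort: %s",
                  paste(missing_cov, collapse = ", ")))
  }
  df <- as.data.frame(cohort[, covariates, drop = FALSE])
  # categorical batch enters as one-hot with the first level dropped
  for (cl in names(df)) {
    if (is.character(df[[cl]]) || is.factor(df[[cl]])) {
      df[[cl]] <- factor(df[[cl]])
    }
  }
  mm <- model.matrix(reformulate(covariates), data = df)
  mm[, setdiff(colnames(mm), "(Intercept)"), drop = FALSE]
}

obs_report <- function(type, estimates, reri, fit, n,
                       additive = NULL, single = NULL, counts = NULL,
                       reri_unadjusted = NULL, covariates = NULL) {
  structure(
    list(type = type, estimates = estimates, additive = additive,
         single = single, counts = counts, reri = reri,
         reri_unadjusted = reri_unadjusted, fit = fit, n = n,
         covariates = covariates),
    class = "obs_report"
  )
}

#' @export
print.obs_report <- function(x, ...) {
  cat(sprintf("<obs_report> %s observational analysis, n = %d\n", x$type, x$n))
  print(x$estimates)
  if (!is.null(x$additive)) {
    cat(sprintf("Additive term exp(b1+b2+b3) = %.4f (95%% CI %.4f to %.4f)\n",
                x$additive$or, x$additive$ci_low, x$additive$ci_high))
  }
  print(x$reri)
  invisible(x)
}

#' @method tidy obs_report
#' @export
tidy.obs_report <- function(x, ...) {
  out <- x$estimates
  if (!is.null(x$additive)) {
    out <- dplyr::bind_rows(out, tibble(
      term = "additive_term", or = x$additive$or,
      ci_low = x$additive$ci_low, ci_high = x$additive$ci_high,
      adjusted = TRUE
    ))
  }
  dplyr::bind_rows(out, tibble(
    term = "RERI", or = NA_real_, estimate = x$reri$estimate,
    ci_low = x$reri$ci_low, ci_high = x$reri$ci_high,
    adjusted = TRUE
  ))
}

# joint OR of both exposures with delta CI on the sum of the three
# coefficients: SE^2 = 1' Sigma 1 over the 3x3 covariance block
additive_term_ci <- function(fit, terms) {
  b <- fit$coefficients[terms]
  Sigma <- fit$vcov[terms, terms]
  s <- sum(b)
  se <- sqrt(sum(Sigma))
  list(or = exp(s), ci_low = exp(s - Z95 * se), ci_high = exp(s + Z95 * se))
}

#' Continuous observational interaction analysis
#'
#' Logistic model of psoriasis on measured 25(OH)D coded per 10 nmol/l
#' *decrease* (predictor `-vitd_adj / 10`, so the coefficient is directly
#' risk-increasing), measured BMI per 5 kg/m^2 increase (`bmi / 5`), their
#' cross-product, and the adjustment covariates (default age and sex).
#' Reports the component ORs, the cross-product OR, the additive term
#' `exp(b1 + b2 + b3)` with delta CI, and the RERI at the (+1, +1)
#' risk-increasing contrast. Complete-case on all model variables.
#'
#' @param cohort Cohort tibble (season adjustment is applied if `vitd_adj`
#'   is absent).
#' @param covariates Adjustment covariates (default `c("age", "sex")`).
#' @param ci_method,n_boot,seed Passed to [reri_from_fit()].
#' @return An `obs_report` (type `"continuous"`).
#' @export
run_observational_continuous <- function(cohort, covariates = c("age", "sex"),
                                         ci_method = c("delta", "bootstrap"),
                                         n_boot = 2000L, seed = NULL) {
  ci_method <- match.arg(ci_method)
  if (!"vitd_adj" %in% names(cohort)) {
    cohort <- add_season_adjusted(cohort)
  }
  use <- as_tibble(cohort)
  keep <- complete.cases(use[, c("vitd_adj", "bmi", "psoriasis", covariates)])
  use <- use[keep, , drop = FALSE]
  x_vd <- -use$vitd_adj / 10
  x_bmi <- use$bmi / 5
  X <- cbind(
    `(Intercept)` = 1,
    vitd_per10_decrease = x_vd,
    bmi_per5_increase = x_bmi,
    cross_product = x_vd * x_bmi,
    covariate_design(use, covariates)
  )
  fit <- fit_logistic(X, use$psoriasis)
  trm <- c("vitd_per10_decrease", "bmi_per5_increase", "cross_product")
  td <- tidy(fit, exponentiate = TRUE)
  est <- td[match(trm, td$term), c("term", "estimate", "conf.low", "conf.high")]
  names(est) <- c("term", "or", "ci_low", "ci_high")
  est$adjusted <- TRUE
  reri <- reri_from_fit(fit, trm, type = "continuous", contrast = c(1, 1),
                        method = ci_method, n_boot = n_boot, seed = seed)
  obs_report(
    "continuous", est, reri, fit, n = fit$n,
    additive = additive_term_ci(fit, trm), covariates = covariates
  )
}

#' 2x2 observational interaction analysis
#'
#' The dichotomized cross-sectional design: exposure groups from
#' [dichotomize_exposures()], complete-case on both measured exposures and
#' the covariates. The unadjusted column comes from the saturated
#' group-indicator logistic fit, whose ORs equal the closed-form 2x2
#' cross-product ratios exactly; the adjusted column adds the covariates
#' (default age and sex). Both columns carry a RERI with CI, and the report
#' also includes the two single (marginal) associations of each exposure
#' against its own reference.
#'
#' @inheritParams run_observational_continuous
#' @return An `obs_report` (type `"2x2"`) with `estimates` (combined-group
#'   ORs, unadjusted and adjusted), `single` (marginal associations),
#'   `counts`, `reri` (adjusted) and `reri_unadjusted`.
#' @export
run_observational_2x2 <- function(cohort, covariates = c("age", "sex"),
                                  ci_method = c("delta", "bootstrap"),
                                  n_boot = 2000L, seed = NULL) {
  ci_method <- match.arg(ci_method)
  use <- dichotomize_exposures(cohort)
  keep <- complete.cases(use[, c("obs_group", "psoriasis", covariates)])
  use <- use[keep, , drop = FALSE]

  counts <- use |>
    dplyr::count(.data$obs_group, .data$psoriasis) |>
    tidyr::pivot_wider(names_from = "psoriasis", values_from = "n",
                       names_prefix = "y", values_fill = 0L) |>
    dplyr::arrange(.data$obs_group)
  if (nrow(counts) < 4L || any(counts$y0 == 0L) || any(counts$y1 == 0L)) {
    abort("Empty cell in the observational 2x2 table.")
  }

  ind <- function(g) as.numeric(use$obs_group == g)
  X0 <- cbind(`(Intercept)` = 1, group1 = ind(1L), group2 = ind(2L),
              group3 = ind(3L))
  fit_unadj <- fit_logistic(X0, use$psoriasis)
  Xa <- cbind(X0, covariate_design(use, covariates))
  fit_adj <- fit_logistic(Xa, use$psoriasis)
  trm <- c("group1", "group2", "group3")

  or_block <- function(fit, adjusted) {
    td <- tidy(fit, exponentiate = TRUE)
    out <- td[match(trm, td$term), c("term", "estimate", "conf.low", "conf.high")]
    names(out) <- c("term", "or", "ci_low", "ci_high")
    dplyr::bind_rows(
      tibble(term = "group0", or = 1, ci_low = NA_real_, ci_high = NA_real_),
      out
    ) |>
      dplyr::mutate(adjusted = adjusted)
  }
  estimates <- dplyr::bind_rows(or_block(fit_unadj, FALSE),
                                or_block(fit_adj, TRUE))

  single_block <- function(exposed, label) {
    a <- sum(use$psoriasis == 1 & exposed)
    b <- sum(use$psoriasis == 0 & exposed)
    cc <- sum(use$psoriasis == 1 & !exposed)
    d <- sum(use$psoriasis == 0 & !exposed)
    unadj <- odds_ratio_2x2(a, b, cc, d)
    Xs <- cbind(`(Intercept)` = 1, exposed = as.numeric(exposed),
                covariate_design(use, covariates))
    fs <- tidy(fit_logistic(Xs, use$psoriasis), exponentiate = TRUE)
    fs <- fs[fs$term == "exposed", ]
    tibble(
      exposure = label,
      cases = a, noncases = b,
      or_unadjusted = unadj$or, ci_low_unadjusted = unadj$ci_low,
      ci_high_unadjusted = unadj$ci_high,
      or_adjusted = fs$estimate, ci_low_adjusted = fs$conf.low,
      ci_high_adjusted = fs$conf.high
    )
  }
  single <- dplyr::bind_rows(
    single_block(use$low_vitd, "25(OH)D < 25 nmol/l"),
    single_block(use$high_bmi, "BMI > 27.5 kg/m^2")
  )

  reri_unadj <- reri_from_fit(fit_unadj, trm, type = "2x2",
                              method = ci_method, n_boot = n_boot, seed = seed)
  reri_adj <- reri_from_fit(fit_adj, trm, type = "2x2",
                            method = ci_method, n_boot = n_boot, seed = seed)
  obs_report(
    "2x2", estimates, reri_adj, fit_adj, n = fit_adj$n,
    single = single, counts = counts, reri_unadjusted = reri_unadj,
    covariates = covariates
  )
}
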