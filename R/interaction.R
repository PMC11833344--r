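# Additive-interaction machinery: odds ratios from 2x2 tables, the relative
# excess risk due to interaction (RERI = OR11 - OR10 - OR01 + 1), delta-method
# and bootstrap confidence intervals, the all-ORs-above-1 validity rule, the
# additive term exp(b1 + b2 + b3), and fixed-effect meta-analysis of RERI
# across cohorts.

#' Odds ratio from a 2x2 table with Woolf confidence interval
#'
#' `OR = (a d) / (c b)` with `a` = exposed cases, `b` = exposed non-cases,
#' `c` = reference cases, `d` = reference non-cases;
#' `SE(log OR) = sqrt(1/a + 1/b + 1/c + 1/d)` and the 95% CI is
#' `exp(log OR +/- 1.96 SE)`. No continuity correction is applied: a zero
#' cell is an error (the tables this targets have large cells).
#'
#' @param cases_exposed,noncases_exposed,cases_ref,noncases_ref Cell counts.
#' @return One-row tibble of class `odds_ratio`: `or`, `log_or`, `se_log_or`,
#'   `ci_low`, `ci_high`.
#' @examples
#' odds_ratio_2x2(435, 11666, 10669, 339125) # rounds to 1.19
#' @export
odds_ratio_2x2 <- function(cases_exposed, noncases_exposed,
                           cases_ref, noncases_ref) {
  cells <- c(a = cases_exposed, b = noncases_exposed,
             c = cases_ref, d = noncases_ref)
  if (any(!is.finite(cells)) || any(cells < 0)) {
    abort("All cell counts must be finite and non-negative.")
  }
  if (any(cells == 0)) {
    abort("Zero cell in the 2x2 table; the Woolf odds ratio is undefined (continuity corrections are out of scope).")
  }
  log_or <- log(cells[["a"]]) + log(cells[["d"]]) -
    log(cells[["c"]]) - log(cells[["b"]])
  se <- sqrt(sum(1 / cells))
  out <- tibble(
    or = exp(log_or), log_or = log_or, se_log_or = se,
    ci_low = exp(log_or - Z95 * se), ci_high = exp(log_or + Z95 * se)
  )
  class(out) <- c("odds_ratio", class(out))
  out
}

#' RERI from three component odds ratios
#'
#' `RERI = OR11 - OR10 - OR01 + 1`, where OR11 is the doubly-exposed group's
#' odds ratio and OR10/OR01 the singly-exposed ones, all against the
#' doubly-unexposed reference. Zero indicates exact additivity of the two
#' exposures' effects on the odds scale; positive values super-additive
#' interaction.
#'
#' @param or11,or10,or01 Positive odds ratios against the common reference.
#' @return The RERI point estimate (a bare number).
#' @examples
#' reri_from_ors(2.0, 1.5, 1.3) # 0.2
#' @export
reri_from_ors <- function(or11, or10, or01) {
  for (nm in c("or11", "or10", "or01")) {
    v <- get(nm)
    check_scalar_number(v, nm)
    if (v <= 0) abort(sprintf("`%s` must be positive.", nm))
  }
  or11 - or10 - or01 + 1
}

#' Additive term of a logistic interaction model
#'
#' `exp(b1 + b2 + b3)`: the joint odds ratio of both exposures including the
#' cross-product coefficient, equal to the product of the three component
#' odds ratios.
#'
#' @param b1,b2,b3 Coefficients on the log-odds scale.
#' @return `exp(b1 + b2 + b3)`.
#' @examples
#' additive_term(log(1.03), log(1.18), log(1.00)) # 1.2154
#' @export
additive_term <- function(b1, b2, b3) {
  for (nm in c("b1", "b2", "b3")) check_scalar_number(get(nm), nm)
  exp(b1 + b2 + b3)
}

#' RERI validity rule
#'
#' A RERI estimate is considered valid when all three component odds ratios
#' are strictly above 1; otherwise downstream reports must flag it as
#' "interpret with caution".
#'
#' @param component_ors Numeric vector of the three component odds ratios.
#' @return `TRUE` iff all are strictly greater than 1.
#' @export
check_validity <- function(component_ors) {
  if (any(!is.finite(component_ors)) || any(component_ors <= 0)) {
    abort("component_ors must be positive.")
  }
  all(component_ors > 1)
}

new_reri_result <- function(estimate, se, ci_low, ci_high, method,
                            component_ors, contrast = NULL, n = NA_integer_) {
  structure(
    list(
      estimate = estimate, se = se, ci_low = ci_low, ci_high = ci_high,
      method = method, valid = check_validity(component_ors),
      component_ors = component_ors, contrast = contrast, n = n
    ),
    class = "reri_result"
  )
}

#' @export
print.reri_result <- function(x, ...) {
  cat(sprintf("RERI = %.4f (95%% CI %.4f to %.4f), %s method%s\n",
              x$estimate, x$ci_low, x$ci_high, x$method,
              if (x$valid) "" else " [not all component ORs > 1: interpret with caution]"))
  cat(sprintf("component ORs: OR01 = %.4f, OR10 = %.4f, OR11 = %.4f\n",
              x$component_ors[["or01"]], x$component_ors[["or10"]],
              x$component_ors[["or11"]]))
  invisible(x)
}

#' @method tidy reri_result
#' @export
tidy.reri_result <- function(x, ...) {
  tibble(
    term = "RERI", estimate = x$estimate, std.error = x$se,
    conf.low = x$ci_low, conf.high = x$ci_high,
    method = x$method, valid = x$valid
  )
}

# Point estimate, gradient and component ORs of the RERI expression for a
# coefficient triple. For the 2x2 design the three coefficients are the three
# factorial-group indicators (b = (b_g1, b_g2, b_g3)); for the continuous
# design they are the two risk-increasing scores and their cross-product,
# evaluated at the (c1, c2) contrast (default +1 SD, +1 SD).
reri_value <- function(b, type, contrast = c(1, 1)) {
  if (type == "2x2") {
    e <- unname(exp(b))
    list(
      estimate = e[3L] - e[2L] - e[1L] + 1,
      gradient = c(-e[1L], -e[2L], e[3L]),
      component_ors = c(or01 = unname(e[1L]), or10 = unname(e[2L]),
                        or11 = unname(e[3L]))
    )
  } else {
    c1 <- contrast[1L]
    c2 <- contrast[2L]
    b <- unname(b)
    e11 <- exp(c1 * b[1L] + c2 * b[2L] + c1 * c2 * b[3L])
    e10 <- exp(c1 * b[1L])
    e01 <- exp(c2 * b[2L])
    list(
      estimate = e11 - e10 - e01 + 1,
      gradient = c(c1 * (e11 - e10), c2 * (e11 - e01), c1 * c2 * e11),
      component_ors = c(or01 = unname(e01), or10 = unname(e10),
                        or11 = unname(e11))
    )
  }
}

#' RERI from a fitted logistic model
#'
#' Computes the relative excess risk due to interaction from three named
#' coefficients of a [fit_logistic()] fit. For the 2x2 factorial design
#' (`type = "2x2"`) the terms are the three factorial-group indicator
#' coefficients (groups 1, 2 and 3 against the reference group 0) and
#' `RERI = exp(b_g3) - exp(b_g2) - exp(b_g1) + 1`. For the continuous design
#' (`type = "continuous"`) the terms are the two exposure scores in
#' risk-increasing orientation and their cross-product, and the RERI is
#' evaluated at the `contrast = c(1, 1)` unit contrast:
#' `exp(c1 b1 + c2 b2 + c1 c2 b3) - exp(c1 b1) - exp(c2 b2) + 1`.
#'
#' The default CI is the delta method: `SE^2 = g' Sigma g` with `g` the
#' gradient of the RERI expression and `Sigma` the corresponding covariance
#' sub-matrix; the 95% interval is `estimate +/- 1.96 SE`. With
#' `method = "bootstrap"` individuals are resampled with replacement
#' `n_boot` times, the model refitted, and the percentile interval reported
#' (the fit must have been created with `keep_data = TRUE`).
#'
#' @param fit A `logit_fit`.
#' @param terms Character(3): coefficient names, ordered (group1, group2,
#'   group3) for `"2x2"` or (exposure 1, exposure 2, cross-product) for
#'   `"continuous"`.
#' @param type `"2x2"` or `"continuous"`.
#' @param contrast Length-2 contrast for the continuous design (units of the
#'   two exposure terms).
#' @param method `"delta"` or `"bootstrap"`.
#' @param n_boot Bootstrap replicates (a warning is raised below 200).
#' @param seed Optional seed for the bootstrap (caller's RNG state is
#'   restored afterwards).
#' @return A `reri_result`: estimate, SE, 95% CI, method tag, component odds
#'   ratios and the all-ORs-above-1 validity flag.
#' @export
reri_from_fit <- function(fit, terms, type = c("2x2", "continuous"),
                          contrast = c(1, 1),
                          method = c("delta", "bootstrap"),
                          n_boot = 2000L, seed = NULL) {
  stopifnot(inherits(fit, "logit_fit"))
  type <- match.arg(type)
  method <- match.arg(method)
  if (length(terms) != 3L) abort("`terms` must name exactly 3 coefficients.")
  missing_terms <- setdiff(terms, fit$terms)
  if (length(missing_terms) > 0L) {
    abort(sprintf("Term(s) not in fit: %s", paste(missing_terms, collapse = ", ")))
  }
  b <- fit$coefficients[terms]
  rv <- reri_value(b, type, contrast)
  if (any(!is.finite(rv$gradient))) abort("Non-finite RERI gradient.")

  if (method == "delta") {
    Sigma <- fit$vcov[terms, terms]
    se <- sqrt(drop(crossprod(rv$gradient, Sigma %*% rv$gradient)))
    return(new_reri_result(
      rv$estimate, se, rv$estimate - Z95 * se, rv$estimate + Z95 * se,
      method = "delta", component_ors = rv$component_ors,
      contrast = if (type == "continuous") contrast else NULL, n = fit$n
    ))
  }

  if (is.null(fit$X)) {
    abort("Bootstrap needs the fit's data; refit with keep_data = TRUE.")
  }
  if (n_boot < 200L) {
    warn(sprintf("n_boot = %d is small; percentile CIs below 200 replicates are unstable.", n_boot))
  }
  local_seed(seed)
  n <- fit$n
  boot <- vapply(seq_len(n_boot), function(i) {
    idx <- sample.int(n, n, replace = TRUE)
    bf <- tryCatch(
      fit_logistic(fit$X[idx, , drop = FALSE], fit$y[idx], keep_data = FALSE),
      error = function(e) NULL
    )
    if (is.null(bf)) return(NA_real_)
    reri_value(bf$coefficients[terms], type, contrast)$estimate
  }, numeric(1))
  boot <- boot[is.finite(boot)]
  if (length(boot) < n_boot * 0.5) {
    abort("More than half of the bootstrap refits failed.")
  }
  ci <- unname(quantile(boot, c(0.025, 0.975)))
  new_reri_result(
    rv$estimate, sd(boot), ci[1L], ci[2L],
    method = "bootstrap", component_ors = rv$component_ors,
    contrast = if (type == "continuous") contrast else NULL, n = fit$n
  )
}

#' Fixed-effect (inverse-variance) meta-analysis of RERI estimates
#'
#' Pools per-cohort RERI point estimates with weights proportional to
#' `1/se^2`; the pooled SE is `sqrt(1 / sum(1/se^2))` and the 95% CI is Wald.
#'
#' @param estimates Numeric vector of study point estimates (length >= 2).
#' @param ses Matching vector of positive standard errors.
#' @param labels Optional study labels.
#' @return A `meta_result`: pooled estimate, SE, 95% CI and normalized
#'   per-study weights. Supports [tidy()] and [autoplot()].
#' @export
meta_fixed <- function(estimates, ses, labels = NULL) {
  if (length(estimates) != length(ses)) {
    abort("estimates and ses must have the same length.")
  }
  if (length(estimates) < 2L) abort("Need at least 2 studies to pool.")
  if (any(!is.finite(ses)) || any(ses <= 0)) abort("All ses must be positive.")
  labels <- labels %||% paste0("study", seq_along(estimates))
  w <- 1 / ses^2
  pooled <- sum(w * estimates) / sum(w)
  se <- sqrt(1 / sum(w))
  structure(
    list(
      estimate = pooled, se = se,
      ci_low = pooled - Z95 * se, ci_high = pooled + Z95 * se,
      weights = setNames(w / sum(w), labels),
      studies = tibble(study = labels, estimate = estimates, se = ses)
    ),
    class = "meta_result"
  )
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("Fixed-effect pooled estimate = %.4f (95%% CI %.4f to %.4f), k = %d\n",
              x$estimate, x$ci_low, x$ci_high, nrow(x$studies)))
  invisible(x)
}

#' @method tidy meta_result
#' @export
tidy.meta_result <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$studies,
                  conf.low = .data$estimate - Z95 * .data$se,
                  conf.high = .data$estimate + Z95 * .data$se,
                  weight = unname(x$weights)),
    tibble(study = "pooled", estimate = x$estimate, se = x$se,
           conf.low = x$ci_low, conf.high = x$ci_high, weight = 1)
  )
}
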