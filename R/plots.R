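# ggplot2 visualisations of the result objects: forest-style OR plots for
# the factorial and observational reports and a forest plot for the RERI
# meta-analysis.

forest_or_plot <- function(d, title, subtitle = NULL) {
  d$term <- factor(d$term, levels = rev(d$term))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$or, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
      height = 0.15, na.rm = TRUE
    ) +
    ggplot2::geom_point(size = 2, na.rm = TRUE) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Odds ratio (95% CI, log scale)", y = NULL,
                  title = title, subtitle = subtitle) +
    ggplot2::theme_minimal()
}

#' Forest plot of a factorial MR report
#'
#' Per-group (2x2) or per-term (continuous) odds ratios with 95% CIs on a
#' log scale; the RERI estimate is shown in the subtitle with its validity
#' annotation.
#'
#' @param object A `factorial_mr` report.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot factorial_mr
#' @export
autoplot.factorial_mr <- function(object, ...) {
  d <- object$estimates
  sub <- sprintf("RERI = %.3f (95%% CI %.3f to %.3f)%s",
                 object$reri$estimate, object$reri$ci_low,
                 object$reri$ci_high,
                 if (object$reri$valid) "" else " — interpret with caution")
  forest_or_plot(
    d, sprintf("%s factorial MR%s", object$type,
               if (object$scaled) " (phenotype units)" else ""), sub
  )
}

#' Forest plot of an observational interaction report
#'
#' @param object An `obs_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot obs_report
#' @export
autoplot.obs_report <- function(object, ...) {
  d <- object$estimates
  if ("adjusted" %in% names(d)) {
    d <- d[d$adjusted, , drop = FALSE]
  }
  sub <- sprintf("RERI = %.3f (95%% CI %.3f to %.3f)",
                 object$reri$estimate, object$reri$ci_low, object$reri$ci_high)
  forest_or_plot(d, sprintf("%s observational analysis", object$type), sub)
}

#' Forest plot of a RERI meta-analysis
#'
#' @param object A `meta_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot meta_result
#' @export
autoplot.meta_result <- function(object, ...) {
  d <- tidy(object)
  d$study <- factor(d$study, levels = rev(d$study))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$study)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high),
      height = 0.15
    ) +
    ggplot2::geom_point(ggplot2::aes(size = .data$weight),
                        show.legend = FALSE) +
    ggplot2::labs(x = "RERI (95% CI)", y = NULL,
                  title = "Fixed-effect meta-analysis of RERI") +
    ggplot2::theme_minimal()
}

#' Plot instrument diagnostics
#'
#' Per-dependent-variable regression coefficients of trait and candidate
#' confounders on the standardized score, with 95% CIs.
#'
#' @param object An `instrument_diag` tibble from [run_diagnostics()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot instrument_diag
#' @export
autoplot.instrument_diag <- function(object, ...) {
  d <- as_tibble(object)
  d$dependent <- factor(d$dependent, levels = rev(d$dependent))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$beta_per_sd, y = .data$dependent,
                                  colour = .data$role)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.15
    ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Coefficient per 1 SD of score", y = NULL,
                  title = sprintf("Instrument diagnostics (%s score)",
                                  attr(object, "trait") %||% "")) +
    ggplot2::theme_minimal()
}
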