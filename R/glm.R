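# Logistic and univariable linear fits: the numeric substrate of every
# analysis stage. Logistic models are fitted by iteratively reweighted least
# squares (Newton scoring with step-halving, so the log-likelihood is
# non-decreasing across iterations); the coefficient covariance is the inverse
# observed information, which for the canonical-link logistic equals the
# expected information and is exactly what the delta-method RERI needs.

logistic_loglik <- function(X, y, b) {
  eta <- drop(X %*% b)
  # log(1 + exp(eta)) computed stably for large |eta|
  lse <- ifelse(eta > 30, eta, log1p(exp(eta)))
  sum(y * eta - lse)
}

#' Fit a logistic regression by IRLS
#'
#' Maximum-likelihood logistic regression on an explicit design matrix
#' (including the intercept column). Convergence is declared when the largest
#' coefficient change drops below `tol` (default 1e-8) within `max_iter`
#' iterations; step-halving guarantees the log-likelihood never decreases.
#' Rows with any missing value are dropped (complete-case). Errors are raised
#' for a rank-deficient design, a degenerate outcome, apparent separation
#' (any coefficient exceeding 15 on the logit scale), or non-convergence (the
#' error message carries the log-likelihood trace).
#'
#' @param design Numeric matrix (or data frame) of predictors, one column per
#'   term, including an intercept column of ones.
#' @param outcome 0/1 vector.
#' @param tol Convergence tolerance on the max absolute coefficient change.
#' @param max_iter Maximum IRLS iterations.
#' @param keep_data Retain the (complete-case) design and outcome in the fit,
#'   enabling bootstrap resampling in [reri_from_fit()].
#' @return A `logit_fit` object: coefficients, covariance matrix (inverse
#'   observed information), `n`, iteration count, log-likelihood and its
#'   per-iteration trace. Supports [tidy()], [glance()] and `print()`.
#' @examples
#' x <- cbind(`(Intercept)` = 1)
#' f <- fit_logistic(x[rep(1, 100), , drop = FALSE], rep(c(0, 1), c(75, 25)))
#' coef(f)[1] # logit(0.25)
#' @export
fit_logistic <- function(design, outcome, tol = 1e-8, max_iter = 100L,
                         keep_data = TRUE) {
  X <- as.matrix(design)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- as.numeric(outcome)
  if (length(y) != nrow(X)) abort("design and outcome lengths differ.")
  keep <- complete.cases(X) & !is.na(y)
  X <- X[keep, , drop = FALSE]
  y <- y[keep]
  if (!is_binary01(y)) abort("outcome must be coded 0/1.")
  n <- length(y)
  p <- ncol(X)
  if (n <= p) abort("Fewer observations than model terms.")
  if (length(unique(y)) < 2L) {
    abort(sprintf(
      "Degenerate outcome: all %d observations equal %d; the likelihood has no interior maximum (complete separation).",
      n, as.integer(y[1L])
    ))
  }
  if (qr(X)$rank < p) abort("Design matrix is rank deficient.")

  b <- numeric(p)
  icpt <- which(apply(X, 2L, function(cl) all(cl == 1)))
  if (length(icpt) > 0L) b[icpt[1L]] <- qlogis(mean(y))
  ll <- logistic_loglik(X, y, b)
  trace <- ll
  converged <- FALSE
  iterations <- 0L
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% b)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    XtWX <- crossprod(X * w, X)
    delta <- tryCatch(
      solve(XtWX, crossprod(X, y - mu)),
      error = function(e) abort("Information matrix is numerically singular.")
    )
    step <- 1
    b_new <- b + drop(delta)
    ll_new <- logistic_loglik(X, y, b_new)
    halvings <- 0L
    while ((!is.finite(ll_new) || ll_new < ll) && halvings < 30L) {
      step <- step / 2
      b_new <- b + step * drop(delta)
      ll_new <- logistic_loglik(X, y, b_new)
      halvings <- halvings + 1L
    }
    moved <- max(abs(b_new - b))
    b <- b_new
    ll <- ll_new
    trace <- c(trace, ll)
    iterations <- it
    if (max(abs(b)) > 15) {
      abort(paste0(
        "Apparent separation: a coefficient exceeded 15 on the logit scale (max |b| = ",
        format(max(abs(b)), digits = 4), ")."
      ))
    }
    if (moved < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    abort(sprintf(
      "IRLS did not converge in %d iterations; log-likelihood trace: %s",
      max_iter, paste(format(trace, digits = 10), collapse = " -> ")
    ))
  }
  eta <- drop(X %*% b)
  mu <- plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-12)
  V <- solve(crossprod(X * w, X))
  dimnames(V) <- list(colnames(X), colnames(X))
  structure(
    list(
      coefficients = setNames(drop(b), colnames(X)),
      vcov = V,
      n = n,
      converged = TRUE,
      iterations = iterations,
      loglik = ll,
      loglik_trace = trace,
      terms = colnames(X),
      X = if (keep_data) X else NULL,
      y = if (keep_data) y else NULL
    ),
    class = "logit_fit"
  )
}

#' @export
coef.logit_fit <- function(object, ...) object$coefficients

#' @export
vcov.logit_fit <- function(object, ...) object$vcov

#' @export
logLik.logit_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            nobs = object$n, class = "logLik")
}

#' @export
print.logit_fit <- function(x, ...) {
  cat(sprintf("<logit_fit> n = %d, %d terms, logLik = %.3f (%d IRLS iterations)\n",
              x$n, length(x$coefficients), x$loglik, x$iterations))
  print(tidy(x), ...)
  invisible(x)
}

#' Tidy a logistic fit
#'
#' @param x A `logit_fit`.
#' @param conf.level Confidence level (Wald, 1.96-for-95% convention).
#' @param exponentiate Report odds ratios instead of log-odds coefficients?
#' @param ... Unused.
#' @return A tibble with one row per model term.
#' @method tidy logit_fit
#' @export
tidy.logit_fit <- function(x, conf.level = 0.95, exponentiate = FALSE, ...) {
  est <- x$coefficients
  se <- sqrt(diag(x$vcov))
  z <- if (isTRUE(all.equal(conf.level, 0.95))) Z95 else qnorm(1 - (1 - conf.level) / 2)
  out <- tibble(
    term = x$terms,
    estimate = unname(est),
    std.error = unname(se),
    statistic = unname(est / se),
    p.value = 2 * pnorm(-abs(unname(est / se))),
    conf.low = unname(est - z * se),
    conf.high = unname(est + z * se)
  )
  if (exponentiate) {
    out$estimate <- exp(out$estimate)
    out$conf.low <- exp(out$conf.low)
    out$conf.high <- exp(out$conf.high)
  }
  out
}

#' @method glance logit_fit
#' @export
glance.logit_fit <- function(x, ...) {
  tibble(
    nobs = x$n, df = length(x$coefficients), logLik = x$loglik,
    iterations = x$iterations, converged = x$converged
  )
}

#' Univariable ordinary least squares fit
#'
#' Complete-case OLS of `y` on a single predictor `x`, reporting the slope
#' with a t-based 95% CI, `R^2` and the F statistic, which for a univariable
#' fit satisfies `F = (n - 2) R^2 / (1 - R^2)`. This is the instrument-
#' strength workhorse (trait regressed on a standardized PRS gives the
#' first-stage effect per 1 SD of score, with R^2/F quantifying instrument
#' strength) and also serves the PRS-confounder association tables.
#'
#' @param x Predictor vector.
#' @param y Response vector.
#' @return A `linear_fit` object (slope, intercept, `r.squared`, `fstat`,
#'   `n`, slope SE and CI) supporting [tidy()] and [glance()].
#' @export
fit_linear_univariable <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3L) abort("Need at least 3 complete observations.")
  sxx <- sum((x - mean(x))^2)
  if (sxx <= 0) abort("Predictor is constant; slope is undefined.")
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else 0
  fstat <- (n - 2) * r2 / (1 - r2)
  se <- sqrt(rss / (n - 2) / sxx)
  tq <- qt(0.975, df = n - 2)
  structure(
    list(
      slope = slope, intercept = intercept, r.squared = r2, fstat = fstat,
      n = n, se_slope = se,
      ci = c(lower = slope - tq * se, upper = slope + tq * se)
    ),
    class = "linear_fit"
  )
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf(
    "<linear_fit> n = %d, slope = %.4g (95%% CI %.4g to %.4g), R^2 = %.4g, F = %.4g\n",
    x$n, x$slope, x$ci[["lower"]], x$ci[["upper"]], x$r.squared, x$fstat
  ))
  invisible(x)
}

#' @method tidy linear_fit
#' @export
tidy.linear_fit <- function(x, ...) {
  tibble(
    term = c("(Intercept)", "x"),
    estimate = c(x$intercept, x$slope),
    std.error = c(NA_real_, x$se_slope),
    conf.low = c(NA_real_, x$ci[["lower"]]),
    conf.high = c(NA_real_, x$ci[["upper"]])
  )
}

#' @method glance linear_fit
#' @export
glance.linear_fit <- function(x, ...) {
  tibble(r.squared = x$r.squared, statistic = x$fstat, nobs = x$n)
}
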