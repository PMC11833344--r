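# Internal helpers shared across modules.

# Population standard deviation (divide by n, not n - 1). Standardized scores
# use this convention so that mean 0 / SD 1 holds exactly over the analysis
# sample (the +/- 1/n difference from the sample SD moves medians only at the
# 1e-6 scale, but the convention is fixed once here).
pop_sd <- function(x) {
  sqrt(mean((x - mean(x))^2))
}

is_binary01 <- function(x) {
  all(x %in% c(0, 1))
}

# Wald z for 95% intervals; 1.96 exactly, matching the reporting convention of
# the epidemiological tables this package reproduces.
Z95 <- 1.96

check_scalar_number <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x))) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  invisible(x)
}

# Restore the RNG state on exit when a local seed is requested, so seeded
# subroutines (bootstrap, simulation) do not perturb the caller's stream.
local_seed <- function(seed, env = parent.frame()) {
  if (is.null(seed)) {
    return(invisible(NULL))
  }
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    withr::defer(assign(".Random.seed", old, envir = globalenv()), envir = env)
  }
  set.seed(seed)
  invisible(seed)
}
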