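# End-to-end pipeline runner: simulate (or read) one or more cohorts, build
# the PRSs, run the 2x2 and continuous factorial MR, the observational
# analyses and instrument diagnostics, write report TSVs, and meta-analyse
# the per-cohort RERI estimates. This function is the surface behind the
# `factorial-mr` command-line wrapper shipped in exec/.

# YAML 1.1 resolves a bare `n` key to boolean FALSE; map it back, and accept
# the unambiguous alias `n_samples`.
fix_n_key <- function(x) {
  nm <- names(x)
  nm[nm %in% c("FALSE", "n_samples")] <- "n"
  names(x) <- nm
  x
}

pipeline_cohort_inputs <- function(entry, seed_i) {
  entry <- fix_n_key(entry)
  if (!is.null(entry$paths)) {
    p <- entry$paths
    wb <- read_weight_table(p$weights_bmi, trait = "BMI")
    wv <- read_weight_table(p$weights_vitd, trait = "25OHD")
    geno <- read_genotypes(p$genotypes)
    cohort <- read_cohort(p$cohort)
    bmi_prs <- standardize_prs(compute_prs(geno, wb))
    vitd_prs <- standardize_prs(compute_prs(geno, wv))
    list(cohort = cohort, bmi_prs = bmi_prs, vitd_prs = vitd_prs,
         truth = NULL)
  } else {
    cfg_args <- entry[intersect(names(entry), c("n", "preset"))]
    extra <- entry[setdiff(names(entry),
                           c("n", "preset", "seed", "name", "genotypes"))]
    cfg <- do.call(sim_config, c(cfg_args, extra, list(seed = seed_i)))
    sim <- generate_cohort(cfg, genotypes = isTRUE(entry$genotypes))
    list(cohort = sim$cohort, bmi_prs = sim$scores$bmi,
         vitd_prs = sim$scores$vitd, truth = sim$truth, sim = sim)
  }
}

#' Run the full factorial MR pipeline
#'
#' For each configured cohort (simulated via [generate_cohort()], or read
#' from weight/genotype/cohort files): compute and standardize the PRSs,
#' assign factorial groups, run the 2x2 and continuous factorial MR
#' analyses, the observational continuous and 2x2 analyses (when measured
#' 25(OH)D is available), and instrument diagnostics for both scores. With
#' two or more cohorts, the per-cohort 2x2 RERI estimates are pooled by
#' fixed-effect inverse-variance meta-analysis. Tidied report TSVs are
#' written under `out_dir` when given.
#'
#' @param config Path to a YAML file or an equivalent list. Keys: `seed`;
#'   `out_dir`; `covariates` (default [mr_covariates()]; `"none"` for
#'   unadjusted); `ci_method`; `n_boot`; `cohorts`, a list of entries each
#'   with a `name` and either simulation fields (`preset`, `n` — spell it
#'   `n_samples` in YAML, where a bare `n` key reads as a boolean —, any
#'   [sim_config()] override, `genotypes: true` to simulate dosage panels)
#'   or `paths` (`weights_bmi`, `weights_vitd`, `genotypes`, `cohort`).
#' @param out_dir Output directory for report TSVs (overrides the config
#'   key; `NULL` writes nothing).
#' @param seed Overrides the config seed. Cohort `i` uses `seed + i`.
#' @return A `pipeline_result`: per-cohort lists (`mr_2x2`,
#'   `mr_continuous`, `observational_continuous`, `observational_2x2`,
#'   `diagnostics`, `truth`) plus `meta` and the effective `seed`.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL, seed = NULL) {
  if (is.character(config)) {
    config <- yaml::read_yaml(config)
  }
  config <- fix_n_key(config)
  seed <- as.integer(seed %||% config$seed %||% 1L)
  out_dir <- out_dir %||% config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  covariates <- config$covariates %||% mr_covariates()
  if (identical(covariates, "none")) covariates <- NULL
  ci_method <- config$ci_method %||% "delta"
  n_boot <- config$n_boot %||% 2000L
  cohorts <- config$cohorts %||% list(
    list(name = "ukb_like", preset = "ukb", n = config$n %||% 10000L),
    list(name = "hunt_like", preset = "hunt", n = config$n %||% 10000L)
  )
  inform(sprintf("Pipeline seed: %d (%d cohort(s))", seed, length(cohorts)))

  emit <- function(name, label, x) {
    if (is.null(out_dir) || is.null(x)) return(invisible(NULL))
    readr::write_tsv(tidy(x), file.path(out_dir,
                                        paste0(name, "_", label, ".tsv")))
  }

  results <- purrr::imap(cohorts, function(entry, i) {
    name <- entry$name %||% paste0("cohort", i)
    inputs <- pipeline_cohort_inputs(entry, seed + i)
    cohort <- inputs$cohort
    has_vitd <- "vitd" %in% names(cohort) && any(!is.na(cohort$vitd))
    covs <- intersect(covariates, names(cohort))

    mr2 <- run_2x2_factorial(cohort, inputs$bmi_prs, inputs$vitd_prs,
                             covariates = covs, ci_method = ci_method,
                             n_boot = n_boot, seed = seed + i)
    mrc <- run_continuous_factorial(cohort, inputs$bmi_prs, inputs$vitd_prs,
                                    covariates = covs, ci_method = ci_method,
                                    n_boot = n_boot, seed = seed + i)
    obs_c <- if (has_vitd) run_observational_continuous(cohort) else NULL
    obs_2 <- if (has_vitd) run_observational_2x2(cohort) else NULL
    diag_bmi <- run_diagnostics(cohort, inputs$bmi_prs, "bmi")
    diag_vitd <- if (has_vitd) run_diagnostics(cohort, inputs$vitd_prs,
                                               "vitd") else NULL

    emit(name, "mr_2x2", mr2)
    emit(name, "mr_continuous", mrc)
    emit(name, "observational_continuous", obs_c)
    emit(name, "observational_2x2", obs_2)
    if (!is.null(out_dir)) {
      readr::write_tsv(as_tibble(diag_bmi),
                       file.path(out_dir, paste0(name, "_diagnostics_bmi.tsv")))
      if (!is.null(diag_vitd)) {
        readr::write_tsv(as_tibble(diag_vitd),
                         file.path(out_dir,
                                   paste0(name, "_diagnostics_vitd.tsv")))
      }
      if (!is.null(inputs$sim)) {
        write_cohort(cohort, file.path(out_dir, paste0(name, "_cohort.tsv")))
        if (!is.null(inputs$sim$weights)) {
          write_weight_table(
            inputs$sim$weights$bmi,
            file.path(out_dir, paste0(name, "_weights_bmi.tsv"))
          )
          write_weight_table(
            inputs$sim$weights$vitd,
            file.path(out_dir, paste0(name, "_weights_vitd.tsv"))
          )
        }
      }
    }
    list(name = name, mr_2x2 = mr2, mr_continuous = mrc,
         observational_continuous = obs_c, observational_2x2 = obs_2,
         diagnostics = list(bmi = diag_bmi, vitd = diag_vitd),
         truth = inputs$truth)
  })

  meta <- NULL
  if (length(results) >= 2L) {
    meta <- meta_fixed(
      purrr::map_dbl(results, ~ .x$mr_2x2$reri$estimate),
      purrr::map_dbl(results, ~ .x$mr_2x2$reri$se),
      labels = purrr::map_chr(results, "name")
    )
    if (!is.null(out_dir)) {
      readr::write_tsv(tidy(meta), file.path(out_dir, "meta_reri_2x2.tsv"))
    }
  }
  structure(
    list(cohorts = results, meta = meta, seed = seed, out_dir = out_dir),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d cohort(s), seed %d\n",
              length(x$cohorts), x$seed))
  for (r in x$cohorts) {
    cat(sprintf("  %s: 2x2 RERI %.4f (%.4f to %.4f)\n", r$name,
                r$mr_2x2$reri$estimate, r$mr_2x2$reri$ci_low,
                r$mr_2x2$reri$ci_high))
  }
  if (!is.null(x$meta)) print(x$meta)
  invisible(x)
}
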