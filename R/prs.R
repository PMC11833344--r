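# Polygenic risk score construction: weighted allele sums over a genotype
# dosage matrix, standardization (with the optional risk-direction flip used
# for the 25(OH)D score), and median dichotomization into the four factorial
# MR groups.

new_prs_tbl <- function(x, trait, n_requested, n_used, variants_used,
                        orientation = 1L) {
  x <- as_tibble(x)
  attr(x, "trait") <- trait
  attr(x, "n_variants_requested") <- as.integer(n_requested)
  attr(x, "n_variants_used") <- as.integer(n_used)
  attr(x, "variants_used") <- variants_used
  attr(x, "orientation") <- as.integer(orientation)
  class(x) <- unique(c("prs_tbl", class(x)))
  x
}

#' @export
print.prs_tbl <- function(x, ...) {
  cat(sprintf(
    "<prs_tbl> trait %s: %d samples, %d/%d variants used, orientation %+d\n",
    attr(x, "trait") %||% "?", nrow(x),
    attr(x, "n_variants_used"), attr(x, "n_variants_requested"),
    attr(x, "orientation")
  ))
  NextMethod()
}

#' Number of variants behind a PRS
#'
#' @param prs A `prs_tbl`.
#' @return Named integer vector with `requested` and `used` counts (e.g.
#'   941 requested / 940 used when one published variant is absent from the
#'   genotype data).
#' @export
prs_n_variants <- function(prs) {
  c(requested = attr(prs, "n_variants_requested"),
    used = attr(prs, "n_variants_used"))
}

#' Compute a polygenic risk score from dosages and weights
#'
#' The raw score of each sample is the weighted sum of effect-allele dosages,
#' `sum_j w_j d_j`. When a variant's counted allele in the genotype data is
#' the weight table's *other* allele, the dosage is flipped to `2 - d` before
#' weighting; when neither genotype allele matches the weight table's pair,
#' the variant is skipped with a warning. Weight-table variants absent from
#' the genotype matrix are skipped and reflected in the
#' `n_variants_used` attribute (retrievable via [prs_n_variants()]).
#' Missing individual dosages are mean-imputed per variant (the mean of the
#' non-missing dosages, i.e. twice the effect-allele frequency), keeping the
#' analysis sample size constant; imputed variants are listed in the
#' `imputed_variants` attribute.
#'
#' @param genotypes A `geno_matrix` from [read_genotypes()].
#' @param weights A `weight_tbl` from [read_weight_table()].
#' @return A `prs_tbl` tibble with columns `sample_id` and `raw`, plus
#'   metadata attributes (`trait`, `n_variants_requested`, `n_variants_used`,
#'   `variants_used`, `orientation`).
#' @export
compute_prs <- function(genotypes, weights) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  weights <- as_tibble(weights)
  present <- weights$variant_id %in% genotypes$alleles$variant_id
  if (!any(present)) {
    abort("No weight-table variants found in the genotype matrix.")
  }
  w <- weights[present, , drop = FALSE]
  al <- genotypes$alleles[match(w$variant_id, genotypes$alleles$variant_id), ]
  on_effect <- al$counted_allele == w$effect_allele &
    al$other_allele == w$other_allele
  on_other <- al$counted_allele == w$other_allele &
    al$other_allele == w$effect_allele
  mismatch <- !(on_effect | on_other)
  if (any(mismatch)) {
    warn(sprintf(
      "Skipping %d variant(s) whose genotype alleles match neither weight-table allele: %s",
      sum(mismatch), paste(head(w$variant_id[mismatch], 5L), collapse = ", ")
    ))
    w <- w[!mismatch, , drop = FALSE]
    on_other <- on_other[!mismatch]
  }
  if (nrow(w) == 0L) {
    abort("No allele-consistent overlapping variants between weights and genotypes.")
  }
  D <- genotypes$dosage[, w$variant_id, drop = FALSE]
  if (any(on_other)) {
    D[, on_other] <- 2 - D[, on_other]
  }
  imputed <- character(0)
  if (anyNA(D)) {
    na_cols <- which(colSums(is.na(D)) > 0L)
    imputed <- colnames(D)[na_cols]
    for (j in na_cols) {
      mj <- mean(D[, j], na.rm = TRUE)
      D[is.na(D[, j]), j] <- mj
    }
  }
  raw <- drop(D %*% w$weight)
  out <- new_prs_tbl(
    tibble(sample_id = rownames(genotypes$dosage), raw = unname(raw)),
    trait = attr(weights, "trait"),
    n_requested = sum(!duplicated(weights$variant_id)),
    n_used = nrow(w),
    variants_used = w$variant_id
  )
  attr(out, "imputed_variants") <- imputed
  out
}

#' Standardize a PRS (optionally flipping its direction)
#'
#' Centres the raw score and divides by its population SD (divide-by-n) over
#' the analysis sample, so the `standardized` column has mean 0 and SD 1
#' exactly. With `flip = TRUE` the standardized score is negated and the
#' orientation attribute set to -1, so that +1 unit means one SD *decrease*
#' in the genetically predicted trait — the risk-increasing orientation used
#' for the 25(OH)D score in continuous factorial models ("per 1 SD
#' decrease"). Flipping twice restores the original orientation.
#'
#' @param prs A `prs_tbl` (from [compute_prs()] or a previous call).
#' @param flip Negate the standardized score (toggle orientation)?
#' @return The `prs_tbl` with a `standardized` column and updated
#'   `orientation` attribute.
#' @export
standardize_prs <- function(prs, flip = FALSE) {
  stopifnot(inherits(prs, "prs_tbl"))
  base <- if ("standardized" %in% names(prs)) {
    prs$standardized
  } else {
    s <- pop_sd(prs$raw)
    if (s <= 0) abort("Cannot standardize a constant score (SD is zero).")
    (prs$raw - mean(prs$raw)) / s
  }
  orientation <- attr(prs, "orientation") %||% 1L
  if (flip) {
    base <- -base
    orientation <- -orientation
  }
  out <- prs
  out$standardized <- base
  attr(out, "orientation") <- as.integer(orientation)
  out
}

#' Assign the four factorial MR groups by median dichotomization
#'
#' Both scores are dichotomized at their median in the trait-increasing
#' orientation; values equal to or below the median count as "low". Groups
#' follow the factorial coding with the expected-lowest-risk cell as
#' reference: group 0 = BMI score low & vitamin D score high (reference),
#' group 1 = both low, group 2 = BMI high & vitamin D high,
#' group 3 = BMI high & vitamin D low (expected highest risk).
#'
#' @param bmi_prs `prs_tbl` for the BMI score.
#' @param vitd_prs `prs_tbl` for the 25(OH)D score, in trait-increasing
#'   orientation (an error is raised if it has been flipped, since medians
#'   must be taken on the trait scale).
#' @return Tibble with `sample_id` and integer `group` in 0..3.
#' @export
assign_factorial_groups <- function(bmi_prs, vitd_prs) {
  stopifnot(inherits(bmi_prs, "prs_tbl"), inherits(vitd_prs, "prs_tbl"))
  if ((attr(vitd_prs, "orientation") %||% 1L) != 1L) {
    abort("vitd_prs must be in trait-increasing (unflipped) orientation for median splitting.")
  }
  if (!setequal(bmi_prs$sample_id, vitd_prs$sample_id) ||
      nrow(bmi_prs) != nrow(vitd_prs)) {
    abort("bmi_prs and vitd_prs must cover the same samples.")
  }
  bmi_prs <- standardize_prs(bmi_prs)
  vitd_prs <- standardize_prs(vitd_prs)
  v <- vitd_prs$standardized[match(bmi_prs$sample_id, vitd_prs$sample_id)]
  b <- bmi_prs$standardized
  bmi_low <- b <= median(b)
  vitd_low <- v <= median(v)
  group <- dplyr::case_when(
    bmi_low & !vitd_low ~ 0L,
    bmi_low & vitd_low ~ 1L,
    !bmi_low & !vitd_low ~ 2L,
    TRUE ~ 3L
  )
  tibble(sample_id = bmi_prs$sample_id, group = group)
}
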