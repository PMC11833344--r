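# Readers and writers for the tabular inputs of a factorial MR analysis:
# per-variant weight tables, genotype dosage matrices (delimited or VCF), the
# cohort phenotype/covariate table, and result reports. Variant identity is
# matched by id string only (published rsID lists carry no coordinates).

guess_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}

read_table_guess <- function(path, delim = NULL) {
  delim <- delim %||% guess_delim(path)
  readr::read_delim(
    path,
    delim = delim, col_types = readr::cols(.default = readr::col_character()),
    na = c("", "NA"), progress = FALSE, show_col_types = FALSE
  )
}

match_column <- function(nms, candidates, what, path) {
  hit <- which(tolower(nms) %in% candidates)
  if (length(hit) == 0L) {
    abort(sprintf(
      "No %s column found in '%s' (looked for: %s).",
      what, path, paste(candidates, collapse = ", ")
    ))
  }
  hit[1L]
}

#' Read a PRS weight table
#'
#' Reads a delimited (TSV/CSV) table of per-variant weights defining one
#' polygenic risk score: variant id, effect allele, other allele and the
#' per-allele weight on the trait. Column names are matched case-insensitively
#' against the common aliases (`variant_id`/`rsid`/`snp`/`id`,
#' `effect_allele`/`ea`/`a1`, `other_allele`/`oa`/`a2`,
#' `weight`/`beta`/`effect_size`).
#'
#' @param path Path to a delimited file with a header row.
#' @param trait Optional trait label (e.g. `"BMI"`, `"25OHD"`) stored as an
#'   attribute and echoed in downstream reports.
#' @param delim Field delimiter; guessed from the header line when `NULL`.
#' @return A tibble of class `weight_tbl` with columns `variant_id`,
#'   `effect_allele`, `other_allele`, `weight`, row order preserved, and a
#'   `trait` attribute.
#' @examples
#' p <- tempfile(fileext = ".tsv")
#' writeLines(c(
#'   "variant_id\teffect_allele\tother_allele\tweight",
#'   "rs1\tA\tG\t0.1", "rs2\tC\tT\t-0.2"
#' ), p)
#' read_weight_table(p, trait = "BMI")
#' @export
read_weight_table <- function(path, trait = NULL, delim = NULL) {
  raw <- read_table_guess(path, delim)
  nms <- names(raw)
  idx <- c(
    id = match_column(nms, c("variant_id", "rsid", "snp", "id", "variant"),
                      "variant id", path),
    ea = match_column(nms, c("effect_allele", "ea", "a1"), "effect allele", path),
    oa = match_column(nms, c("other_allele", "oa", "a2"), "other allele", path),
    w  = match_column(nms, c("weight", "beta", "effect_size", "b"), "weight", path)
  )
  out <- tibble(
    variant_id    = raw[[idx[["id"]]]],
    effect_allele = toupper(raw[[idx[["ea"]]]]),
    other_allele  = toupper(raw[[idx[["oa"]]]]),
    weight_chr    = raw[[idx[["w"]]]]
  )
  w <- suppressWarnings(as.numeric(out$weight_chr))
  bad <- which(is.na(w) & !is.na(out$weight_chr))
  if (length(bad) > 0L) {
    abort(sprintf(
      "Non-numeric weight '%s' at row %d of '%s'.",
      out$weight_chr[bad[1L]], bad[1L], path
    ))
  }
  out$weight <- w
  out$weight_chr <- NULL
  new_weight_tbl(out, trait = trait)
}

new_weight_tbl <- function(x, trait = NULL) {
  x <- as_tibble(x)
  dup <- x$variant_id[duplicated(x$variant_id)]
  if (length(dup) > 0L) {
    abort(sprintf("Duplicated variant id(s) in weight table: %s",
                  paste(unique(dup), collapse = ", ")))
  }
  if (any(!is.finite(x$weight))) {
    abort("All weights must be finite.")
  }
  same <- x$effect_allele == x$other_allele
  if (any(same)) {
    abort(sprintf("effect_allele equals other_allele for: %s",
                  paste(x$variant_id[same], collapse = ", ")))
  }
  attr(x, "trait") <- trait
  class(x) <- c("weight_tbl", class(x))
  x
}

#' Write a PRS weight table
#'
#' @param x A `weight_tbl` (or data frame with the same columns).
#' @param path Output path; written as TSV.
#' @return `x`, invisibly.
#' @export
write_weight_table <- function(x, path) {
  readr::write_tsv(
    as_tibble(x)[, c("variant_id", "effect_allele", "other_allele", "weight")],
    path
  )
  invisible(x)
}

# ---- genotype matrix ---------------------------------------------------------

new_geno_matrix <- function(dosage, alleles) {
  stopifnot(is.matrix(dosage), nrow(alleles) == ncol(dosage))
  if (anyDuplicated(rownames(dosage))) abort("Duplicated sample ids.")
  if (anyDuplicated(colnames(dosage))) abort("Duplicated variant ids.")
  rng <- range(dosage, na.rm = TRUE)
  if (is.finite(rng[1L]) && (rng[1L] < -1e-6 || rng[2L] > 2 + 1e-6)) {
    abort(sprintf("Dosages must lie in [0, 2]; observed range [%g, %g].",
                  rng[1L], rng[2L]))
  }
  dosage[] <- pmin(pmax(dosage, 0), 2)
  structure(
    list(dosage = dosage, alleles = as_tibble(alleles)),
    class = "geno_matrix"
  )
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d samples x %d variants (%d missing dosages)\n",
              nrow(x$dosage), ncol(x$dosage), sum(is.na(x$dosage))))
  invisible(x)
}

#' Read a genotype dosage matrix
#'
#' Two encodings are supported. Delimited (`format = "delim"`): samples as
#' rows, first column the sample id, remaining column headers of the form
#' `variant_id|counted_allele|other_allele`, cells the dosage of the counted
#' allele in `[0, 2]` (missing allowed). VCF (`format = "vcf"`, v4.x via
#' \pkg{vcfR}): per-sample dosage from the `DS` FORMAT field when present,
#' otherwise the ALT-allele count from `GT`; the counted allele is ALT.
#' Multi-allelic VCF records are skipped with a warning.
#'
#' @param path Input path.
#' @param format `"auto"` (by file extension), `"delim"` or `"vcf"`.
#' @return A `geno_matrix`: a samples-by-variants dosage matrix plus an
#'   `alleles` tibble (`variant_id`, `counted_allele`, `other_allele`).
#' @export
read_genotypes <- function(path, format = c("auto", "delim", "vcf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "delim"
  }
  if (format == "vcf") read_genotypes_vcf(path) else read_genotypes_delim(path)
}

read_genotypes_delim <- function(path) {
  raw <- read_table_guess(path)
  if (ncol(raw) < 2L) abort("Genotype table needs a sample id column and at least one variant column.")
  sample_ids <- raw[[1L]]
  heads <- names(raw)[-1L]
  parts <- strsplit(heads, "|", fixed = TRUE)
  bad <- lengths(parts) != 3L
  if (any(bad)) {
    abort(sprintf(
      "Genotype column header(s) not of the form 'variant_id|counted|other': %s",
      paste(heads[bad], collapse = ", ")
    ))
  }
  alleles <- tibble(
    variant_id     = vapply(parts, `[[`, "", 1L),
    counted_allele = toupper(vapply(parts, `[[`, "", 2L)),
    other_allele   = toupper(vapply(parts, `[[`, "", 3L))
  )
  dos <- vapply(raw[-1L], function(col) suppressWarnings(as.numeric(col)),
                numeric(length(sample_ids)))
  dos <- matrix(dos, nrow = length(sample_ids),
                dimnames = list(sample_ids, alleles$variant_id))
  new_geno_matrix(dos, alleles)
}

read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  fix <- matrix(fix, ncol = 7L,
                dimnames = list(NULL, c("CHROM", "POS", "ID", "REF", "ALT",
                                        "QUAL", "FILTER")))
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    warn(sprintf("Skipping %d multi-allelic VCF record(s).", sum(multi)))
  }
  keep <- which(!multi)
  if (length(keep) == 0L) abort("No bi-allelic records in VCF.")
  ids <- fix[keep, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste(fix[keep, "CHROM"], fix[keep, "POS"],
                     fix[keep, "REF"], fix[keep, "ALT"], sep = ":")[noid]

  fmt_has <- function(key) {
    any(grepl(paste0("(^|:)", key, "(:|$)"), vcf@gt[, 1L]))
  }
  if (fmt_has("DS")) {
    ds <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
    dos_vm <- ds[keep, , drop = FALSE]
  } else {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    gt <- gt[keep, , drop = FALSE]
    count_alt <- function(g) {
      ifelse(is.na(g) | grepl("\\.", g),
             NA_real_,
             vapply(strsplit(g, "[/|]"), function(a) sum(a == "1"), 0))
    }
    dos_vm <- apply(gt, 2L, count_alt)
    dos_vm <- matrix(dos_vm, nrow = length(keep),
                     dimnames = list(NULL, colnames(gt)))
  }
  dos <- t(dos_vm)
  colnames(dos) <- ids
  alleles <- tibble(
    variant_id     = ids,
    counted_allele = toupper(fix[keep, "ALT"]),
    other_allele   = toupper(fix[keep, "REF"])
  )
  new_geno_matrix(dos, alleles)
}

#' Write a genotype dosage matrix as a delimited table
#'
#' Inverse of the delimited encoding accepted by [read_genotypes()].
#'
#' @param x A `geno_matrix`.
#' @param path Output path (TSV).
#' @return `x`, invisibly.
#' @export
write_genotypes <- function(x, path) {
  stopifnot(inherits(x, "geno_matrix"))
  heads <- paste(x$alleles$variant_id, x$alleles$counted_allele,
                 x$alleles$other_allele, sep = "|")
  out <- as_tibble(x$dosage, .name_repair = "minimal")
  names(out) <- heads
  out <- dplyr::bind_cols(tibble(sample_id = rownames(x$dosage)), out)
  readr::write_tsv(out, path)
  invisible(x)
}

# ---- cohort table ------------------------------------------------------------

cohort_numeric_cols <- function(nms) {
  intersect(
    c("age", "sex", "bmi", "vitd", "draw_month", "psoriasis",
      grep("^pc[0-9]+$", nms, value = TRUE)),
    nms
  )
}

#' Read a cohort phenotype/covariate table
#'
#' Expects a delimited file with one row per participant and at least
#' `sample_id`, `age`, `sex` and `psoriasis` columns; `batch`, `pc1`..`pc20`,
#' `bmi` (kg/m^2), `vitd` (serum 25-hydroxyvitamin D, nmol/l) and `draw_month`
#' (1-12) are used when present. Missing cells are allowed for `bmi`, `vitd`
#' and `draw_month` and are kept as `NA` (each analysis is complete-case on
#' the variables it uses). Rows with missing psoriasis status are dropped with
#' a warning; a psoriasis value outside \{0, 1\} is an error. Per-column
#' missingness counts are reported via [rlang::inform()].
#'
#' @param path Input path (TSV/CSV).
#' @param delim Field delimiter; guessed when `NULL`.
#' @return A validated tibble.
#' @export
read_cohort <- function(path, delim = NULL) {
  raw <- read_table_guess(path, delim)
  if (!"sample_id" %in% names(raw)) {
    names(raw)[1L] <- "sample_id"
  }
  need <- setdiff(c("age", "sex", "psoriasis"), names(raw))
  if (length(need) > 0L) {
    abort(sprintf("Cohort table '%s' lacks column(s): %s",
                  path, paste(need, collapse = ", ")))
  }
  out <- raw
  for (col in cohort_numeric_cols(names(out))) {
    v <- suppressWarnings(as.numeric(out[[col]]))
    bad <- which(is.na(v) & !is.na(out[[col]]))
    if (length(bad) > 0L) {
      abort(sprintf("Non-numeric value '%s' in column '%s' at row %d of '%s'.",
                    out[[col]][bad[1L]], col, bad[1L], path))
    }
    out[[col]] <- v
  }
  drop <- is.na(out$psoriasis)
  if (any(drop)) {
    warn(sprintf("Dropped %d row(s) with missing psoriasis status.", sum(drop)))
    out <- out[!drop, , drop = FALSE]
  }
  validate_cohort(out)
  miss <- vapply(out, function(x) sum(is.na(x)), 0L)
  miss <- miss[miss > 0L]
  if (length(miss) > 0L) {
    inform(paste0(
      "Missing values: ",
      paste(sprintf("%s: %d", names(miss), miss), collapse = ", ")
    ))
  }
  as_tibble(out)
}

validate_cohort <- function(x) {
  if (!is_binary01(x$psoriasis)) {
    abort("psoriasis must be coded 0/1.")
  }
  if (any(x$age <= 0, na.rm = TRUE)) abort("age must be positive.")
  if ("bmi" %in% names(x) && any(x$bmi <= 0, na.rm = TRUE)) {
    abort("bmi must be positive where present.")
  }
  if ("vitd" %in% names(x) && any(x$vitd < 0, na.rm = TRUE)) {
    abort("vitd must be non-negative where present.")
  }
  if ("draw_month" %in% names(x) &&
      any(!(x$draw_month %in% 1:12), na.rm = TRUE)) {
    abort("draw_month must be in 1..12 where present.")
  }
  invisible(x)
}

#' Write a cohort table
#'
#' @param x Cohort tibble.
#' @param path Output path (TSV).
#' @return `x`, invisibly.
#' @export
write_cohort <- function(x, path) {
  readr::write_tsv(as_tibble(x), path)
  invisible(x)
}
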