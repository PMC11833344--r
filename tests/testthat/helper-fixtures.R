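# In-code fixtures shared across the suite: tiny weight/genotype files and a
# convenience wrapper around the synthetic cohort generator.

write_tmp_lines <- function(lines, fileext = ".tsv") {
  p <- tempfile(fileext = fileext)
  writeLines(lines, p)
  p
}

# Weight table: 3 variants, tab-separated.
tiny_weight_file <- function(weights = c(0.1, 0.2, 0.3)) {
  write_tmp_lines(c(
    "variant_id\teffect_allele\tother_allele\tweight",
    sprintf("rs1\tA\tG\t%g", weights[1]),
    sprintf("rs2\tC\tT\t%g", weights[2]),
    sprintf("rs3\tG\tA\t%g", weights[3])
  ))
}

# Matching genotype dosage table (2 samples unless rows supplied).
tiny_geno_file <- function(rows = c("s1\t0\t1\t2", "s2\t1\t2\t0"),
                           heads = "sample_id\trs1|A|G\trs2|C|T\trs3|G|A") {
  write_tmp_lines(c(heads, rows))
}

make_geno <- function(dosage, variant_ids, counted, other) {
  heads <- paste(c("sample_id",
                   paste(variant_ids, counted, other, sep = "|")),
                 collapse = "\t")
  rows <- vapply(seq_len(nrow(dosage)), function(i) {
    paste(c(rownames(dosage)[i], dosage[i, ]), collapse = "\t")
  }, "")
  read_genotypes(tiny_geno_file(rows = rows, heads = heads))
}

# Small simulated cohort in the fast (direct-score) mode.
quick_sim <- function(n = 20000, seed = 1, ...) {
  generate_cohort(sim_config(n = n, seed = seed, ...), genotypes = FALSE)
}
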