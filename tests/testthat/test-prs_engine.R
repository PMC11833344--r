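test_that("PRS is the weighted effect-allele dosage sum, with allele flipping", {
  wt <- read_weight_table(tiny_weight_file(c(0.1, 0.2, 0.3)), trait = "BMI")
  g <- make_geno(
    matrix(c(0, 1, 2), nrow = 1, dimnames = list("s1", NULL)),
    c("rs1", "rs2", "rs3"), counted = c("A", "C", "G"),
    other = c("G", "T", "A")
  )
  prs <- compute_prs(g, wt)
  expect_equal(prs$raw, 0 * 0.1 + 1 * 0.2 + 2 * 0.3) # 0.8

  # counted allele is the weight table's *other* allele: dosage flips to 2 - d
  g_fl <- make_geno(
    matrix(c(2), nrow = 1, dimnames = list("s1", NULL)),
    "rs1", counted = "G", other = "A"
  )
  wt_fl <- read_weight_table(write_tmp_lines(c(
    "variant_id\teffect_allele\tother_allele\tweight", "rs1\tA\tG\t0.5"
  )))
  expect_equal(compute_prs(g_fl, wt_fl)$raw, 0.5 * (2 - 2))

  # allele pair matching neither -> skipped with warning; none left -> error
  g_bad <- make_geno(
    matrix(c(1, 1), nrow = 1, dimnames = list("s1", NULL)),
    c("rs1", "rs2"), counted = c("T", "C"), other = c("C", "T")
  )
  expect_warning(p2 <- compute_prs(g_bad, wt), "neither")
  expect_equal(prs_n_variants(p2)[["used"]], 1L)
})

test_that("variants absent from the genotypes are skipped and counted", {
  wt <- read_weight_table(tiny_weight_file(), trait = "BMI")
  g <- make_geno(
    matrix(c(1, 2), nrow = 1, dimnames = list("s1", NULL)),
    c("rs1", "rs2"), counted = c("A", "C"), other = c("G", "T")
  )
  prs <- compute_prs(g, wt)
  expect_equal(unname(prs_n_variants(prs)), c(3L, 2L))

  g_none <- make_geno(
    matrix(1, nrow = 1, dimnames = list("s1", NULL)),
    "rs99", counted = "A", other = "G"
  )
  expect_error(compute_prs(g_none, wt), "No weight-table variants")
})

test_that("missing dosages are mean-imputed per variant", {
  wt <- read_weight_table(write_tmp_lines(c(
    "variant_id\teffect_allele\tother_allele\tweight", "rs1\tA\tG\t1"
  )))
  g <- make_geno(
    matrix(c(0, 2, NA), ncol = 1, dimnames = list(c("s1", "s2", "s3"), NULL)),
    "rs1", counted = "A", other = "G"
  )
  prs <- compute_prs(g, wt)
  expect_equal(prs$raw[3], 1) # mean of non-missing (0, 2)
  expect_equal(attr(prs, "imputed_variants"), "rs1")
})

test_that("PRS is linear in the weights and equivariant under sample permutation", {
  set.seed(11)
  n <- 40
  dos <- matrix(sample(0:2, n * 5, replace = TRUE), nrow = n,
                dimnames = list(sprintf("s%02d", 1:n), NULL))
  ids <- paste0("rs", 1:5)
  g <- make_geno(dos, ids, counted = rep("A", 5), other = rep("G", 5))
  w <- tibble::tibble(variant_id = ids, effect_allele = "A",
                      other_allele = "G", weight = runif(5, -1, 1))
  p1 <- compute_prs(g, w)
  w2 <- dplyr::mutate(w, weight = 2 * weight)
  expect_equal(compute_prs(g, w2)$raw, 2 * p1$raw)

  perm <- sample(n)
  g_perm <- make_geno(dos[perm, , drop = FALSE], ids,
                      counted = rep("A", 5), other = rep("G", 5))
  p_perm <- compute_prs(g_perm, w)
  expect_equal(p_perm$raw[match(p1$sample_id, p_perm$sample_id)], p1$raw)
})

test_that("standardization gives exact mean 0 / SD 1 and flip negates", {
  wt <- read_weight_table(write_tmp_lines(c(
    "variant_id\teffect_allele\tother_allele\tweight", "rs1\tA\tG\t1"
  )), trait = "25OHD")
  g <- make_geno(
    matrix(c(0, 1, 2), ncol = 1, dimnames = list(c("s1", "s2", "s3"), NULL)),
    "rs1", counted = "A", other = "G"
  )
  prs <- standardize_prs(compute_prs(g, wt))
  expect_equal(mean(prs$standardized), 0, tolerance = 1e-10)
  expect_equal(sqrt(mean(prs$standardized^2)), 1, tolerance = 1e-10)
  # raw (0,1,2): population SD sqrt(2/3)
  expect_equal(prs$standardized, c(-1, 0, 1) / sqrt(2 / 3))

  flipped <- standardize_prs(prs, flip = TRUE)
  expect_equal(flipped$standardized, -prs$standardized)
  expect_equal(attr(flipped, "orientation"), -1L)
  expect_equal(standardize_prs(flipped, flip = TRUE)$standardized,
               prs$standardized) # involution

  g_const <- make_geno(
    matrix(c(1, 1, 1), ncol = 1, dimnames = list(c("s1", "s2", "s3"), NULL)),
    "rs1", counted = "A", other = "G"
  )
  expect_error(standardize_prs(compute_prs(g_const, wt)), "constant")
})

test_that("factorial groups follow the reference coding with ties counted low", {
  mk <- function(vals, trait) {
    factorialmr:::new_prs_tbl(
      tibble::tibble(sample_id = sprintf("s%02d", seq_along(vals)), raw = vals),
      trait = trait, n_requested = 1L, n_used = 1L, variants_used = "rs1"
    )
  }
  bmi <- mk(c(1, 2, 3, 4), "BMI")   # median 2.5
  vitd <- mk(c(4, 3, 2, 1), "25OHD") # median 2.5
  grp <- assign_factorial_groups(bmi, vitd)
  # s1: bmi low, vitd high -> 0; s2: low/high -> 0; s3: high/low -> 3; s4 -> 3
  expect_equal(grp$group, c(0L, 0L, 3L, 3L))

  # value exactly at the median classifies as low
  bmi2 <- mk(c(1, 2, 3), "BMI")  # median 2: s2 low
  vitd2 <- mk(c(3, 2, 1), "25OHD")
  grp2 <- assign_factorial_groups(bmi2, vitd2)
  expect_equal(grp2$group[2], 1L) # both exactly at median -> both low -> group 1

  # flipped vitD score must be rejected for median splitting
  expect_error(
    assign_factorial_groups(bmi, standardize_prs(vitd, flip = TRUE)),
    "trait-increasing"
  )
  expect_error(assign_factorial_groups(bmi, mk(c(1, 2), "25OHD")),
               "same samples")
})

test_that("groups partition the sample near-equally for independent scores", {
  sim <- quick_sim(n = 4000, seed = 5)
  grp <- assign_factorial_groups(sim$scores$bmi, sim$scores$vitd)
  counts <- table(grp$group)
  expect_equal(sum(counts), 4000L)
  expect_equal(length(counts), 4L)
  # continuous independent scores with distinct values and even n: exact
  # halves per score, so each group within sampling deviation of n/4
  expect_true(all(abs(counts - 1000) < 150))
})
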