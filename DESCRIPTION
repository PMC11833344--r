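Package: factorialmr
Title: Factorial Mendelian Randomization and Additive Interaction Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for factorial Mendelian randomization studies of two
    modifiable exposures instrumented by polygenic risk scores (PRS), built
    around the psoriasis / body-mass-index / serum 25-hydroxyvitamin D design:
    PRS construction from genotype dosages and published weight tables, median
    dichotomization into 2x2 factorial groups, logistic models for the 2x2 and
    continuous factorial designs, relative excess risk due to interaction
    (RERI) with delta-method and bootstrap confidence intervals and the
    all-odds-ratios-above-one validity rule, Wald-ratio scaling of estimates to
    phenotype units, instrument-strength diagnostics, season adjustment of
    25-hydroxyvitamin D and the matching cross-sectional observational
    analyses, fixed-effect meta-analysis of RERI across cohorts, and a
    calibrated synthetic biobank cohort generator (with an additive-null
    outcome mode for coverage experiments) that stands in for access-restricted
    individual-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
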