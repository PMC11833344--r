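---
title: "Factorial MR and additive interaction: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Factorial MR and additive interaction: models, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`factorialmr` implements a factorial Mendelian randomization (MR) analysis of
two exposures — genetically predicted body mass index (BMI) and serum
25-hydroxyvitamin D (25(OH)D) — on the odds of a binary outcome (psoriasis),
together with the matching cross-sectional observational analyses and a
calibrated synthetic cohort generator. This vignette explains the models and
their assumptions, the tunable parameters, the numerical choices, and what the
simulation-based tests do and do not establish.

## The factorial MR design

Each exposure is instrumented by a polygenic risk score (PRS): the weighted
sum of effect-allele dosages over a published variant panel,
$s_i = \sum_j w_j d_{ij}$, computed by `compute_prs()` and standardized to
mean 0, SD 1 by `standardize_prs()`. When the counted allele in the genotype
data is the panel's *other* allele the dosage is flipped to $2 - d$; panel
variants absent from the genotype data are skipped and reported (e.g. a
941-variant panel with 940 available); sporadically missing dosages are
mean-imputed per variant so the analysis sample stays constant.

**2×2 design.** Both scores are dichotomized at their median (values equal to
or below the median count as low), giving four groups; the reference group 0
(low BMI score, high 25(OH)D score) is the cell expected to have the lowest
risk. `run_2x2_factorial()` fits

$$\operatorname{logit} P(Y = 1) = \beta_0 + b_1 G_1 + b_2 G_2 + b_3 G_3 +
\gamma' Z$$

with group indicators $G_k$ and covariates $Z$ (age, sex, genotyping batch
one-hot with first level dropped, principal components 1–20).

**Continuous design.** `run_continuous_factorial()` replaces the indicators by
the standardized BMI score (per 1 SD increase), the standardized 25(OH)D score
*negated* so that +1 means one SD decrease (the risk-increasing orientation),
and their cross-product computed after the flip. The flip is applied only for
continuous modelling, never before median splitting, because group membership
is defined on the trait-increasing scale.

## RERI: interaction on the additive scale

With component odds ratios $OR_{01}, OR_{10}, OR_{11}$ against the
doubly-unexposed reference, the relative excess risk due to interaction is

$$\mathrm{RERI} = OR_{11} - OR_{10} - OR_{01} + 1 .$$

Zero indicates exact additivity of the two effects on the odds scale; a
logistic model with zero cross-product term is *multiplicative*, not additive,
and implies $\mathrm{RERI} = (OR_{10} - 1)(OR_{01} - 1) > 0$ whenever both
exposures are harmful. In the 2×2 design the component ORs are
$e^{b_1}, e^{b_2}, e^{b_3}$; in the continuous design they are evaluated at a
contrast $(c_1, c_2)$, by default (+1 SD, +1 SD):
$OR_{11} = e^{c_1 b_1 + c_2 b_2 + c_1 c_2 b_3}$.

**Confidence intervals.** The default is the delta method,
$\mathrm{SE}^2 = g' \Sigma g$ with $g$ the gradient of the RERI expression in
$(b_1, b_2, b_3)$ and $\Sigma$ the coefficient covariance (inverse observed
information). The source tables print symmetric-looking RERI intervals, which
is what the delta method produces; a percentile bootstrap over individuals is
available by flag (`method = "bootstrap"`) and serves as the oracle for the
delta approximation in the test suite. All 95% intervals use 1.96 exactly and
reports round to 2 decimals, matching the reporting convention of the field's
tables.

**Validity.** A RERI estimate is flagged valid only when all three component
ORs are strictly above 1; otherwise reports carry an "interpret with caution"
annotation. This is a reporting rule, not a numerical guard.

**Scaling to phenotype units.** `scale_estimates()` rescales the continuous
log-ORs by Wald ratios — each exposure coefficient multiplied by
target/first-stage (e.g. 5 kg/m² divided by the kg/m²-per-SD first-stage
effect), the cross-product by both factors, the covariance block conformably —
and then *recomputes* the RERI, which is non-linear in the coefficients. The
2×2 report is not scaled: per-group scaling from first-stage betas alone is
not well defined, and the package makes no attempt to invent one.

## Logistic substrate

`fit_logistic()` is a purpose-built IRLS (Newton scoring) implementation:
tolerance 1e-8 on the maximum coefficient change, at most 100 iterations,
step-halving so the log-likelihood never decreases, complete-case rows only.
It errors (rather than warns) on rank deficiency, degenerate outcomes,
apparent separation (any coefficient beyond ±15 on the logit scale) and
non-convergence, because a silent fallback would propagate into the RERI. The
covariance is the inverse observed information, which equals the expected
information for the canonical-link logistic — exactly the matrix the delta
method needs. The test suite cross-checks coefficients, covariance and
log-likelihood against `stats::glm` on simulated data, and against closed-form
2×2 odds ratios with Woolf variance $1/a + 1/b + 1/c + 1/d$.

## Observational counterparts

Measured 25(OH)D is season-adjusted by `season_adjust()`: subtract the draw
season's mean, add the autumn mean (winter = Dec–Feb, spring = Mar–May,
summer = Jun–Aug, autumn = Sep–Nov). Season means are estimated from the
analysis sample itself — the population-wide means behind the source analysis
are not recoverable — making the operation idempotent and exactly cancelling
any constant per-season offset. The continuous model codes 25(OH)D per
10 nmol/l *decrease* by sign-flip-and-scale of the predictor (rather than
inverting the OR afterwards) so the cross-product's sign convention is
unambiguous and the RERI contrast is (+1, +1) risk-increasing. The 2×2 model
dichotomizes at season-adjusted 25(OH)D < 25 nmol/l and BMI > 27.5 kg/m² (the
WHO public-health action threshold), both strict inequalities. One
complete-case set (both exposures plus covariates) is used for every row of
the 2×2 report; the source tables appear to have used per-block subsets, but
the blocks are mutually inconsistent there, so a single well-defined set was
chosen.

## Synthetic cohort generator

Individual-level biobank data are access-restricted, so `generate_cohort()`
emulates the analysis conditions. Defaults (the `"ukb"` preset) are calibrated
to the published cohort descriptives: prevalence 3.1%, BMI 27.4 (4.8) kg/m²,
season-adjusted 25(OH)D 54.8 (19.7) nmol/l, score-explained variance
R² = 4.8% (BMI, 941 variants) and 4.6% (25(OH)D, 21 variants), age 56.9
(7.9), 53.8% female, trait missingness 0.32% (BMI) and 8.85% (25(OH)D). The
`"hunt"` preset: prevalence 9.0%, BMI 26.4 (4.4), R² = 3.4%, age 46.1 (16.9),
no measured 25(OH)D. The first-stage slope is `sqrt(R²) × SD(trait)` per 1 SD
of score (`calibrate_first_stage()`), reproducing the published 1.05 and 0.81
kg/m² and ≈4.22 nmol/l per-SD effects. Season offsets default to winter −7,
spring −2, summer +9 nmol/l relative to autumn — a seasonal amplitude typical
of mid/high-latitude 25(OH)D — and are exactly removed by `season_adjust()`.
Batch is drawn uniformly over 5 levels and the 20 PCs are standard normal,
all with zero true effect on the outcome, mirroring covariates that adjust
for structure absent from the simulation.

**Outcome generation is group-odds-based, not logistic-with-product-term.**
In `additive_null` mode the four group odds are
$o_0 \times \{1, OR_{01}, OR_{10}, OR_{10} + OR_{01} - 1\}$, so the true RERI
is exactly zero — the property the coverage experiments need, and one no
product-free logistic model has. `specified_reri` adds a chosen RERI to the
doubly-exposed factor; `multiplicative` uses $OR_{10} OR_{01}$. The baseline
odds $o_0$ is solved by `uniroot` so the expected prevalence matches the
configuration. Continuous forms apply the same constructions per exposure
unit, on either the scores or the measured traits. The generator returns the
implied truth (`sim_truth`) for recovery tests.

With `genotypes = FALSE` the standardized scores are drawn directly as
N(0, 1) — the large-panel limiting distribution of a standardized PRS — which
is the fast path used for replicate-heavy experiments.

**What the simulations do not emulate:** linkage disequilibrium and
relatedness, assortative mating, pleiotropic instrument-confounder paths,
non-Gaussian trait tails, informative missingness, and time-varying effects.
Passing recovery and coverage tests therefore demonstrates correctness of the
estimators under the stated generating model, not robustness of MR assumptions
in real cohorts.

## Problem sizes and numerical choices

The test suite uses desk-scale problem sizes chosen to keep Monte Carlo error
well inside the asserted tolerances: 500 additive-null cohorts of n = 20,000
for delta-CI coverage (binomial SE of the coverage proportion ≈ 1%), 200
cohorts of n = 50,000 for recovery of an injected RERI of 0.5 and of the
multiplicative-mode RERI 0.0057, a 2,000-replicate bootstrap at n = 20,000
for the delta-vs-bootstrap comparison, and full 941/21-variant genotype
simulation at n = 20,000 for the generator-closure checks. The full-size
n = 398,404 is supported but not the default. Standardization uses the
population SD (divide by n) of the post-exclusion analysis sample; median
ties are resolved by the "equal to or below is low" rule; PRS/weight matching
is by exact variant-id string with no positional liftover.

## Known limitations

* RERI is reported on the odds-ratio scale; with common outcomes (e.g. the
  9% prevalence preset) ORs exceed risk ratios and RERI departs from its
  risk-scale analogue.
* The delta CI is first-order; with very sparse cells (small n, rare
  outcome) the bootstrap flag is the safer choice.
* `scale_estimates()` covers the continuous design only (see above).
* The published pooled RERI of the two source cohorts is not reproducible by
  inverse-variance pooling of the printed per-cohort values; `meta_fixed()`
  implements standard fixed-effect pooling and makes no attempt to match
  that figure.
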