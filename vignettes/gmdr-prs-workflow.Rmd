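---
title: "Polygenic risk from GMDR models and its dietary modifiers: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polygenic risk from GMDR models and its dietary modifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmdrisk)
```

`gmdrisk` implements a complete case-control workflow for small panels of
immunity/inflammation candidate variants: genotype quality control and
single-SNP screening, generalized multifactor dimensionality reduction
(GMDR) over SNP combinations, an unweighted risk-allele polygenic risk
score (PRS), stratified gene–environment interaction tests, and dietary
scoring. This vignette is the package's own account of the methods, their
assumptions, and the places where the design was genuinely open.

## 1. The disease model and the synthetic cohort

Real cohorts of this kind (large Korean population-based case-control
studies of hyperthyroidism) are available only on request, so the package
ships a generator whose output has the same shape as the three tables such
a study provides: a subjects × variants dosage matrix (additive 0/1/2
coding on the minor allele, with missing calls), a phenotype/covariate
table, and dietary exposures. Case status is drawn from a logistic model

$$\mathrm{logit}\,P(Y_i = 1) = \beta_0 + \sum_j \beta_j g_{ij}
 + \sum_t \gamma_t\, I(\text{all SNPs of } t \text{ carry} \ge 1 \text{ risk allele})
 + \sum_u \delta_u\, g_{iu}\, I(x_{iu} < c_u)
 + \sum_c \theta_c (x_{ic} - \bar x_c),$$

so the intercept controls prevalence, `main_effects` are per-allele log
odds ratios, `epistasis_terms` are carrier-product interactions,
`gxe_terms` couple an allele count to a low-exposure indicator, and
covariate effects enter centred (adding a covariate effect barely moves
the marginal prevalence).

Defaults are calibrated to the emulated study: `koges_like_config()` sets
39,641 subjects, ~2% prevalence, and ten candidate variants with the
published minor-allele frequencies (0.0121–0.365) and per-allele odds
ratios (0.88–1.60). The covariate spec centres age at 53.7 y, makes 64.8%
of subjects women (with the published ~3-fold female odds), BMI 23.9 ±
2.9 kg/m², 14.1% metabolic syndrome, and gives the dietary exposures
right-skewed (lognormal) distributions located at the published intake
means (seaweed ~1.9 g/d, Ca ~441 mg/d, energy ~96% of the estimated
requirement, 55% alcohol abstainers, and so on). A fraction of cases
(default 312/842 = 37.05%) is flagged as in complete remission; these
subjects stay in every genetic stage but are conventionally excluded from
lifestyle fits, because treatment changes lifestyle but not genotype.

**Linkage disequilibrium.** Blocks are generated by a template-haplotype
copy-mixture: on each of a subject's two haplotypes, every block variant
copies a shared template allele with probability $q = r^2{}^{1/4}$ and
otherwise draws a fresh Bernoulli(MAF) allele. For equal MAFs the pairwise
dosage correlation is $q^2$, hence pairwise $r^2$ equals the target, and
the target 1 produces exactly identical columns. We chose this scheme over
a Gaussian-copula latent haplotype because a scalar target $r^2$ then has
a closed-form calibration, with no bivariate-normal machinery; the cost is
that unequal MAFs attenuate the realized $r^2$, which the tests
accommodate by checking convergence toward (not equality with) the target.

**Reproducibility.** One master seed drives everything through a fixed
stream-splitting rule (genotypes seed+0, covariates +1, phenotype +2,
missingness +3, remission +4, modulo 2³¹−1), so stages are individually
re-runnable and a cohort is bit-identical across runs.

**What the generator does not emulate:** realistic haplotype maps and
recombination, population stratification, informative missingness, chip
intensity artefacts, family structure, and any correlation structure among
dietary exposures beyond independence. Tests that pass on this generator
therefore demonstrate the *operations* (estimation, search, calibration),
not robustness to confounding or to structured genotyping error in real
data.

## 2. Quality control and the screening funnel

Per-variant records carry call rate (threshold ≥ 0.96), heterozygosity
rate, minor-allele frequency, and an exact Hardy–Weinberg test (threshold
P > 0.05); every violated rule is recorded, and filtering is idempotent.
The HWE test is the exact conditional enumeration over heterozygote
counts, not the chi-square approximation, because the panel includes a
variant at MAF 0.0121 where the approximation fails; the test suite checks
it against an independent direct-multinomial enumeration oracle to 1e-12
on every table up to n = 50.

The "<30% heterozygosity" chip rule deserves a note: applied per variant
it would reject every common SNP (HWE heterozygosity at MAF 0.35 is
~0.46), which is why the analysis driver relaxes it for the common-variant
panel. Its origin is subject-level (duplicate-concordance QC), so
`qc_filter()` also emits a per-subject heterozygosity report; the
threshold is an ordinary argument. The chip pipeline's gender-bias check
concerns sex chromosomes and is documented as an inactive pass-through for
the autosomal matrices handled here.

The GWAS is the additive-coded logistic Wald test (matching the default of
the standard command-line GWAS tool), always reported per minor allele
with the orientation recomputed from the data. Degenerate variants and
complete separation yield flagged rows with an infinite-OR sentinel, never
exceptions, so a screening loop survives pathological columns. The screen
keeps P < 1e-5 by default with no multiplicity correction — the emulated
design uses a fixed screen, and the threshold is exposed as an argument.
"Strong LD" is undefined in the source design; pruning is greedy in
P-value order at $r^2 \ge 0.8$ (the conventional cutoff, configurable),
comparing candidates only against already-kept variants on the same
chromosome. Gene-name screening is a join against a user-supplied
SNP→gene→keyword table; no web annotation is performed.

## 3. GMDR: scores, cells, cross-validation, inference

The GMDR score is the residual $s_i = y_i - \hat p_i$ from the
covariate-only null logistic fit; with an intercept the scores sum to zero
(the score equation of the MLE). Because the covariate set differs between
published analyses of the same data, it is a required explicit input —
never defaulted.

Cells are exact multilocus genotype tuples; a cell is high-risk when its
score sum exceeds the threshold T. Three conventions had to be fixed where
the method's descriptions are silent:

* **T = 0, ties to low.** Zero is the natural cut for centred scores, and
  a deterministic tie rule makes every test reproducible.
* **Empty and unseen cells predict low.** Controls are the majority class
  at 2% prevalence, and predicting the majority class keeps specificity
  well-defined for test folds that land in training-empty cells.
* **Missing genotypes.** A subject missing any genotype of a combination
  is excluded from that combination's table only.

Cross-validation is 10-fold and stratified by case status (at 2%
prevalence unstratified folds would regularly contain no cases). Within
each fold the combination maximizing training balanced accuracy is the
fold winner; the model of record per size is the modal fold winner (ties
broken by higher mean training balanced accuracy, then candidate order),
and CVC counts the folds that chose it. An alternative reading — winner =
best combination on the full data, CVC = folds agreeing — is available
via `cvc_mode = "full_data"`. Reported TRBA/TEBA are means over folds
(`evaluate_combination()` exposes the per-fold values). The sign statistic
counts folds whose held-out balanced accuracy strictly exceeds 0.5, and
its P-value is the exact binomial tail — this convention reproduces every
printed (statistic, P) pair of the method's standard report: 10/10 →
0.0010, 9/10 → 0.0107, 8/10 → 0.0547 at four display decimals.

The search is exhaustive over all $\binom{m}{k}$ combinations and
deliberately capped at m = 12 candidates (the emulated design uses ten).
The suite verifies the search against an independent brute-force
re-implementation — string-keyed cells, explicit counting loops — with
exact agreement on winner, TRBA, TEBA and CVC over randomized small
instances, and verifies recovery: a planted two-SNP interaction (log-OR
1.0, n = 2,000, ten candidates) must emerge as the winning pair with CVC ≥
8/10 in at least 80% of seeds. Because combination search on a small
candidate panel is an interaction-detection problem, that experiment uses
case-enriched sampling (30% baseline prevalence, the spirit of the
balanced designs such methods are benchmarked on; the generator's
prevalence invariant caps it below 50%); the cohort-emulation default
stays at 2%.

The top three combinations per size are retained alongside the model of
record so the non-nested "plus model" ladders of the method's standard
reports can be rendered.

## 4. PRS construction and association

The risk allele of each model SNP is the minor allele when its GWAS OR
exceeds 1, else the major allele; an OR of exactly 1 is an error demanding
manual orientation. The PRS is the integer risk-allele count. A subject
missing any model genotype gets a missing PRS and is excluded from
association fits (complete-case); mean imputation is available behind
`na_action = "impute_mean"` and then yields fractional scores.

Binning follows the published score bins for 6-SNP (0–3 / 4–6 / ≥7) and
7-SNP (0–4 / 5–7 / ≥8) models. These are score-based, not rank-based —
the published group sizes (15,403 / 20,929 / 2,997) are far from tertiles
— so other model sizes fall back to empirical tertiles with ties going
down, documented as a fallback. Category odds ratios come from a
dummy-coded adjusted logistic fit with Wald intervals, matching the GWAS
stage for internal consistency.

## 5. Gene–environment interaction

Exposures are dichotomized at the registry cutoffs (low = strictly below;
a value at the cutoff is high), with dietary patterns cut at the 75th
percentile of the factor score, resolved at run time. The interaction test
interprets "two-way covariate-adjusted ANCOVA with an interaction term" on
a binary outcome as a pooled logistic model with ordinal PRS (0/1/2),
stratum, their product, and covariates, tested by 1-df likelihood ratio —
the ordinal coding matches the single printed P per exposure. Stratified
ORs are fitted separately per stratum with the low-PRS reference; empty
stratum × category cells are flagged and omitted rather than fatal, and
`interaction_table()` always emits a row block per registry exposure so
the output shape is stable under partial failures.

The power experiment for this stage injects the PRS effect only under low
exposure (per-allele product log-OR 0.8 on each model SNP, n = 5,000) and
requires interaction P < 0.05 plus the correct ordering of the stratum ORs
in ≥ 80% of seeds. It uses a 10% baseline prevalence: at the cohort's 2%,
n = 5,000 yields ~100 cases, a design no analyst would power an
interaction test on. The null-calibration experiment (no injected
interaction) checks the LRT's type-I error within [0.03, 0.07] over 200
reduced replicates (n = 1,000 each).

## 6. Dietary scores

The DII here is the plain weighted sum of component intakes divided by
100 — the formula of the emulated analysis, which omits the global
mean/SD standardization of the original index; the standardized variant
sits behind `standardize = TRUE`. Weights are user-supplied parameters
(the shipped `dii_weights_synthetic.tsv` is a synthetic stand-in with
literature-like signs and magnitudes, 38 components after excluding the
four spices absent from food-frequency data); declared unit mismatches are
errors, absent components contribute zero with a warning.

Pattern extraction standardizes the 29 food groups, retains principal
components with eigenvalue > 1.5, varimax-rotates them (Kaiser
normalization, convergence 1e-8), and defines each pattern by loadings ≥
0.40. Factor scores use the regression method (the emulated analysis does
not say; regression scoring is the common default), and each factor's sign
is fixed so its largest-magnitude loading is positive, making output
deterministic. Because two published group lists differ slightly, patterns
are reported by index plus defining groups; naming (Korean-balanced,
Western-style, rice-based) is left to the analyst. The recovery test
plants three orthogonal factors (loading 0.7, noise SD 0.3, n = 2,000)
and requires exact recovery of the count and of every defining group set.

## 7. Numerical choices and problem sizes

* Logistic fits run through IRLS (`glm.fit`) on prebuilt design matrices;
  Wald SEs come from the inverse weighted cross-product. Non-convergence,
  |log OR| > 15 or SE > 20 is flagged as separation.
* The exact HWE and sign tests are enumerations in log-space and exact
  binomial sums; both are oracle-checked rather than approximated.
* The test suite and the acceptance script size their simulations to what
  the properties need: single cohorts of 0.8–100k subjects for calibration
  checks, 20-seed batteries at n = 2,000 (GMDR recovery) and n = 5,000
  (interaction power), 200 reduced replicates for the interaction null,
  and one study-scale run (39,641 subjects) for the end-to-end PRS odds
  ratios. These sizes are the package's own choices: large enough for the
  asserted tolerances, small enough that the full suite runs in minutes on
  one CPU.

## 8. Known limitations

* The GWAS stage is a plain logistic screen: no mixed models, principal
  component adjustment, or X-chromosome dosage handling — fine for the
  synthetic cohorts it ships with, insufficient for structured real data.
* GMDR inference here is the sign test; permutation P-values are not
  implemented.
* The PRS is unweighted by design (risk-allele counting); beta-weighted
  scores are out of scope.
* No multiple-testing correction is applied across the exposure grid,
  mirroring the emulated analysis; with ~15 exposures, expect a nominal
  hit by chance under the null.
* The generator's independence assumptions (see §1) mean that passing
  recovery tests bound what the pipeline can do under ideal sampling, not
  under confounding.
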