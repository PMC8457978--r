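# gmdrisk

Case-control pipelines that ask whether a handful of immunity- and
inflammation-related genetic variants act together on disease risk — and
whether that joint genetic risk is modified by diet and lifestyle — need
four stages that are rarely available as one tested toolchain: genotype
quality control and single-SNP screening, a multifactor dimensionality
reduction search for SNP–SNP interaction models, an unweighted risk-allele
polygenic risk score (PRS) over the selected model, and stratified
gene–environment interaction tests. `gmdrisk` implements all four in R,
together with a synthetic cohort generator emulating a large Korean
population-based hyperthyroidism case-control study (~40,000 subjects, ~2%
prevalence, ten candidate SNPs with per-allele odds ratios between 0.88 and
1.60), so the whole pipeline is exercisable and testable without access to
restricted cohort data.

It is written for genetic epidemiologists who want the generalized
multifactor dimensionality reduction (GMDR) machinery — cell classification
by covariate-adjusted score residuals, cross-validated balanced accuracies,
cross-validation consistency, sign-test inference — as plain, inspectable R
functions rather than a GUI black box.

## The methods in brief

**GMDR.** Fit the covariate-only null logistic model once and score each
subject by the residual `s_i = y_i − p̂_i`. For a combination of k SNPs,
subjects fall into at most 3^k multilocus genotype cells; a cell is labeled
high-risk when `Σ s_i > 0` over its subjects (ties go to low). Predicting
case for high cells gives a balanced accuracy `(sensitivity +
specificity)/2`; 10-fold stratified cross-validation yields the trained
(TRBA) and test (TEBA) balanced accuracies, the cross-validation
consistency (CVC = folds agreeing on the winning combination), and a sign
statistic = number of folds with held-out balanced accuracy above 0.5,
tested by the exact binomial tail `P = Σ_{j≥s} C(10,j)/2^10` (10/10 →
0.0010, 9/10 → 0.0107, 8/10 → 0.0547).

**PRS.** For each SNP of the chosen model the risk allele is the one whose
GWAS odds ratio exceeds 1; the PRS is the per-subject count of risk alleles
(0 to 2k), binned as 0–3 / 4–6 / ≥7 for 6-SNP models and 0–4 / 5–7 / ≥8 for
7-SNP models, with odds ratios of case status estimated for the medium and
high bins against the low bin by adjusted logistic regression.

**Gene–environment.** Each exposure is dichotomized at a registry cutoff
(age 55 y, BMI 25 kg/m², Ca 500 mg/d, seaweed 2.65 g/d, DII 10.0, coffee 3
cups/week, ...; low = strictly below). Category odds ratios are fitted
within each stratum, and the PRS × exposure interaction is tested by a
1-df likelihood ratio on the pooled logistic model with an ordinal PRS
term (0/1/2) and its product with the stratum indicator.

**Dietary scores.** The dietary inflammatory index is the plain weighted
sum `DII = Σ_c w_c · intake_c / 100` over (typically 38) components with
literature-based inflammatory weights; dietary patterns come from PCA over
29 standardized food groups, retaining components with eigenvalue > 1.5,
varimax-rotating them, and defining each pattern by loadings ≥ 0.40.

## Worked example: the full synthetic workflow

The `analysis/` scripts chain the stages on the study-scale synthetic
cohort (run them from the repository root, in order):

```sh
Rscript analysis/01_simulate_cohort.R   # 39,641 subjects, 10 SNPs, ~2% cases
Rscript analysis/02_qc_gwas.R           # QC + adjusted GWAS + LD pruning
Rscript analysis/03_gmdr_search.R       # exhaustive GMDR, sizes 1..7
Rscript analysis/04_prs_association.R   # PRS bins and adjusted ORs
Rscript analysis/05_gene_environment.R  # stratified ORs + interaction P
Rscript analysis/06_dietary_scores.R    # DII and dietary patterns
```

Stage 3 prints the GMDR model ladder (workflow seed 42):

```
  n_snps      trba      teba sign_statistic sign_p   cvc
1      1 0.5254930 0.5254641              9 0.0107  6/10
2      2 0.5367726 0.5367799              9 0.0107  9/10
3      3 0.5482705 0.5366666             10 0.0010  7/10
4      4 0.5635110 0.5309530             10 0.0010  8/10
5      5 0.5875501 0.5166354              7 0.1719  4/10
6      6 0.6311487 0.5109147              8 0.0547 10/10
7      7 0.6842101 0.4883672              3 0.9453 10/10
```

TRBA climbs mechanically with model size (training optimism) while TEBA
peaks for small models — the expected picture when the simulated SNPs act
additively with modest effects, so that no genuine high-order interaction
exists to be found. Stage 4 then reports, for the 6- and 7-SNP models of
record:

```
6-SNP model [rs1881145 rs231775 rs6780858 rs1304322089 rs767861647 rs7002063]: high-vs-low OR 1.86 (1.42-2.42)
7-SNP model [rs1881145 rs231775 rs6780858 rs1304322089 rs1800610 rs767861647 rs7002063]: high-vs-low OR 1.79 (1.44-2.22)
```

i.e. subjects in the high PRS bin carry roughly 1.8–1.9 times the
hyperthyroidism odds of the low bin after covariate adjustment — the
per-allele odds ratios injected by the generator, recovered through the
whole funnel. Stage 5 excludes the ~37% of cases flagged as in complete
remission (treatment changes lifestyle, not genotype) and emits the
stratified OR grid with one interaction P per exposure; under the default
generator, which injects no gene–diet interaction, hits at P < 0.05 occur
at chance level.

Programmatic use mirrors the scripts:

```r
library(gmdrisk)
co  <- simulate_cohort(koges_like_config(seed = 42, missing_rate = 0.01))
cov <- co$covariates[, c("age", "gender_female", "bmi")]
gw  <- gwas_logistic(co$genotypes, co$phenotype, cov)
sc  <- compute_scores(co$phenotype, cov)
ms  <- search_best_models(co$genotypes$dosage, co$phenotype, sc,
                          k_max = 7, seed = 42)
gmdr_ladder(ms)
```

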