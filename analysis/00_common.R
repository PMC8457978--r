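# Shared setup for the analysis workflow. Every numbered script sources
# this file, re-derives the cohort deterministically from WORKFLOW_SEED and
# writes its outputs under results/ (summaries) and scratch/ (per-subject
# tables). Stages are therefore individually re-runnable.

library(gmdrisk)

WORKFLOW_SEED <- 42L

dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

# Study-scale synthetic cohort: 39,641 subjects, the ten candidate variants
# with their published MAFs and per-allele odds ratios, ~2% prevalence, 1%
# genotype missingness.
workflow_cohort <- function() {
  cfg <- koges_like_config(seed = WORKFLOW_SEED, missing_rate = 0.01)
  simulate_cohort(cfg)
}

# Covariate set used for adjustment throughout the workflow.
adjustment_covariates <- function(cohort) {
  cohort$covariates[, c("age", "gender_female", "bmi")]
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote ", path)
}
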