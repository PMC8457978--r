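#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic cohort the whole workflow runs on and
# export it in the exchange formats (dosage TSV + PLINK-style ped/map +
# covariate TSV). Per-subject tables go to scratch/; a compact description
# of what was generated goes to results/.

source("analysis/00_common.R")

co <- workflow_cohort()
print(co)

write_dosage_tsv(co$genotypes, "scratch/cohort_dosage.tsv")
write_ped_map(co$genotypes, "scratch/cohort", phenotype = co$phenotype)
write_covariates_tsv(co$covariates, co$genotypes$subject_ids,
                     "scratch/cohort_covariates.tsv")

summary_tab <- data.frame(
  quantity = c("subjects", "cases", "controls", "prevalence_pct",
               "variants", "genotype_missing_pct"),
  value = c(length(co$phenotype), sum(co$phenotype),
            sum(1 - co$phenotype), round(100 * mean(co$phenotype), 3),
            ncol(co$genotypes$dosage),
            round(100 * mean(is.na(co$genotypes$dosage)), 3)))
write_tsv(summary_tab, "results/01_cohort_summary.tsv")

message(sprintf(
  "cohort: %d cases / %d controls (%.2f%% prevalence), close to the 2%% the disease model targets",
  sum(co$phenotype), sum(1 - co$phenotype), 100 * mean(co$phenotype)))
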