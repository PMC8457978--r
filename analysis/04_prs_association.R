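#!/usr/bin/env Rscript
# Stage 4 — polygenic risk scores from the 6- and 7-SNP GMDR models of
# record: risk-allele orientation from the GWAS, unweighted allele
# counting, published score bins, and adjusted odds ratios of case status
# across the low/medium/high categories.

source("analysis/00_common.R")

co <- workflow_cohort()
covs <- adjustment_covariates(co)
gw <- gwas_logistic(co$genotypes, co$phenotype, covs)
scores <- compute_scores(co$phenotype, covs)
search <- search_best_models(co$genotypes$dosage, co$phenotype, scores,
                             k_max = 7, n_folds = 10, seed = WORKFLOW_SEED)

out <- list()
for (k in c(6L, 7L)) {
  mod <- search[[k]]
  rmap <- assign_risk_alleles(mod$snp_ids, gw)
  prs <- compute_prs(co$genotypes, rmap)
  cats <- categorize_prs(prs, k)
  ors <- prs_odds_ratios(co$phenotype, cats, covs)
  message(sprintf("%d-SNP model [%s]: high-vs-low OR %.2f (%.2f-%.2f)",
                  k, paste(mod$snp_ids, collapse = " "),
                  ors$or[ors$category == "high"],
                  ors$ci_lo[ors$category == "high"],
                  ors$ci_hi[ors$category == "high"]))
  out[[as.character(k)]] <- data.frame(
    model_size = k, category = c("low", ors$category),
    n = c(sum(cats == "low", na.rm = TRUE),
          sum(cats == "medium", na.rm = TRUE),
          sum(cats == "high", na.rm = TRUE)),
    or = c(1, ors$or), ci_lo = c(NA, ors$ci_lo), ci_hi = c(NA, ors$ci_hi),
    p = c(NA, ors$p))
}
write_tsv(do.call(rbind, c(out, list(make.row.names = FALSE))),
          "results/04_prs_odds_ratios.tsv")

# per-subject scores of the 7-SNP model for the interaction stage
mod7 <- search[[7]]
rmap7 <- assign_risk_alleles(mod7$snp_ids, gw)
prs7 <- compute_prs(co$genotypes, rmap7)
write_tsv(data.frame(subject_id = co$genotypes$subject_ids, prs = prs7,
                     category = categorize_prs(prs7, 7)),
          "scratch/04_prs7_subjects.tsv")
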