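# Unweighted risk-allele polygenic risk score (PRS) over a chosen GMDR
# model: each SNP's risk allele (the allele whose GWAS OR exceeds 1) counts
# 1 per copy, scores are binned into low/medium/high, and adjusted odds
# ratios across bins come from a dummy-coded logistic model.

#' Orient the risk allele of each model SNP
#'
#' The risk allele is the minor allele when the per-minor-allele GWAS OR is
#' above 1 and the major allele otherwise; the additive dosage is recoded to
#' count risk alleles (e.g. with risk allele C, genotypes TT/CT/CC score
#' 0/1/2).
#'
#' @param model_snps ids of the SNPs in the model.
#' @param gwas_results data frame from [gwas_logistic()] covering all of
#'   them.
#' @return data frame with columns id, risk_allele, other_allele, source_or,
#'   flip (TRUE when the risk allele is the major allele, i.e. dosage must
#'   be recoded 2 - d).
#' @export
assign_risk_alleles <- function(model_snps, gwas_results) {
  idx <- match(model_snps, gwas_results$id)
  if (anyNA(idx)) {
    stop("no GWAS result for SNP(s): ",
         paste(model_snps[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  or <- gwas_results$or[idx]
  if (any(!is.finite(or) | or <= 0)) {
    stop("non-finite or non-positive OR in model SNPs; resolve flagged fits first",
         call. = FALSE)
  }
  if (any(or == 1)) {
    stop("OR exactly 1 for SNP(s) ",
         paste(model_snps[or == 1], collapse = ", "),
         "; orient the risk allele manually", call. = FALSE)
  }
  flip <- or < 1
  data.frame(
    id = model_snps,
    risk_allele = ifelse(flip, gwas_results$major[idx], gwas_results$minor[idx]),
    other_allele = ifelse(flip, gwas_results$minor[idx], gwas_results$major[idx]),
    source_or = or,
    flip = flip,
    stringsAsFactors = FALSE)
}

#' Per-subject polygenic risk score
#'
#' Integer sum of risk-allele dosages over the model SNPs (range 0 to twice
#' the model size). A subject missing a genotype at any model SNP gets a
#' missing PRS and is excluded from downstream fits (complete-case default);
#' `na_action = "impute_mean"` substitutes the SNP's mean recoded dosage
#' instead (the score is then fractional).
#'
#' @param gm a `genotype_matrix` containing the model SNPs.
#' @param risk_map data frame from [assign_risk_alleles()].
#' @param na_action `"exclude"` (default) or `"impute_mean"`.
#' @return numeric PRS vector (integer-valued under `"exclude"`).
#' @export
compute_prs <- function(gm, risk_map, na_action = c("exclude", "impute_mean")) {
  na_action <- match.arg(na_action)
  d <- gm$dosage[, risk_map$id, drop = FALSE]
  d[, risk_map$flip] <- 2L - d[, risk_map$flip, drop = FALSE]
  if (na_action == "impute_mean") {
    for (j in seq_len(ncol(d))) {
      nas <- is.na(d[, j])
      if (any(nas)) d[nas, j] <- mean(d[, j], na.rm = TRUE)
    }
    rowSums(d)
  } else {
    rowSums(d)  # NA propagates: complete-case
  }
}

#' Bin PRS values into low/medium/high categories
#'
#' Models with 6 or 7 SNPs use the published score bins (6 SNPs: 0-3 / 4-6 /
#' >=7; 7 SNPs: 0-4 / 5-7 / >=8). Other model sizes fall back to empirical
#' tertiles of the scores (low: score <= 33.3rd percentile; medium: up to
#' the 66.7th; high above — ties go down), documented as a fallback because
#' the published bins are score-based, not rank-based.
#'
#' @param prs numeric PRS vector (NA allowed).
#' @param model_size number of SNPs in the model.
#' @return factor with levels low/medium/high.
#' @export
categorize_prs <- function(prs, model_size) {
  if (model_size == 6L) {
    lo <- 3; hi <- 7
  } else if (model_size == 7L) {
    lo <- 4; hi <- 8
  } else {
    q <- stats::quantile(prs, c(1 / 3, 2 / 3), na.rm = TRUE, names = FALSE)
    lab <- ifelse(is.na(prs), NA_character_,
                  ifelse(prs <= q[1], "low",
                         ifelse(prs <= q[2], "medium", "high")))
    return(factor(lab, levels = c("low", "medium", "high")))
  }
  lab <- ifelse(is.na(prs), NA_character_,
                ifelse(prs <= lo, "low",
                       ifelse(prs < hi, "medium", "high")))
  factor(lab, levels = c("low", "medium", "high"))
}

# Wald OR/CI/P rows for the non-reference levels of `term` in a dummy-coded
# logistic fit y ~ term + covariates.
category_or_fit <- function(phenotype, categories, covariates = NULL) {
  df <- data.frame(.y = phenotype, .cat = categories)
  if (!is.null(covariates) && ncol(as.data.frame(covariates)) > 0L) {
    df <- cbind(df, as.data.frame(covariates))
  }
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (nlevels(droplevels(df$.cat)) < 2L) {
    stop("PRS category is constant after removing incomplete rows", call. = FALSE)
  }
  X <- stats::model.matrix(~ ., df[, -1, drop = FALSE])
  fit <- fit_logistic(X, df$.y)
  sel <- grep("^\\.cat", colnames(X))
  b <- fit$beta[sel]; se <- fit$se[sel]
  data.frame(
    category = sub("^\\.cat", "", colnames(X)[sel]),
    or = exp(b), ci_lo = exp(b - 1.96 * se), ci_hi = exp(b + 1.96 * se),
    p = 2 * stats::pnorm(-abs(b / se)),
    n = nrow(df), row.names = NULL, stringsAsFactors = FALSE)
}

#' Adjusted odds ratios across PRS categories
#'
#' Logistic fit of case status on dummy-coded PRS category (low = reference)
#' plus covariates; per-category OR with Wald 95% CI.
#'
#' @param phenotype 0/1 case vector.
#' @param categories factor from [categorize_prs()].
#' @param covariates optional data frame.
#' @return data frame with one row per non-reference category (medium,
#'   high): or, ci_lo, ci_hi, p, n.
#' @export
prs_odds_ratios <- function(phenotype, categories, covariates = NULL) {
  tabs <- table(categories)
  empty <- names(tabs)[tabs == 0]
  if (length(empty)) {
    stop("empty PRS category: ", paste(empty, collapse = ", "), call. = FALSE)
  }
  category_or_fit(phenotype, categories, covariates)
}
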