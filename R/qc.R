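# Genotype quality control and the single-SNP screening funnel:
# call-rate / heterozygosity / exact-HWE filters, additive logistic GWAS,
# P-value screening, gene-keyword screening, and LD r^2 pruning.

#' Minor-allele frequency of one variant
#'
#' @param dosages integer vector in \{0, 1, 2, NA\}; counts of allele 1.
#' @return list with `maf` = min(f, 1 - f) where f is the allele-1 frequency
#'   over non-missing calls, `allele1_freq`, `minor_is_allele1`, `n_used`.
#' @export
compute_maf <- function(dosages) {
  d <- dosages[!is.na(dosages)]
  if (length(d) == 0L) stop("MAF undefined: all calls missing", call. = FALSE)
  if (!all(d %in% 0:2)) stop("dosages must be 0, 1, 2 or NA", call. = FALSE)
  f <- sum(d) / (2 * length(d))
  list(maf = min(f, 1 - f), allele1_freq = f,
       minor_is_allele1 = f <= 0.5, n_used = length(d))
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test: conditional on the observed allele counts, all
#' heterozygote counts of the right parity are enumerated, and P is the sum
#' of the probabilities of configurations no more probable than the observed
#' one. The exact test is used (rather than the chi-square approximation)
#' because rare variants with MAF around 0.01 are in scope and the
#' approximation fails there.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (homozygous, heterozygous,
#'   homozygous for the other allele).
#' @return the exact two-sided P-value.
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("genotype counts must be non-negative",
                                         call. = FALSE)
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("empty genotype table", call. = FALSE)
  n1 <- 2 * n_AA + n_Aa                 # copies of allele A
  n_rare <- min(n1, 2 * n - n1)
  if (n_rare == 0) return(1.0)          # monomorphic: single configuration
  hets <- seq(n_rare %% 2, n_rare, by = 2)
  # unnormalized log-weights of P(n_Aa = h | n, allele counts)
  lw <- lfactorial(n) - lfactorial((n1 - hets) / 2) - lfactorial(hets) -
    lfactorial((2 * n - n1 - hets) / 2) + hets * log(2)
  w <- exp(lw - max(lw))
  probs <- w / sum(w)
  p_obs <- probs[match(n_Aa, hets)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-9)]))
}

#' Variant-level quality-control filter
#'
#' Applies the chip-style inclusion rules on called genotypes: call rate at
#' least `call_rate`, heterozygosity rate below `het_rate`, and exact HWE
#' P above `hwe_p`. Every violated rule is recorded. A per-subject
#' heterozygosity report is attached for information; the gender-bias check
#' of the original chip pipeline applies to sex chromosomes and is an
#' inactive pass-through for the autosomal matrices handled here.
#'
#' @param gm a `genotype_matrix`.
#' @param call_rate minimum fraction of non-missing calls (default 0.96,
#'   i.e. missing rate below 4%).
#' @param het_rate maximum heterozygous fraction (default 0.30).
#' @param hwe_p minimum exact HWE P-value (default 0.05).
#' @return list with `matrix` (the filtered `genotype_matrix`), `records`
#'   (data frame: id, call_rate, maf, het_rate, hwe_p, passed, reasons) and
#'   `subject_het` (data frame: subject_id, het_rate).
#' @export
qc_filter <- function(gm, call_rate = 0.96, het_rate = 0.30, hwe_p = 0.05) {
  d <- gm$dosage
  if (is.null(d) || ncol(d) == 0L || nrow(d) == 0L) {
    stop("empty genotype matrix", call. = FALSE)
  }
  m <- ncol(d)
  rec <- data.frame(id = gm$variant_meta$id,
                    call_rate = NA_real_, maf = NA_real_, het_rate = NA_real_,
                    hwe_p = NA_real_, passed = FALSE, reasons = "",
                    stringsAsFactors = FALSE)
  for (j in seq_len(m)) {
    dj <- d[, j]
    ok <- !is.na(dj)
    cr <- mean(ok)
    n_aa <- sum(dj[ok] == 2L); n_het <- sum(dj[ok] == 1L); n_AA <- sum(dj[ok] == 0L)
    hr <- if (any(ok)) n_het / sum(ok) else NA_real_
    mafj <- if (any(ok)) compute_maf(dj)$maf else NA_real_
    hp <- if (any(ok)) hwe_exact_test(n_AA, n_het, n_aa) else NA_real_
    reasons <- character(0)
    if (cr < call_rate) reasons <- c(reasons, "call_rate")
    if (!is.na(hr) && hr >= het_rate) reasons <- c(reasons, "het_rate")
    if (!is.na(hp) && hp <= hwe_p) reasons <- c(reasons, "hwe")
    if (!any(ok)) reasons <- c(reasons, "all_missing")
    rec$call_rate[j] <- cr; rec$maf[j] <- mafj; rec$het_rate[j] <- hr
    rec$hwe_p[j] <- hp
    rec$passed[j] <- length(reasons) == 0L
    rec$reasons[j] <- paste(reasons, collapse = ";")
  }
  keep <- which(rec$passed)
  out <- gm
  out$dosage <- d[, keep, drop = FALSE]
  out$variant_meta <- gm$variant_meta[keep, , drop = FALSE]
  subject_het <- data.frame(
    subject_id = gm$subject_ids,
    het_rate = rowMeans(d == 1L, na.rm = TRUE),
    stringsAsFactors = FALSE)
  list(matrix = out, records = rec, subject_het = subject_het)
}

# Weighted-least-squares IRLS logistic fit on a prebuilt design matrix;
# returns coefficients, standard errors and deviance without formula
# overhead (the GWAS loop refits thousands of variants).
fit_logistic <- function(X, y) {
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(), control = list(maxit = 50))
  )
  w <- fit$weights
  XtWX <- crossprod(X * sqrt(w))
  se <- rep(NA_real_, ncol(X))
  vc <- try(chol2inv(chol(XtWX)), silent = TRUE)
  if (!inherits(vc, "try-error")) se <- sqrt(diag(vc))
  list(beta = fit$coefficients, se = se, converged = fit$converged,
       deviance = fit$deviance, fitted = fit$fitted.values,
       boundary = fit$boundary)
}

#' Per-variant additive logistic GWAS
#'
#' Fits, variant by variant, a maximum-likelihood logistic model of case
#' status on the minor-allele dosage (additive 0/1/2 coding) with the
#' supplied covariates, and reports the per-minor-allele odds ratio with
#' Wald 95% confidence interval and Wald P. Subjects missing the genotype at
#' a variant are excluded for that variant only; subjects missing any
#' covariate are excluded throughout. With no covariates and a binary (0/1)
#' "dosage" the fit reduces to the crude 2x2 cross-product odds ratio.
#'
#' Degenerate variants (constant dosage among complete cases) and fits
#' showing complete separation are returned flagged with an infinite-OR
#' sentinel rather than raising an error.
#'
#' @param gm a `genotype_matrix` (dosage coded on the minor allele; the
#'   orientation is recomputed from the data and flipped where needed so the
#'   reported OR is always per minor allele).
#' @param phenotype 0/1 case vector.
#' @param covariates optional data frame; factors are dummy-coded.
#' @return data frame ordered by P ascending with columns id, chr, pos,
#'   minor, major, or, ci_lo, ci_hi, p, maf, hwe_p, n_used, status
#'   (`"ok"`, `"degenerate"` or `"separation"`).
#' @export
gwas_logistic <- function(gm, phenotype, covariates = NULL) {
  stopifnot(all(phenotype %in% 0:1))
  d <- gm$dosage
  meta <- gm$variant_meta
  n <- nrow(d)
  C <- NULL
  keep_subj <- rep(TRUE, n)
  if (!is.null(covariates) && ncol(as.data.frame(covariates)) > 0L) {
    covariates <- as.data.frame(covariates)
    keep_subj <- stats::complete.cases(covariates)
    C <- stats::model.matrix(~ ., covariates[keep_subj, , drop = FALSE])[, -1, drop = FALSE]
  }
  y_all <- phenotype[keep_subj]
  d <- d[keep_subj, , drop = FALSE]
  m <- ncol(d)
  res <- data.frame(id = meta$id, chr = meta$chr, pos = meta$pos,
                    minor = meta$minor, major = meta$major,
                    or = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                    p = NA_real_, maf = NA_real_, hwe_p = NA_real_,
                    n_used = NA_integer_, status = "ok",
                    stringsAsFactors = FALSE)
  for (j in seq_len(m)) {
    gj <- d[, j]
    ok <- !is.na(gj)
    g <- gj[ok]; y <- y_all[ok]
    res$n_used[j] <- length(g)
    if (length(g) == 0L) { res$status[j] <- "degenerate"; next }
    mafj <- compute_maf(g)
    res$maf[j] <- mafj$maf
    res$hwe_p[j] <- hwe_exact_test(sum(g == 0L), sum(g == 1L), sum(g == 2L))
    if (!mafj$minor_is_allele1) {
      g <- 2L - g                        # re-orient: report per minor allele
      mm <- res$minor[j]; res$minor[j] <- res$major[j]; res$major[j] <- mm
    }
    if (stats::var(g) == 0) { res$status[j] <- "degenerate"; next }
    X <- cbind(`(Intercept)` = 1, g = g,
               if (!is.null(C)) C[ok, , drop = FALSE])
    fit <- fit_logistic(X, y)
    b <- fit$beta[2]; se <- fit$se[2]
    if (!fit$converged || is.na(se) || se > 20 || abs(b) > 15) {
      res$status[j] <- "separation"
      res$or[j] <- if (!is.na(b) && b < 0) 0 else Inf
      next
    }
    res$or[j] <- exp(b)
    res$ci_lo[j] <- exp(b - 1.96 * se)
    res$ci_hi[j] <- exp(b + 1.96 * se)
    res$p[j] <- 2 * stats::pnorm(-abs(b / se))
  }
  res[order(res$p, res$id), ]
}

#' Select screening candidates by GWAS P-value
#'
#' @param results data frame from [gwas_logistic()].
#' @param p_threshold inclusion threshold (default 1e-5, the conventional
#'   suggestive genome-wide screen used here; no multiplicity correction is
#'   applied on top of the fixed screen).
#' @return character vector of variant ids with P strictly below the
#'   threshold, ordered by P ascending then id.
#' @export
select_candidates <- function(results, p_threshold = 1e-5) {
  hit <- results[!is.na(results$p) & results$p < p_threshold, , drop = FALSE]
  hit <- hit[order(hit$p, hit$id), , drop = FALSE]
  hit$id
}

#' Screen candidates by gene annotation keywords
#'
#' Joins GWAS candidates against a user-supplied SNP-to-gene annotation
#' table and keeps variants whose annotated keywords match any of the
#' requested ones (the immunity/inflammation funnel step; no web annotation
#' is performed).
#'
#' @param ids candidate variant ids.
#' @param annotation data frame with columns `id`, `gene`, `keywords`
#'   (semicolon-separated).
#' @param keywords character vector to match (case-insensitive).
#' @return the subset of `ids` annotated with a matching keyword, in input
#'   order.
#' @export
screen_genes <- function(ids, annotation, keywords = c("inflammation", "thyroid")) {
  ann <- annotation[match(ids, annotation$id), , drop = FALSE]
  hit <- vapply(seq_along(ids), function(i) {
    kw <- ann$keywords[i]
    if (is.na(kw) || is.na(ann$gene[i]) || !nzchar(ann$gene[i])) return(FALSE)
    any(tolower(trimws(strsplit(kw, ";")[[1]])) %in% tolower(keywords))
  }, logical(1))
  ids[hit]
}

#' Composite-genotype LD r-squared between two variants
#'
#' Squared Pearson correlation of the dosage vectors over subjects
#' non-missing at both variants.
#'
#' @param a,b dosage vectors.
#' @return r-squared in \[0, 1\], or `NA` (flagged via attribute
#'   `"degenerate"`) when either variant has zero variance or fewer than two
#'   complete pairs exist.
#' @export
ld_r2 <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2L) return(structure(NA_real_, degenerate = TRUE))
  a <- a[ok]; b <- b[ok]
  if (stats::var(a) == 0 || stats::var(b) == 0) {
    return(structure(NA_real_, degenerate = TRUE))
  }
  stats::cor(a, b)^2
}

#' Greedy LD pruning of screening candidates
#'
#' Scans the candidates in their given order (strongest association first)
#' and drops a variant when its r-squared with an already-kept variant on the
#' same chromosome reaches the threshold; variants kept earlier thus shadow
#' later correlated ones, mirroring the "strong LD provides similar
#' information" removal of the screening funnel.
#'
#' @param candidates variant ids ordered by GWAS P ascending.
#' @param gm the `genotype_matrix` holding those variants.
#' @param r2_threshold removal threshold (default 0.8).
#' @return the pruned id vector, in input order.
#' @export
ld_prune <- function(candidates, gm, r2_threshold = 0.8) {
  meta <- gm$variant_meta
  chr <- meta$chr[match(candidates, meta$id)]
  kept <- character(0); kept_chr <- integer(0)
  for (i in seq_along(candidates)) {
    id <- candidates[i]
    same <- kept[kept_chr == chr[i]]
    drop <- FALSE
    for (k in same) {
      r2 <- ld_r2(gm$dosage[, id], gm$dosage[, k])
      if (!is.na(r2) && r2 >= r2_threshold) { drop <- TRUE; break }
    }
    if (!drop) { kept <- c(kept, id); kept_chr <- c(kept_chr, chr[i]) }
  }
  kept
}
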