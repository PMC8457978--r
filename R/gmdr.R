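# Generalized multifactor dimensionality reduction (GMDR), from scratch.
#
# Subjects are scored by the residual of a covariate-only null logistic
# model (score = y - fitted probability), multilocus genotype cells are
# labeled high/low risk by the sign of their summed scores, and SNP
# combinations are ranked by cross-validated balanced accuracy. The model of
# record per combination size carries the trained balanced accuracy (TRBA),
# test balanced accuracy (TEBA), cross-validation consistency (CVC) and an
# exact one-sided sign test on the number of folds beating chance.

#' Covariate-adjusted GMDR score residuals
#'
#' Fits the null logistic model `phenotype ~ covariates` once and returns
#' per-subject scores `y - fitted`. With an intercept in the null model the
#' scores sum to zero (score equation of the MLE), which is what makes the
#' zero threshold of [classify_cells()] the natural cell-labeling cut.
#'
#' @param phenotype 0/1 case vector.
#' @param covariates optional data frame; subjects with a missing covariate
#'   are dropped (their score is `NA`) and counted in the `n_dropped`
#'   attribute.
#' @return numeric score vector aligned with `phenotype` (NA where dropped).
#' @export
compute_scores <- function(phenotype, covariates = NULL) {
  stopifnot(all(phenotype %in% 0:1))
  n <- length(phenotype)
  keep <- rep(TRUE, n)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if (!is.null(covariates) && ncol(as.data.frame(covariates)) > 0L) {
    covariates <- as.data.frame(covariates)
    keep <- stats::complete.cases(covariates)
    X <- stats::model.matrix(~ ., covariates[keep, , drop = FALSE])
  }
  fit <- fit_logistic(X[, , drop = FALSE], phenotype[keep])
  if (!fit$converged) {
    stop("null model did not converge for covariate set: ",
         paste(colnames(X)[-1], collapse = ", "), call. = FALSE)
  }
  scores <- rep(NA_real_, n)
  scores[keep] <- phenotype[keep] - fit$fitted
  attr(scores, "n_dropped") <- sum(!keep)
  scores
}

# Integer cell code of each subject for a combination: 1 + sum g_j 3^(j-1),
# NA when any genotype in the combination is missing.
cell_codes <- function(geno) {
  geno <- as.matrix(geno)
  k <- ncol(geno)
  as.integer(1 + geno %*% 3^(seq_len(k) - 1))
}

#' Build and label the multilocus genotype cell table
#'
#' Groups subjects by their exact multilocus genotype tuple over the
#' combination's SNPs and labels each cell `high` when its summed score
#' exceeds the threshold, `low` otherwise (ties at the threshold go to
#' `low`, so the classification is deterministic); cells with no subjects
#' are `empty`. Subjects missing a genotype at any combination SNP are
#' excluded from the table.
#'
#' @param scores GMDR score vector from [compute_scores()].
#' @param phenotype 0/1 case vector.
#' @param geno n x k matrix of dosages for the combination's SNPs.
#' @param threshold cell-labeling cut on the score sum (default 0, matching
#'   the centering of the scores).
#' @return list with `cells` (data frame: cell code, genotype tuple string,
#'   score_sum, n_case, n_control, label), `label_by_code` (character vector
#'   of length 3^k), `assign` (per-subject cell code, NA if excluded), `k`.
#' @export
classify_cells <- function(scores, phenotype, geno, threshold = 0) {
  geno <- as.matrix(geno)
  k <- ncol(geno)
  stopifnot(k >= 1L)
  code <- cell_codes(geno)
  ok <- !is.na(code) & !is.na(scores)
  n_cells <- 3L^k
  score_sum <- n_case <- n_control <- numeric(n_cells)
  cs <- rowsum(scores[ok], code[ok])
  cc <- rowsum(phenotype[ok], code[ok])
  cn <- rowsum(1 - phenotype[ok], code[ok])
  idx <- as.integer(rownames(cs))
  score_sum[idx] <- cs; n_case[idx] <- cc; n_control[idx] <- cn
  occupied <- (n_case + n_control) > 0
  label <- ifelse(!occupied, "empty",
                  ifelse(score_sum > threshold, "high", "low"))
  tuples <- vapply(seq_len(n_cells) - 1L, function(code0) {
    paste(code0 %/% 3^(seq_len(k) - 1) %% 3, collapse = "/")
  }, character(1))
  cells <- data.frame(cell = seq_len(n_cells), genotype = tuples,
                      score_sum = score_sum, n_case = n_case,
                      n_control = n_control, label = label,
                      stringsAsFactors = FALSE)
  list(cells = cells[occupied, , drop = FALSE], label_by_code = label,
       assign = ifelse(ok, code, NA_integer_), k = k)
}

#' Balanced accuracy of a high/low cell classification
#'
#' Predicted class is case for subjects in `high` cells and control
#' otherwise; subjects in empty or unseen cells are predicted control (the
#' majority class, which keeps specificity well-defined). Balanced accuracy
#' is (sensitivity + specificity) / 2.
#'
#' @param predicted_high logical vector (TRUE = predicted case).
#' @param phenotype 0/1 vector.
#' @return balanced accuracy in \[0, 1\], or `NA` when the evaluation set
#'   has no cases or no controls (the fold is flagged by the caller).
#' @export
balanced_accuracy <- function(predicted_high, phenotype) {
  ok <- !is.na(predicted_high) & !is.na(phenotype)
  y <- phenotype[ok]; p <- predicted_high[ok]
  if (sum(y == 1L) == 0L || sum(y == 0L) == 0L) return(NA_real_)
  sens <- mean(p[y == 1L])
  spec <- mean(!p[y == 0L])
  (sens + spec) / 2
}

# Stratified fold assignment: cases and controls are split separately so
# every fold carries cases even at 2% prevalence.
make_folds <- function(phenotype, n_folds, seed) {
  set.seed(seed)
  fold <- integer(length(phenotype))
  for (cls in c(0L, 1L)) {
    idx <- which(phenotype == cls)
    fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  fold
}

# Train/test balanced accuracies of one combination on fixed folds.
eval_combo_on_folds <- function(code, phenotype, scores, folds, n_folds,
                                threshold = 0) {
  n_cells <- max(code, na.rm = TRUE)
  train_ba <- test_ba <- rep(NA_real_, n_folds)
  ok <- !is.na(code) & !is.na(scores)
  for (f in seq_len(n_folds)) {
    tr <- ok & folds != f
    te <- ok & folds == f
    cs <- rowsum(scores[tr], code[tr])
    lab_high <- rep(FALSE, n_cells)
    lab_high[as.integer(rownames(cs))] <- cs[, 1] > threshold
    train_ba[f] <- balanced_accuracy(lab_high[code[tr]], phenotype[tr])
    test_ba[f] <- balanced_accuracy(lab_high[code[te]], phenotype[te])
  }
  list(train_ba = train_ba, test_ba = test_ba)
}

#' Cross-validated evaluation of one SNP combination
#'
#' Splits subjects into stratified folds, builds and labels the cell table
#' on each training nine-tenths, and evaluates balanced accuracy on the
#' training set (mean = TRBA) and the held-out tenth (mean = TEBA).
#' Test-fold genotype cells that were empty in training are predicted low.
#'
#' @param geno n x k dosage matrix of the combination.
#' @param phenotype 0/1 case vector.
#' @param scores GMDR scores from [compute_scores()].
#' @param n_folds number of folds (default 10).
#' @param seed fold-assignment seed.
#' @param folds optional precomputed fold vector (overrides `seed`).
#' @return list with `trba`, `teba`, `fold_train_ba`, `fold_test_ba`.
#' @export
evaluate_combination <- function(geno, phenotype, scores, n_folds = 10,
                                 seed = 1L, folds = NULL) {
  if (is.null(folds)) folds <- make_folds(phenotype, n_folds, seed)
  if (any(tabulate(folds[phenotype == 1L], n_folds) == 0L)) {
    stop("a fold has zero cases; use fewer folds or a larger cohort",
         call. = FALSE)
  }
  code <- cell_codes(as.matrix(geno))
  ev <- eval_combo_on_folds(code, phenotype, scores, folds, n_folds)
  list(trba = mean(ev$train_ba, na.rm = TRUE),
       teba = mean(ev$test_ba, na.rm = TRUE),
       fold_train_ba = ev$train_ba, fold_test_ba = ev$test_ba)
}

#' Exact one-sided sign test on fold successes
#'
#' P = sum over j >= n_success of C(n_folds, j) / 2^n_folds: the binomial
#' tail probability of at least `n_success` of `n_folds` folds beating
#' chance under the null that each does so with probability one half. With
#' ten folds this gives 0.0010, 0.0107 and 0.0547 for 10, 9 and 8 successes
#' (to four display decimals).
#'
#' @param n_success number of folds with test balanced accuracy above 0.5.
#' @param n_folds number of folds.
#' @return exact tail P-value.
#' @export
sign_test <- function(n_success, n_folds) {
  stopifnot(n_success >= 0, n_success <= n_folds)
  sum(choose(n_folds, seq(n_success, n_folds))) / 2^n_folds
}

#' Exhaustive GMDR search over SNP combinations
#'
#' For each combination size k = 1..`k_max`, evaluates every combination of
#' the candidate SNPs on a shared stratified fold split. Within each fold
#' the combination maximizing training balanced accuracy is the fold winner;
#' the model of record is the modal fold winner (ties broken by higher mean
#' training balanced accuracy, then candidate order), its CVC is the number
#' of folds choosing it, and its sign statistic is the number of folds where
#' its held-out balanced accuracy exceeds 0.5. Reported TRBA/TEBA are means
#' over folds. The top three combinations per size (by TRBA) are retained so
#' a model ladder can be rendered.
#'
#' @param geno n x m dosage matrix of the candidate SNPs (m <= 12: the
#'   search is exhaustive and deliberately guarded against combinatorial
#'   blow-up).
#' @param phenotype 0/1 case vector.
#' @param scores GMDR scores from [compute_scores()].
#' @param k_max largest combination size searched.
#' @param n_folds folds (default 10).
#' @param seed fold-assignment seed.
#' @param cvc_mode `"modal"` (default: CVC counts folds choosing the modal
#'   fold winner) or `"full_data"` (the winner is the combination with the
#'   best training balanced accuracy on the full data; CVC counts folds
#'   agreeing with it).
#' @return list of class `gmdr_search`: one model per k, each a list with
#'   `snp_ids`, `trba`, `teba`, `cvc`, `sign_statistic`, `sign_p`,
#'   `fold_winners`, `top3` (data frame).
#' @export
search_best_models <- function(geno, phenotype, scores, k_max = 2,
                               n_folds = 10, seed = 1L,
                               cvc_mode = c("modal", "full_data")) {
  cvc_mode <- match.arg(cvc_mode)
  geno <- as.matrix(geno)
  m <- ncol(geno)
  if (m > 12L) stop("exhaustive search capped at 12 candidate SNPs (got ", m, ")",
                    call. = FALSE)
  stopifnot(k_max >= 1L, k_max <= m)
  snp_ids <- colnames(geno)
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(m))
  folds <- make_folds(phenotype, n_folds, seed)
  if (any(tabulate(folds[phenotype == 1L], n_folds) == 0L)) {
    stop("a fold has zero cases; use fewer folds or a larger cohort",
         call. = FALSE)
  }
  models <- vector("list", k_max)
  for (k in seq_len(k_max)) {
    combos <- utils::combn(m, k)
    nc <- ncol(combos)
    train_mat <- matrix(NA_real_, nc, n_folds)
    test_mat <- matrix(NA_real_, nc, n_folds)
    for (ci in seq_len(nc)) {
      code <- cell_codes(geno[, combos[, ci], drop = FALSE])
      ev <- eval_combo_on_folds(code, phenotype, scores, folds, n_folds)
      train_mat[ci, ] <- ev$train_ba
      test_mat[ci, ] <- ev$test_ba
    }
    fold_winner <- apply(train_mat, 2, which.max)
    mean_trba <- rowMeans(train_mat, na.rm = TRUE)
    if (cvc_mode == "modal") {
      tab <- tabulate(fold_winner, nc)
      cand <- which(tab == max(tab))
      winner <- cand[order(-mean_trba[cand], cand)][1]
    } else {
      full <- vapply(seq_len(nc), function(ci) {
        code <- cell_codes(geno[, combos[, ci], drop = FALSE])
        ct <- classify_cells(scores, phenotype, geno[, combos[, ci], drop = FALSE])
        balanced_accuracy(ct$label_by_code[ct$assign] == "high", phenotype)
      }, numeric(1))
      winner <- which.max(full)
    }
    cvc <- sum(fold_winner == winner)
    sign_stat <- sum(test_mat[winner, ] > 0.5, na.rm = TRUE)
    top_idx <- order(-mean_trba)[seq_len(min(3L, nc))]
    top3 <- data.frame(
      model = vapply(top_idx, function(ci)
        paste(snp_ids[combos[, ci]], collapse = ","), character(1)),
      trba = mean_trba[top_idx],
      teba = rowMeans(test_mat, na.rm = TRUE)[top_idx],
      stringsAsFactors = FALSE)
    models[[k]] <- list(
      snp_ids = snp_ids[combos[, winner]],
      trba = mean_trba[winner],
      teba = mean(test_mat[winner, ], na.rm = TRUE),
      cvc = cvc,
      sign_statistic = sign_stat,
      sign_p = sign_test(sign_stat, n_folds),
      n_folds = n_folds,
      fold_winners = vapply(fold_winner, function(ci)
        paste(snp_ids[combos[, ci]], collapse = ","), character(1)),
      top3 = top3)
    class(models[[k]]) <- "gmdr_model"
  }
  structure(models, class = "gmdr_search")
}

#' @export
print.gmdr_model <- function(x, ...) {
  cat(sprintf("GMDR model [%s]: TRBA %.4f, TEBA %.4f, sign %d (P=%.4f), CVC %d/%d\n",
              paste(x$snp_ids, collapse = " "), x$trba, x$teba,
              x$sign_statistic, x$sign_p, x$cvc, x$n_folds))
  invisible(x)
}

#' Tabulate a GMDR search as a model ladder
#'
#' @param search a `gmdr_search` result.
#' @return data frame with one row per combination size, mirroring the usual
#'   GMDR report (model SNPs, TRBA, TEBA, sign statistic and P, CVC).
#' @export
gmdr_ladder <- function(search) {
  do.call(rbind, lapply(search, function(mod) {
    data.frame(model = paste(mod$snp_ids, collapse = ","),
               n_snps = length(mod$snp_ids),
               trba = mod$trba, teba = mod$teba,
               sign_statistic = mod$sign_statistic,
               sign_p = round(mod$sign_p, 4),
               cvc = sprintf("%d/%d", mod$cvc, mod$n_folds),
               stringsAsFactors = FALSE)
  }))
}
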