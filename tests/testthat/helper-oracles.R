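# Independent oracles, deliberately written as plain enumerations/loops so
# they share no code path with the package implementation.

# Exact HWE test by direct multinomial enumeration: P(h heterozygotes | n,
# allele counts) = [n! / (a! h! b!)] 2^h * nA! na! / (2n)!, computed from
# choose() products.
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  na_ <- 2 * n - nA
  rare <- min(nA, na_)
  if (rare == 0) return(1.0)
  hets <- seq(rare %% 2, rare, by = 2)
  prob_of <- function(h) {
    a <- (nA - h) / 2
    b <- (na_ - h) / 2
    if (nA < na_) { aa <- a; bb <- b } else { aa <- b; bb <- a }
    # multinomial count of genotype configs x 2^h over total allele configs
    exp(lchoose(n, aa) + lchoose(n - aa, h) + h * log(2) - lchoose(2 * n, min(nA, na_)))
  }
  probs <- vapply(hets, prob_of, numeric(1))
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_Aa, hets)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-9)]))
}

# Stratified fold assignment following the documented rule (cases and
# controls sampled separately from a repeated 1..n_folds sequence).
oracle_folds <- function(y, n_folds, seed) {
  set.seed(seed)
  f <- integer(length(y))
  for (cls in c(0L, 1L)) {
    idx <- which(y == cls)
    f[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  f
}

# Brute-force GMDR evaluation of one combination on fixed folds, using
# string-keyed cells and explicit counting.
oracle_eval <- function(geno, y, scores, folds, n_folds) {
  n <- length(y)
  keys <- apply(as.matrix(geno), 1, paste, collapse = "-")
  usable <- !is.na(scores) & !grepl("NA", keys, fixed = TRUE)
  train_ba <- test_ba <- rep(NA_real_, n_folds)
  for (f in seq_len(n_folds)) {
    tr <- which(usable & folds != f)
    te <- which(usable & folds == f)
    sums <- list()
    for (i in tr) {
      k <- keys[i]
      sums[[k]] <- (if (is.null(sums[[k]])) 0 else sums[[k]]) + scores[i]
    }
    is_high <- function(k) !is.null(sums[[k]]) && sums[[k]] > 0
    ba <- function(idx) {
      tp <- fn <- tn <- fp <- 0
      for (i in idx) {
        pred <- is_high(keys[i])
        if (y[i] == 1 && pred) tp <- tp + 1
        if (y[i] == 1 && !pred) fn <- fn + 1
        if (y[i] == 0 && !pred) tn <- tn + 1
        if (y[i] == 0 && pred) fp <- fp + 1
      }
      if (tp + fn == 0 || tn + fp == 0) return(NA_real_)
      (tp / (tp + fn) + tn / (tn + fp)) / 2
    }
    train_ba[f] <- ba(tr)
    test_ba[f] <- ba(te)
  }
  list(train_ba = train_ba, test_ba = test_ba)
}

# Brute-force exhaustive GMDR search (one model per combination size),
# mirroring the selection contract: per-fold winner by training balanced
# accuracy, model of record = modal fold winner (ties by higher mean
# training BA then combination order), CVC = folds choosing it, sign
# statistic = folds with its held-out BA above one half.
oracle_search <- function(geno, y, scores, k_max, n_folds, seed) {
  geno <- as.matrix(geno)
  m <- ncol(geno)
  ids <- colnames(geno)
  folds <- oracle_folds(y, n_folds, seed)
  out <- list()
  for (k in seq_len(k_max)) {
    combos <- utils::combn(m, k)
    nc <- ncol(combos)
    train <- matrix(NA_real_, nc, n_folds)
    test <- matrix(NA_real_, nc, n_folds)
    for (ci in seq_len(nc)) {
      ev <- oracle_eval(geno[, combos[, ci], drop = FALSE], y, scores,
                        folds, n_folds)
      train[ci, ] <- ev$train_ba
      test[ci, ] <- ev$test_ba
    }
    fw <- integer(n_folds)
    for (f in seq_len(n_folds)) fw[f] <- which.max(train[, f])
    counts <- tabulate(fw, nc)
    cand <- which(counts == max(counts))
    mtr <- rowMeans(train, na.rm = TRUE)
    cand <- cand[order(-mtr[cand], cand)]
    winner <- cand[1]
    out[[k]] <- list(
      snp_ids = ids[combos[, winner]],
      trba = mtr[winner],
      teba = mean(test[winner, ], na.rm = TRUE),
      cvc = sum(fw == winner),
      sign_statistic = sum(test[winner, ] > 0.5, na.rm = TRUE))
  }
  out
}
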