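test_that("score residuals follow the null-model score equation", {
  # intercept-only, 2 cases + 8 controls: fitted probability 0.2 for all
  y <- c(1, 1, rep(0, 8))
  s <- compute_scores(y)
  expect_equal(unname(s[y == 1]), rep(0.8, 2), tolerance = 1e-8)
  expect_equal(unname(s[y == 0]), rep(-0.2, 8), tolerance = 1e-8)
  expect_lt(abs(sum(s)), 1e-8)

  # covariate-adjusted fit: scores still sum to zero
  set.seed(2)
  y2 <- rbinom(500, 1, 0.3)
  cov2 <- data.frame(age = rnorm(500, 50, 8), bmi = rnorm(500, 24, 3))
  s2 <- compute_scores(y2, cov2)
  expect_lt(abs(sum(s2)), 1e-8)

  # prevalence one half: scores are exactly +/- 0.5
  y3 <- rep(c(0, 1), 50)
  expect_setequal(round(unique(compute_scores(y3)), 10), c(-0.5, 0.5))
})

test_that("cells aggregate scores and respect the tie rule", {
  # prevalence 0.5 => scores +/- 0.5; one SNP with cells by dosage
  y <- c(1, 1, 1, 0, 1, 0, 1, 0, 0, 0)
  g <- matrix(c(0, 0, 0, 0, 1, 1, 1, 1, 2, 2), ncol = 1)
  s <- compute_scores(y)
  ct <- classify_cells(s, y, g)
  cells <- ct$cells
  # dosage-0 cell: 3 cases + 1 control => 3(0.5) + 1(-0.5) = 1.0 => high
  c0 <- cells[cells$genotype == "0", ]
  expect_equal(c0$score_sum, 1.0)
  expect_identical(c0$label, "high")
  # dosage-1 cell: 2 cases + 2 controls => sum 0 => tie => low
  c1 <- cells[cells$genotype == "1", ]
  expect_equal(c1$score_sum, 0.0)
  expect_identical(c1$label, "low")
  # cell totals account for every classified subject
  expect_equal(sum(cells$n_case + cells$n_control), length(y))
})

test_that("a two-SNP combination has at most nine cells and drops missing subjects", {
  set.seed(6)
  g <- cbind(rbinom(300, 2, 0.4), rbinom(300, 2, 0.4))
  g[1:10, 1] <- NA
  y <- rbinom(300, 1, 0.4)
  s <- compute_scores(y)
  ct <- classify_cells(s, y, g)
  expect_lte(nrow(ct$cells), 9L)
  expect_equal(sum(ct$cells$n_case + ct$cells$n_control), 290)
  expect_equal(sum(ct$cells$score_sum), sum(s[!is.na(g[, 1])]),
               tolerance = 1e-10)
})

test_that("balanced accuracy is the mean of sensitivity and specificity", {
  y <- c(rep(1, 10), rep(0, 10))
  expect_equal(balanced_accuracy(y == 1, y), 1.0)            # perfect
  expect_equal(balanced_accuracy(rep(FALSE, 20), y), 0.5)    # all-control
  # 20-subject fixture: sensitivity 6/10, specificity 5/10
  pred <- c(rep(TRUE, 6), rep(FALSE, 4), rep(TRUE, 5), rep(FALSE, 5))
  expect_equal(balanced_accuracy(pred, y), 0.55)
  expect_true(is.na(balanced_accuracy(rep(TRUE, 5), rep(1, 5))))
})

test_that("sign test matches the exact binomial tail", {
  expect_equal(sign_test(10, 10), 1 / 1024)
  expect_equal(round(sign_test(10, 10), 4), 0.0010)
  expect_equal(sign_test(9, 10), 11 / 1024)
  expect_equal(round(sign_test(9, 10), 4), 0.0107)
  expect_equal(round(sign_test(8, 10), 4), 0.0547)
  expect_equal(sign_test(0, 10), 1.0)
  for (n in 1:20) {
    for (s in 0:n) {
      expect_equal(sign_test(s, n), sum(dbinom(s:n, n, 0.5)),
                   tolerance = 1e-12)
    }
  }
})

test_that("cross-validated evaluation is deterministic and fold-consistent", {
  cfg <- simulation_config(1200, maf = rep(0.3, 2),
                           baseline_logit = qlogis(0.3),
                           epistasis_terms = list(list(variants = 1:2, log_or = 1.2)),
                           seed = 10)
  co <- simulate_cohort(cfg)
  s <- compute_scores(co$phenotype)
  e1 <- evaluate_combination(co$genotypes$dosage, co$phenotype, s, seed = 5)
  e2 <- evaluate_combination(co$genotypes$dosage, co$phenotype, s, seed = 5)
  expect_identical(e1, e2)
  e3 <- evaluate_combination(co$genotypes$dosage, co$phenotype, s, seed = 6)
  expect_false(identical(e1$fold_test_ba, e3$fold_test_ba))
  expect_gt(e1$teba, 0.5)
})

test_that("null combinations have held-out balanced accuracy near one half", {
  tebas <- numeric(10)
  for (r in 1:10) {
    cfg <- simulation_config(3000, maf = rep(0.3, 2),
                             baseline_logit = qlogis(0.3), seed = 200 + r)
    co <- simulate_cohort(cfg)
    s <- compute_scores(co$phenotype)
    tebas[r] <- evaluate_combination(co$genotypes$dosage, co$phenotype, s,
                                     seed = r)$teba
  }
  expect_lt(abs(mean(tebas) - 0.5), 0.02)
})

test_that("training accuracy exceeds test accuracy on average", {
  diffs <- numeric(20)
  for (r in 1:20) {
    cfg <- simulation_config(800, maf = rep(0.3, 3),
                             baseline_logit = qlogis(0.3), seed = 400 + r)
    co <- simulate_cohort(cfg)
    s <- compute_scores(co$phenotype)
    ev <- evaluate_combination(co$genotypes$dosage[, 1:2], co$phenotype, s,
                               seed = r)
    diffs[r] <- ev$trba - ev$teba
  }
  expect_gt(mean(diffs), 0)
})

test_that("search guards and trivial cases behave as specified", {
  y <- rep(c(0, 1), 100)
  s <- compute_scores(y)
  g <- matrix(rbinom(200 * 13, 2, 0.3), 200, 13)
  expect_error(search_best_models(g, y, s, k_max = 1), "capped at 12")
  g1 <- g[, 1, drop = FALSE]
  colnames(g1) <- "only"
  mod <- search_best_models(g1, y, s, k_max = 1, seed = 3)[[1]]
  expect_identical(mod$snp_ids, "only")
  expect_equal(mod$cvc, 10L)           # no competition
  expect_equal(mod$sign_p, sign_test(mod$sign_statistic, 10))
})

test_that("exhaustive search agrees exactly with the brute-force oracle", {
  set.seed(99)
  for (i in 1:6) {
    n <- sample(60:200, 1)
    m <- sample(3:5, 1)
    y <- rbinom(n, 1, 0.4)
    if (sum(y) < 12 || sum(1 - y) < 12) y[sample(n, 24)] <- rep(c(0, 1), 12)
    g <- matrix(rbinom(n * m, 2, runif(1, 0.2, 0.5)), n, m)
    colnames(g) <- paste0("s", seq_len(m))
    covs <- data.frame(x = rnorm(n))
    s <- compute_scores(y, covs)
    k_max <- sample(2:3, 1)
    seed <- sample.int(10000, 1)
    got <- search_best_models(g, y, s, k_max = k_max, n_folds = 5, seed = seed)
    want <- oracle_search(g, y, s, k_max = k_max, n_folds = 5, seed = seed)
    for (k in seq_len(k_max)) {
      expect_identical(got[[k]]$snp_ids, want[[k]]$snp_ids)
      expect_equal(got[[k]]$trba, want[[k]]$trba, tolerance = 1e-12)
      expect_equal(got[[k]]$teba, want[[k]]$teba, tolerance = 1e-12)
      expect_equal(got[[k]]$cvc, want[[k]]$cvc)
      expect_equal(got[[k]]$sign_statistic, want[[k]]$sign_statistic)
    }
  }
})

test_that("a planted epistatic pair wins the two-locus search", {
  cfg <- simulation_config(
    2000, maf = rep(0.3, 6), baseline_logit = qlogis(0.3),
    epistasis_terms = list(list(variants = 1:2, log_or = 1.2)), seed = 55)
  co <- simulate_cohort(cfg)
  s <- compute_scores(co$phenotype)
  mod <- search_best_models(co$genotypes$dosage, co$phenotype, s,
                            k_max = 2, seed = 8)[[2]]
  expect_setequal(mod$snp_ids, c("snp1", "snp2"))
  expect_gte(mod$cvc, 8L)
  expect_nrow <- nrow(mod$top3)
  expect_lte(expect_nrow, 3L)
})

test_that("the model ladder renders one row per combination size", {
  cfg <- simulation_config(800, maf = rep(0.3, 4),
                           baseline_logit = qlogis(0.3), seed = 60)
  co <- simulate_cohort(cfg)
  s <- compute_scores(co$phenotype)
  sr <- search_best_models(co$genotypes$dosage, co$phenotype, s, k_max = 3,
                           seed = 2)
  lad <- gmdr_ladder(sr)
  expect_equal(nrow(lad), 3L)
  expect_equal(lad$n_snps, 1:3)
  expect_true(all(lad$sign_p >= 0 & lad$sign_p <= 1))
})
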