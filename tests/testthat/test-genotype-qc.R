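test_that("minor-allele frequency is computed over non-missing calls", {
  d_sym <- rep(0:2, times = c(25, 50, 25))
  expect_equal(compute_maf(d_sym)$maf, 0.5)
  d_rare <- rep(0:2, times = c(98, 2, 0))
  expect_equal(compute_maf(d_rare)$maf, 0.01)          # 2 / 200 by hand
  expect_false(compute_maf(rep(2L, 10))$minor_is_allele1)
  expect_equal(compute_maf(c(0L, 1L, NA, 2L))$n_used, 3L)
  expect_error(compute_maf(c(NA_integer_, NA_integer_)), "missing")
  expect_error(compute_maf(c(0L, 3L)), "0, 1, 2")
})

test_that("exact HWE test matches hand enumeration on small tables", {
  # (1,2,1): allele counts 4/4; het in {0,2,4} with probs 3/35*{1,...}:
  # every configuration is no more probable than the observed one => P = 1
  expect_equal(hwe_exact_test(1, 2, 1), 1.0)
  expect_equal(hwe_exact_test(100, 0, 0), 1.0)          # monomorphic
  expect_equal(hwe_exact_test(57, 14, 50), hwe_oracle(57, 14, 50),
               tolerance = 1e-12)
  expect_error(hwe_exact_test(-1, 2, 1), "non-negative")
})

test_that("exact HWE test agrees with the enumeration oracle on random tables", {
  set.seed(42)
  for (i in 1:300) {
    n <- sample(1:50, 1)
    a <- sample(0:n, 1)
    h <- sample(0:(n - a), 1)
    b <- n - a - h
    expect_equal(hwe_exact_test(a, h, b), hwe_oracle(a, h, b),
                 tolerance = 1e-12)
  }
})

make_gm <- function(dosage, chr = NULL) {
  m <- ncol(dosage)
  structure(list(
    dosage = dosage,
    variant_meta = data.frame(
      id = colnames(dosage), chr = if (is.null(chr)) rep(1L, m) else chr,
      pos = seq_len(m), minor = rep("A", m), major = rep("G", m),
      stringsAsFactors = FALSE),
    subject_ids = sprintf("S%04d", seq_len(nrow(dosage)))),
    class = "genotype_matrix")
}

test_that("QC filter records every violated rule", {
  set.seed(7)
  n <- 400
  good <- rbinom(n, 2, 0.15)     # expected heterozygosity ~0.26, under the cut
  miss <- good; miss[sample(n, 20)] <- NA            # 5% missing
  het <- rep(c(0L, 1L), length.out = n)              # 50% heterozygous, HWE-violating too
  hwe_bad <- c(rep(0L, 200), rep(2L, 200))           # no hets at MAF 0.5
  gm <- make_gm(cbind(v_good = good, v_miss = miss, v_het = het,
                      v_hwe = hwe_bad))
  res <- qc_filter(gm)
  rec <- res$records
  expect_true(rec$passed[rec$id == "v_good"])
  expect_match(rec$reasons[rec$id == "v_miss"], "call_rate")
  expect_match(rec$reasons[rec$id == "v_het"], "het_rate")
  expect_match(rec$reasons[rec$id == "v_hwe"], "hwe")
  expect_identical(colnames(res$matrix$dosage), "v_good")
  expect_equal(nrow(res$subject_het), n)
})

test_that("a toy with one violation per rule filters to nothing, with distinct reasons", {
  het <- rep(c(0L, 1L), length.out = 400)
  hwe_bad <- c(rep(0L, 200), rep(2L, 200))
  miss <- rbinom(400, 2, 0.3); miss[1:20] <- NA
  gm <- make_gm(cbind(a = miss, b = het, c = hwe_bad))
  res <- qc_filter(gm)
  expect_equal(ncol(res$matrix$dosage), 0L)
  expect_setequal(unique(sub(";.*", "", res$records$reasons)),
                  c("call_rate", "het_rate", "hwe"))
})

test_that("QC filtering is idempotent", {
  cfg <- simulation_config(1500, maf = c(0.05, 0.2, 0.4), missing_rate = 0.02,
                           seed = 19)
  gm <- simulate_genotypes(cfg)
  once <- qc_filter(gm)
  twice <- qc_filter(once$matrix)
  expect_identical(once$matrix$dosage, twice$matrix$dosage)
  expect_true(all(twice$records$passed))
})

test_that("crude two-by-two logistic fit reproduces the cross-product odds ratio", {
  # thyroid-cancer exposure counts: cases 41 exposed / 489 unexposed,
  # controls 321 exposed / 38,478 unexposed
  exposure <- c(rep(1L, 41), rep(0L, 489), rep(1L, 321), rep(0L, 38478))
  y <- c(rep(1L, 530), rep(0L, 38799))
  gm <- make_gm(cbind(cancer = exposure))
  res <- gwas_logistic(gm, y)
  expect_equal(res$or[1], (41 * 38478) / (489 * 321), tolerance = 1e-6)
  expect_lt(res$ci_lo[1], res$or[1])
  expect_gt(res$ci_hi[1], res$or[1])
})

test_that("GWAS handles degenerate and separated variants without raising", {
  set.seed(5)
  n <- 300
  y <- rbinom(n, 1, 0.3)
  const <- rep(1L, n)
  sep <- y * 2L                      # dosage 2 iff case: complete separation
  ok <- rbinom(n, 2, 0.3)
  gm <- make_gm(cbind(v_const = const, v_sep = sep, v_ok = ok))
  res <- gwas_logistic(gm, y)
  expect_equal(res$status[res$id == "v_const"], "degenerate")
  expect_equal(res$status[res$id == "v_sep"], "separation")
  expect_true(is.infinite(res$or[res$id == "v_sep"]))
  expect_equal(res$status[res$id == "v_ok"], "ok")
})

test_that("GWAS always reports the odds ratio per minor allele", {
  set.seed(8)
  n <- 2000
  g <- rbinom(n, 2, 0.7)             # allele 1 is the MAJOR allele here
  eta <- qlogis(0.2) + 0.5 * g
  y <- rbinom(n, 1, plogis(eta))
  gm <- make_gm(cbind(v = g))
  res <- gwas_logistic(gm, y)
  # risk increases with allele-1 count, so per MINOR allele OR must be < 1
  expect_lt(res$or[1], 1)
  expect_equal(res$minor[1], "G")    # orientation swapped from the metadata
  expect_lte(res$maf[1], 0.5)
})

test_that("null GWAS P-values are uniform", {
  cfg <- simulation_config(600, maf = runif(2000, 0.1, 0.5),
                           baseline_logit = qlogis(0.3), seed = 23)
  co <- simulate_cohort(cfg)
  gw <- gwas_logistic(co$genotypes, co$phenotype)
  ks <- suppressWarnings(ks.test(gw$p, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(mean(gw$p < 0.05) - 0.05), 0.02)
})

test_that("candidate selection applies the screening threshold with stable order", {
  res <- data.frame(id = c("a", "b", "c"), p = c(1e-6, 2e-5, 1e-7),
                    stringsAsFactors = FALSE)
  expect_identical(select_candidates(res), c("c", "a"))
  expect_identical(select_candidates(res[0, ]), character(0))
  expect_identical(select_candidates(res, 1.0), c("c", "a", "b"))
})

test_that("gene-keyword screen joins against the annotation table", {
  ann <- data.frame(id = c("a", "b", "c", "d"),
                    gene = c("TNF", "ZZZ3", "TSHR", ""),
                    keywords = c("inflammation;immunity", "metabolism",
                                 "thyroid", "inflammation"),
                    stringsAsFactors = FALSE)
  expect_identical(screen_genes(c("a", "b", "c", "d"), ann), c("a", "c"))
  expect_identical(screen_genes("b", ann), character(0))
})

test_that("LD r-squared has the expected invariances", {
  set.seed(3)
  a <- rbinom(5000, 2, 0.4)
  expect_equal(as.numeric(ld_r2(a, a)), 1.0)
  expect_equal(as.numeric(ld_r2(a, 2L - a)), 1.0)   # sign-invariant
  b <- rbinom(5000, 2, 0.4)
  expect_lt(ld_r2(a, b), 0.01)
  z <- rep(1L, 5000)
  expect_true(is.na(ld_r2(a, z)))
  expect_true(isTRUE(attr(ld_r2(a, z), "degenerate")))
})

test_that("greedy LD pruning keeps the strongest of each correlated set", {
  set.seed(12)
  n <- 4000
  A <- rbinom(n, 2, 0.5)
  B <- A; B[sample(n, 120)] <- rbinom(120, 2, 0.5)    # r2 ~ 0.94
  C <- B; C[sample(n, 240)] <- rbinom(240, 2, 0.5)    # r2(B,C) ~ 0.88, r2(A,C) ~ 0.83
  gm <- make_gm(cbind(A = A, B = B, C = C))
  r2_ab <- ld_r2(A, B); r2_bc <- ld_r2(B, C); r2_ac <- ld_r2(A, C)
  thr <- 0.86
  # fixture sanity: the chain is only transitive through B
  expect_gte(r2_ab, thr); expect_gte(r2_bc, thr); expect_lt(r2_ac, thr)
  # greedy trace: A kept; B pruned against A; C compared against kept A only
  expect_identical(ld_prune(c("A", "B", "C"), gm, r2_threshold = thr),
                   c("A", "C"))
  # perfect pair in P-order keeps the first
  gm2 <- make_gm(cbind(A = A, A2 = A))
  expect_identical(ld_prune(c("A", "A2"), gm2), "A")
  # uncorrelated variants are all kept
  D <- rbinom(n, 2, 0.4)
  gm3 <- make_gm(cbind(A = A, D = D))
  expect_identical(ld_prune(c("A", "D"), gm3), c("A", "D"))
  # different chromosomes are never compared
  gm4 <- make_gm(cbind(A = A, B = A), chr = c(1L, 2L))
  expect_identical(ld_prune(c("A", "B"), gm4), c("A", "B"))
})

test_that("pruned output never contains a same-chromosome pair above threshold", {
  cfg <- simulation_config(
    3000, maf = rep(0.3, 8),
    ld_blocks = list(list(variants = 1:3, r2 = 0.95),
                     list(variants = 4:5, r2 = 0.9)),
    seed = 44)
  cfg$variant_meta$chr <- rep(1L, 8)
  gm <- simulate_genotypes(cfg)
  kept <- ld_prune(gm$variant_meta$id, gm, r2_threshold = 0.8)
  if (length(kept) > 1) {
    pairs <- utils::combn(kept, 2)
    for (i in seq_len(ncol(pairs))) {
      expect_lt(ld_r2(gm$dosage[, pairs[1, i]], gm$dosage[, pairs[2, i]]), 0.8)
    }
  }
})
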