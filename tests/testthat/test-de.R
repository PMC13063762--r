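test_that("detection filter keeps genes seen in enough replicates", {
  counts <- rbind(
    sparse = c(5, 0, 0, 0),  # 1 of 4 in every condition
    cspec  = c(3, 4, 5, 0),  # 3 of 4 in every condition
    solid  = c(9, 9, 9, 9)
  )
  cm <- make_tiny_cm(list(C = counts, S = counts, H = counts, HS = counts))
  kept <- filter_min_detected(cm)
  expect_equal(rownames(kept$counts), c("cspec", "solid"))
  # strict scope pools detection across all 16 samples: 4 nonzero suffice
  kept_all <- filter_min_detected(cm, scope = "all_samples")
  expect_true("sparse" %in% rownames(kept_all$counts))
  zero <- cm
  zero$counts[] <- 0L
  expect_error(filter_min_detected(zero), "every gene")
})

test_that("median-of-ratios matches the hand-computed example", {
  m <- matrix(c(10, 30, 20, 60), 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  sf <- median_of_ratios(m)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-4)
  # identical columns give identical factors
  m2 <- cbind(s1 = c(4, 7, 9), s2 = c(4, 7, 9), s3 = c(4, 7, 9))
  rownames(m2) <- paste0("g", 1:3)
  expect_equal(unname(median_of_ratios(m2)), rep(1, 3))
  expect_error(median_of_ratios(diag(3) * 5 + 0), "strictly positive")
})

test_that("median-of-ratios is scale-equivariant and order-invariant", {
  set.seed(99)
  for (i in 1:25) {
    m <- matrix(rpois(60, 50) + 1, 10, 6,
                dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
    sf <- median_of_ratios(m)
    c_scale <- runif(1, 0.2, 5)
    m2 <- m
    m2[, 3] <- m2[, 3] * c_scale
    sf2 <- median_of_ratios(m2)
    # the geometric-mean reference absorbs c^(1/n), so equivariance is a
    # statement about factor ratios: sf_3/sf_k scales by exactly c
    expect_equal(sf2[3] / sf2[-3], c_scale * sf[3] / sf[-3],
                 tolerance = 1e-12)
    expect_equal(median_of_ratios(m[sample(10), ]), sf)
  }
})

test_that("median-of-ratios agrees with the DESeq2 reference", {
  skip_if_not_installed("DESeq2")
  set.seed(4)
  m <- matrix(rnbinom(400, mu = 80, size = 5) + 1L, 50, 8,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:8)))
  expect_equal(median_of_ratios(m),
               DESeq2::estimateSizeFactorsForMatrix(m),
               tolerance = 1e-10)
})

test_that("normalization divides by size factors and preserves zeros", {
  m <- matrix(c(10, 30, 0, 20, 60, 0), 3,
              dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  norm <- normalize_counts(m, median_of_ratios(m))
  expect_equal(norm[1, 1], norm[1, 2])  # equalized across samples
  expect_equal(norm[2, 1], norm[2, 2])
  expect_equal(norm[3, ], c(s1 = 0, s2 = 0))
  expect_equal(normalize_counts(m, c(1, 1)), m)
})

test_that("bh_adjust equals p.adjust and the step-up oracle", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(bh_adjust(p), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(8)
  for (i in 1:50) {
    p <- runif(sample(1:200, 1))
    q <- bh_adjust(p)
    expect_identical(q, oracle_bh(p))
    expect_true(all(q >= p & q <= 1))
  }
})

test_that("naive_contrast recovers forced fold changes", {
  base <- matrix(rep(c(40, 80, 120), 4), 3,
                 dimnames = list(paste0("g", 1:3), NULL))
  cm <- make_tiny_cm(list(C = base, S = base, H = base, HS = base * 2))
  cfg <- de_config(pseudocount = 0)
  # identical groups: log2fc 0 everywhere
  s <- naive_contrast(cm, "S", cfg = cfg, sf = rep(1, 16))
  expect_equal(s$log2fc, rep(0, 3))
  # doubled counts at unit size factors: log2fc exactly 1
  hs <- naive_contrast(cm, "HS", cfg = cfg, sf = rep(1, 16))
  expect_equal(hs$log2fc, rep(1, 3))
  expect_error(naive_contrast(cm, "missing"), ">= 2 replicates")
})

test_that("welch p-values match t.test and are null-uniform", {
  set.seed(5)
  a <- matrix(rnorm(40), 10)
  b <- matrix(rnorm(40, sd = 2), 10)
  p_pkg <- costress:::welch_rows(a, b)
  p_ref <- vapply(1:10, function(i) {
    t.test(a[i, ], b[i, ])$p.value
  }, numeric(1))
  expect_equal(p_pkg, p_ref, tolerance = 1e-12)

  # permuted null counts give approximately uniform p-values
  set.seed(6)
  n <- 2000
  base <- matrix(rnbinom(n * 8, mu = 100, size = 10), n,
                 dimnames = list(sprintf("g%04d", 1:n), NULL))
  cm <- make_tiny_cm(list(C = base[, 1:4], S = base[, 5:8],
                          H = base[, 1:4], HS = base[, 5:8]))
  res <- naive_contrast(cm, "S")
  ks <- ks.test(res$pvalue, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("flag logic is exact: is_high implies is_sdeg", {
  set.seed(12)
  cfg <- sim_config(n_genes = 800, tissues = "shoot", seed = 12)
  cm <- generate_counts(generate_truth(cfg), cfg)
  res <- naive_contrast(cm, "HS")
  expect_identical(res$is_sdeg, res$padj < 0.01)
  expect_identical(res$is_high, res$is_sdeg & abs(res$log2fc) > 2)
  expect_true(all(res$is_sdeg[res$is_high]))
})

test_that("the stand-in DE recovers planted log2FCs with slope near 1", {
  cfg <- sim_config(n_genes = 3000, tissues = "shoot", seed = 21)
  truth <- generate_truth(cfg)
  cm <- generate_counts(truth, cfg)
  res <- naive_contrast(cm, "H")
  sel <- abs(truth$log2fc_h) >= 1
  fit <- lm(res$log2fc[sel] ~ truth$log2fc_h[sel])
  expect_gt(coef(fit)[2], 0.9)
  expect_lt(coef(fit)[2], 1.1)
})

test_that("log PCA is deterministic and separates planted groups", {
  cfg <- sim_config(n_genes = 600, tissues = "shoot", fraction_de = 0.5,
                    seed = 3)
  cm <- generate_counts(generate_truth(cfg), cfg)
  pca <- log_pca(cm, n_components = 3L)
  expect_equal(dim(pca$scores), c(16L, 3L))
  expect_lte(sum(pca$variance_fraction), 1)
  # duplicated sample columns land on identical coordinates
  m_dup <- cm$counts[, c(1, 1, 2, 2)]
  colnames(m_dup) <- c("a1", "a2", "b1", "b2")
  dup <- count_matrix(m_dup,
                      data.frame(sample_id = colnames(m_dup),
                                 condition = cm$samples$condition[c(1, 1, 2, 2)],
                                 tissue = "shoot", replicate = 1:4))
  dup_pca <- log_pca(dup, n_components = 2L)
  expect_equal(dup_pca$scores["a1", ], dup_pca$scores["a2", ])
  expect_equal(dup_pca$scores["b1", ], dup_pca$scores["b2", ])
  # deterministic sign convention: recomputation is identical
  expect_identical(pca$scores, log_pca(cm, n_components = 3L)$scores)
  # salt-treated vs not separates on one of the first two components
  salty <- cm$samples$condition %in% c("S", "HS")
  sep <- vapply(1:2, function(k) {
    abs(mean(pca$scores[salty, k]) - mean(pca$scores[!salty, k])) /
      (sd(pca$scores[, k]) + 1e-9)
  }, numeric(1))
  expect_gt(max(sep), 1)
  expect_error(log_pca(cm, n_components = 20L), "components")
})
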