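test_that("bin rollup truncates hierarchical paths", {
  ann <- data.frame(
    gene_id = c("a", "b", "b", "c"),
    bin_path = c("carbohydrate.sucrose.synthesis",
                 "carbohydrate.sucrose", "carbohydrate.starch",
                 "amino_acid")
  )
  r1 <- rollup_bins(ann, 1)
  expect_equal(r1$bin_path[r1$gene_id == "a"], "carbohydrate")
  # two leaves under one parent collapse to one membership
  expect_equal(sum(r1$gene_id == "b"), 1L)
  # depth beyond the path length leaves it unchanged
  expect_equal(rollup_bins(ann, 10)$bin_path, ann$bin_path)
  expect_error(rollup_bins(ann, 0), "positive")
})

test_that("exact rank-sum p-value matches enumeration", {
  lfc <- data.frame(gene_id = letters[1:6], log2fc = c(1, 2, 3, 4, 5, 6))
  ann <- data.frame(gene_id = letters[1:6],
                    bin_path = c(rep("low", 3), rep("high", 3)))
  res <- bin_test(lfc, ann, min_bin_size = 3)
  expect_equal(res$pvalue[res$bin_path == "low"], 0.1)
  expect_equal(res$pvalue[res$bin_path == "high"], 0.1)
  expect_equal(res$direction[res$bin_path == "low"], -1)
})

test_that("exact-mode p equals the enumeration oracle on small bins", {
  set.seed(17)
  for (i in 1:20) {
    n_in <- sample(3:8, 1)
    n_out <- sample(5:8, 1)
    vals <- sample(seq(0.1, 40, by = 0.13), n_in + n_out)  # tie-free
    ids <- sprintf("g%02d", seq_along(vals))
    lfc <- data.frame(gene_id = ids, log2fc = vals)
    ann <- data.frame(gene_id = ids,
                      bin_path = c(rep("inbin", n_in),
                                   rep("outbin", n_out)))
    res <- bin_test(lfc, ann, min_bin_size = 3)
    p_oracle <- oracle_wilcox_exact(vals[seq_len(n_in)],
                                    vals[-seq_len(n_in)])
    expect_equal(res$pvalue[res$bin_path == "inbin"], p_oracle,
                 tolerance = 1e-12)
  }
})

test_that("identical member and background distributions give p near 1", {
  vals <- rep(c(1, 2, 3, 4, 5), 4)
  ids <- sprintf("g%02d", seq_along(vals))
  lfc <- data.frame(gene_id = ids, log2fc = vals)
  ann <- data.frame(gene_id = ids,
                    bin_path = rep(c("one", "two"), each = 10))
  res <- bin_test(lfc, ann, min_bin_size = 5)
  expect_true(all(res$pvalue > 0.9))
})

test_that("results are invariant to gene order and bin relabeling", {
  set.seed(23)
  n <- 120
  ids <- sprintf("g%03d", 1:n)
  lfc <- data.frame(gene_id = ids, log2fc = rnorm(n))
  ann <- data.frame(gene_id = ids,
                    bin_path = sample(paste0("bin", 1:6), n, replace = TRUE))
  res <- bin_test(lfc, ann)
  perm <- sample(n)
  res2 <- bin_test(lfc[perm, ], ann[sample(n), ])
  expect_equal(res[order(res$bin_path), ], res2[order(res2$bin_path), ],
               ignore_attr = TRUE)
  relab <- ann
  relab$bin_path <- paste0("x_", relab$bin_path)
  res3 <- bin_test(lfc, relab)
  expect_equal(res$pvalue[order(res$bin_path)],
               res3$pvalue[order(res3$bin_path)])
})

test_that("multi-bin genes count in every bin they belong to", {
  ids <- sprintf("g%02d", 1:12)
  lfc <- data.frame(gene_id = ids, log2fc = seq(0.1, 1.2, by = 0.1))
  ann <- rbind(
    data.frame(gene_id = ids[1:6], bin_path = "a"),
    data.frame(gene_id = ids[4:9], bin_path = "b"),  # g4-g6 in both
    data.frame(gene_id = ids[10:12], bin_path = "c")
  )
  res <- bin_test(lfc, ann, min_bin_size = 3)
  expect_equal(res$n_in[res$bin_path == "a"], 6L)
  expect_equal(res$n_in[res$bin_path == "b"], 6L)
  # complement is always "all other annotated genes", including the
  # shared ones' other memberships: n_in + n_out = 12 for every bin
  expect_true(all(res$n_in + res$n_out == 12L))
})

test_that("untestable configurations raise clear errors", {
  lfc <- data.frame(gene_id = letters[1:4], log2fc = 1:4)
  ann <- data.frame(gene_id = letters[1:4], bin_path = "only")
  expect_error(bin_test(lfc, ann, min_bin_size = 3), "testable")
  expect_error(bin_test(lfc, ann[0, ]), "covers no gene")
})

test_that("raw p-values are calibrated under a global null", {
  set.seed(77)
  rates <- replicate(3, {
    n_bins <- 100
    per_bin <- 50
    n <- n_bins * per_bin
    ids <- sprintf("g%05d", 1:n)
    lfc <- data.frame(gene_id = ids, log2fc = rnorm(n))
    ann <- data.frame(gene_id = ids,
                      bin_path = sample(rep(sprintf("bin%03d", 1:n_bins),
                                            per_bin)))
    res <- bin_test(lfc, ann)
    mean(res$pvalue < 0.05)
  })
  expect_gt(mean(rates), 0.02)
  expect_lt(mean(rates), 0.08)
})
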