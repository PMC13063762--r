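make_contrast <- function(ids, lfc, sdeg, high = rep(FALSE, length(ids))) {
  data.frame(gene_id = ids, log2fc = lfc, pvalue = 0.5, padj = 0.5,
             is_sdeg = sdeg, is_high = high, stringsAsFactors = FALSE)
}

test_that("sDEG sets honour direction and high-regulation filters", {
  tb <- make_contrast(letters[1:5],
                      lfc = c(3, 1, -2, 0.5, -0.1),
                      sdeg = c(TRUE, TRUE, TRUE, FALSE, FALSE),
                      high = c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_setequal(build_sdeg_set(tb, "x")$members, c("a", "b", "c"))
  expect_setequal(build_sdeg_set(tb, "x", direction = "up")$members,
                  c("a", "b"))
  expect_equal(build_sdeg_set(tb, "x", direction = "down")$members, "c")
  expect_equal(build_sdeg_set(tb, "x", require_high = TRUE)$members, "a")
  tb$is_high <- FALSE
  expect_warning(
    s <- build_sdeg_set(tb, "x", direction = "down", require_high = TRUE),
    "empty"
  )
  expect_length(s$members, 0)
})

test_that("venn partition enumerates the seven regions correctly", {
  p <- venn_partition(gene_set("S", c("a", "b")),
                      gene_set("H", c("b", "c")),
                      gene_set("HS", "b"))
  expect_equal(p$regions$S_H_HS, "b")
  expect_equal(p$regions$S_only, "a")
  expect_equal(p$regions$H_only, "c")
  expect_length(p$regions$HS_only, 0)
  expect_equal(sum(p$summary$size), 3)

  same <- gene_set("x", letters[1:4])
  p2 <- venn_partition(same, same, same)
  expect_setequal(p2$regions$S_H_HS, letters[1:4])
  expect_equal(sum(p2$summary$size[p2$summary$region != "S_H_HS"]), 0)

  p3 <- venn_partition(gene_set("S", "a"), gene_set("H", "b"),
                       gene_set("HS", "c"))
  expect_equal(p3$summary$size[match(c("S_only", "H_only", "HS_only"),
                                     p3$summary$region)], c(1L, 1L, 1L))
  expect_equal(sum(p3$summary$size), 3)
})

test_that("venn regions are disjoint, cover the union, and rebuild sets", {
  set.seed(31)
  pool <- sprintf("g%04d", 1:800)
  for (i in 1:60) {
    s <- sample(pool, sample(0:500, 1))
    h <- sample(pool, sample(0:500, 1))
    hs <- sample(pool, sample(0:500, 1))
    p <- venn_partition(gene_set("S", s), gene_set("H", h),
                        gene_set("HS", hs))
    r <- p$regions
    all_members <- unlist(r, use.names = FALSE)
    expect_equal(length(all_members), length(unique(all_members)))
    expect_setequal(all_members, union(union(s, h), hs))
    expect_setequal(c(r$S_only, r$S_H, r$S_HS, r$S_H_HS), unique(s))
    expect_setequal(c(r$H_only, r$S_H, r$H_HS, r$S_H_HS), unique(h))
    expect_setequal(c(r$HS_only, r$S_HS, r$H_HS, r$S_H_HS), unique(hs))
    expect_equal(sum(p$summary$fraction_of_union),
                 if (length(all_members)) 1 else 0)
  }
})

test_that("universe selection resolves each mode", {
  hs <- make_contrast(letters[1:6],
                      lfc = c(3, 1, -2.5, 0.5, -0.1, 4),
                      sdeg = c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE),
                      high = c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE))
  contrasts <- list(HS = hs)
  expect_setequal(
    select_universe(universe_spec("all_hs_sdegs"), contrasts),
    c("a", "b", "c", "f")
  )
  expect_setequal(
    select_universe(universe_spec("high_hs_sdegs"), contrasts),
    c("a", "c", "f")
  )

  p <- venn_partition(gene_set("S", c("a", "b")), gene_set("H", c("b", "c")),
                      gene_set("HS", "b"))
  expect_warning(
    u <- select_universe(universe_spec("unique_hs"), partition = p),
    "empty"
  )
  expect_length(u, 0)

  ann <- data.frame(gene_id = letters[1:5],
                    bin_path = c("carbohydrate.sucrose", "carbohydrate.starch",
                                 "amino_acid.proline", "respiration.tca",
                                 "respiration.glycolysis"))
  expect_setequal(
    select_universe(universe_spec("bin_subset", bin_prefix = "respiration"),
                    annotation = ann),
    c("d", "e")
  )
  expect_error(
    select_universe(universe_spec("bin_subset", bin_prefix = "nope"),
                    annotation = ann),
    "nope"
  )

  u <- select_universe(universe_spec("curated_list",
                                     genes = c("a", "b", "zzz")),
                       contrasts)
  expect_setequal(u, c("a", "b"))
  expect_equal(attr(u, "missing"), "zzz")
})

test_that("universe selection is idempotent and order-independent", {
  hs <- make_contrast(rev(letters[1:6]),
                      lfc = c(4, -0.1, 0.5, -2.5, 1, 3),
                      sdeg = c(TRUE, FALSE, FALSE, TRUE, TRUE, TRUE))
  u1 <- select_universe(universe_spec("all_hs_sdegs"), list(HS = hs))
  hs2 <- hs[order(hs$gene_id), ]
  u2 <- select_universe(universe_spec("all_hs_sdegs"), list(HS = hs2))
  expect_setequal(u1, u2)
})
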