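#' Coarsen a hierarchical BIN annotation
#'
#' Truncates dot-separated BIN paths to the first `depth` components and
#' collapses duplicate gene-bin pairs, so enrichment can be run at a coarser
#' level of the functional hierarchy (depth 1 = top-level categories such as
#' "photosynthesis" or "protein biosynthesis").
#'
#' @param annotation Data frame with `gene_id` and `bin_path` columns; a
#'   gene may carry several bins (one row each).
#' @param depth Positive integer; paths shorter than `depth` are kept as is.
#' @return The annotation with truncated, deduplicated paths.
#' @export
rollup_bins <- function(annotation, depth) {
  if (!all(c("gene_id", "bin_path") %in% names(annotation))) {
    stop("annotation needs gene_id and bin_path columns", call. = FALSE)
  }
  if (!is.numeric(depth) || length(depth) != 1L || depth < 1) {
    stop("`depth` must be a positive integer", call. = FALSE)
  }
  parts <- strsplit(annotation$bin_path, ".", fixed = TRUE)
  trunc <- vapply(parts, function(p) {
    paste(p[seq_len(min(depth, length(p)))], collapse = ".")
  }, character(1))
  out <- annotation
  out$bin_path <- trunc
  out <- out[!duplicated(out[c("gene_id", "bin_path")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank-sum functional-category (BIN) enrichment
#'
#' For each functional BIN, tests whether the log2 fold changes of its member
#' genes differ from those of all other *annotated* genes, using a two-sided
#' Wilcoxon rank-sum test, with Benjamini-Hochberg correction across the
#' tested bins. The test is exact when the bin is small (n_in <= 25), the
#' complement moderate (< 1000; a cap that keeps the exact distribution
#' cheap), and there are no ties; otherwise the normal approximation with
#' tie and continuity correction is used.
#'
#' Genes annotated to several bins count in each of their bins' member sets
#' and in the complement of every other bin. Unannotated genes never enter
#' the background.
#'
#' @param lfc_table Data frame with `gene_id` and `log2fc` (one row per
#'   gene of the expression universe).
#' @param annotation Data frame with `gene_id`, `bin_path`.
#' @param min_bin_size Minimum members (and non-members) for a bin to be
#'   tested; default 5.
#' @param level Optional hierarchy depth; when given, the annotation is
#'   first passed through [rollup_bins()]. `NULL` (default) tests the bins
#'   as annotated (leaf level).
#' @return Data frame with one row per tested bin: `bin_path`, `n_in`,
#'   `n_out`, `statistic` (the rank-sum W of the member group), `pvalue`,
#'   `padj`, `direction` (sign of median member shift), sorted by `padj`.
#' @export
bin_test <- function(lfc_table, annotation, min_bin_size = 5L,
                     level = NULL) {
  if (!all(c("gene_id", "log2fc") %in% names(lfc_table))) {
    stop("lfc_table needs gene_id and log2fc columns", call. = FALSE)
  }
  if (anyDuplicated(lfc_table$gene_id)) {
    stop("duplicated gene ids in lfc_table", call. = FALSE)
  }
  if (!is.null(level)) annotation <- rollup_bins(annotation, level)
  annotation <- annotation[annotation$gene_id %in% lfc_table$gene_id, ,
                           drop = FALSE]
  if (!nrow(annotation)) {
    stop("annotation covers no gene of the expression universe",
         call. = FALSE)
  }
  lfc <- stats::setNames(lfc_table$log2fc, lfc_table$gene_id)
  annotated <- unique(annotation$gene_id)
  members <- split(annotation$gene_id, annotation$bin_path)
  members <- lapply(members, unique)

  testable <- vapply(members, function(g) {
    length(g) >= min_bin_size &&
      (length(annotated) - length(g)) >= min_bin_size
  }, logical(1))
  if (!any(testable)) {
    stop("no BIN is testable at min_bin_size = ", min_bin_size, call. = FALSE)
  }
  members <- members[testable]

  rows <- lapply(names(members), function(bin) {
    g_in <- members[[bin]]
    x <- lfc[g_in]
    y <- lfc[setdiff(annotated, g_in)]
    ties <- anyDuplicated(c(x, y)) > 0L
    exact <- length(x) <= 25L && length(y) < 1000L && !ties
    wt <- suppressWarnings(
      stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                         correct = TRUE)
    )
    data.frame(
      bin_path = bin,
      n_in = length(x),
      n_out = length(y),
      statistic = unname(wt$statistic),
      pvalue = wt$p.value,
      direction = sign(stats::median(x) - stats::median(y)),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, rows)
  res$padj <- bh_adjust(res$pvalue)
  res <- res[order(res$padj, res$pvalue), c("bin_path", "n_in", "n_out",
                                            "statistic", "pvalue", "padj",
                                            "direction")]
  rownames(res) <- NULL
  res
}
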