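#' Differential-expression configuration
#'
#' @param min_detected_reps Minimum number of replicates with nonzero counts
#'   for a gene to pass the detection filter (default 3).
#' @param total_reps Replicates per condition in the design (default 4).
#' @param sdeg_alpha Adjusted-p cutoff for the significant-DEG call
#'   (default 0.01).
#' @param high_lfc_threshold Absolute log2FC above which an sDEG is flagged
#'   highly regulated (default 2).
#' @param pseudocount Added before log2 in fold-change and test computations
#'   (default 1).
#' @return A list of class `de_config`.
#' @export
de_config <- function(min_detected_reps = 3L, total_reps = 4L,
                      sdeg_alpha = 0.01, high_lfc_threshold = 2,
                      pseudocount = 1) {
  if (min_detected_reps < 1L || min_detected_reps > total_reps) {
    stop("need 1 <= min_detected_reps <= total_reps", call. = FALSE)
  }
  if (sdeg_alpha <= 0 || high_lfc_threshold <= 0 || pseudocount < 0) {
    stop("thresholds must be positive (pseudocount >= 0)", call. = FALSE)
  }
  structure(
    list(min_detected_reps = as.integer(min_detected_reps),
         total_reps = as.integer(total_reps),
         sdeg_alpha = sdeg_alpha,
         high_lfc_threshold = high_lfc_threshold,
         pseudocount = pseudocount),
    class = "de_config"
  )
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization factors: a reference profile is the per-gene
#' geometric mean across samples, restricted to genes with strictly positive
#' counts in every sample; the size factor of a sample is the median over
#' those genes of count / reference.
#'
#' @param cm A [count_matrix()] or plain counts matrix.
#' @return Named numeric vector of positive size factors, one per sample.
#' @examples
#' m <- matrix(c(10, 30, 20, 60), 2, dimnames = list(c("g1", "g2"),
#'                                                   c("s1", "s2")))
#' median_of_ratios(m)  # 0.7071, 1.4142
#' @export
median_of_ratios <- function(cm) {
  counts <- if (inherits(cm, "count_matrix")) cm$counts else as.matrix(cm)
  all_pos <- rowSums(counts <= 0) == 0L
  if (!any(all_pos)) {
    stop("no gene has strictly positive counts in every sample; ",
         "median-of-ratios is undefined — consider filtering samples or ",
         "using a positive-counts fallback reference", call. = FALSE)
  }
  x <- counts[all_pos, , drop = FALSE]
  log_ref <- rowMeans(log(x))
  # median taken in log space: identical to the ratio median for an odd
  # number of reference genes, geometric interpolation for an even number
  sf <- exp(apply(log(x) - log_ref, 2L, stats::median))
  stats::setNames(sf, colnames(counts))
}

#' Divide counts by per-sample size factors
#'
#' @param cm A [count_matrix()] or counts matrix.
#' @param sf Size factors from [median_of_ratios()] (or any positive
#'   per-sample vector).
#' @return Numeric matrix of normalized counts.
#' @export
normalize_counts <- function(cm, sf = median_of_ratios(cm)) {
  counts <- if (inherits(cm, "count_matrix")) cm$counts else as.matrix(cm)
  if (length(sf) != ncol(counts) || any(sf <= 0)) {
    stop("size factors must be positive, one per sample", call. = FALSE)
  }
  sweep(counts, 2L, sf, `/`)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (via [stats::p.adjust()]), with input validation:
#' p-values must lie in [0, 1].
#'
#' @param pvalues Numeric vector of p-values (NA allowed; propagated).
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(pvalues) {
  if (!is.numeric(pvalues)) {
    stop("p-values must be numeric", call. = FALSE)
  }
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

# Vectorized Welch two-sample t-test on the rows of two matrices.
# Returns two-sided p-values; rows with zero pooled variance get p = 1 when
# means are equal, p = 0 otherwise (degenerate but deterministic).
welch_rows <- function(a, b) {
  n1 <- ncol(a); n2 <- ncol(b)
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- rowSums((a - m1)^2) / (n1 - 1)
  v2 <- rowSums((b - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  degenerate <- !is.finite(tstat) | !is.finite(df)
  p[degenerate] <- ifelse(abs(m1 - m2)[degenerate] < .Machine$double.eps^0.5,
                          1, 0)
  p
}

#' Lightweight per-contrast differential expression
#'
#' A deliberately simple stand-in for a negative-binomial GLM: counts are
#' normalized by [median_of_ratios()] factors, the log2 fold change is the
#' log-ratio of group means (with a pseudocount), and the p-value comes from
#' a Welch two-sample t-test on `log2(normalized + pseudocount)`, adjusted
#' across genes by Benjamini-Hochberg. Result tables produced by dedicated
#' DE tools (e.g. DESeq2 exports read via [read_contrast()]) can be used in
#' place of this function everywhere downstream.
#'
#' Genes with zero counts in both groups are untestable: they receive
#' `log2fc = 0`, `pvalue = 1` and `untestable = TRUE`.
#'
#' @param cm A [count_matrix()] containing both groups.
#' @param condition Condition to test (e.g. `"HS"`).
#' @param reference Reference condition (default `"C"`, the unstressed
#'   control).
#' @param cfg A [de_config()].
#' @param sf Optional size factors; computed from `cm` when omitted.
#' @return A data.frame with columns `gene_id`, `base_mean` (mean normalized
#'   count over both groups), `log2fc`, `pvalue`, `padj`, `is_sdeg`
#'   (padj < sdeg_alpha), `is_high` (sDEG and |log2fc| > high_lfc_threshold),
#'   `untestable`.
#' @export
naive_contrast <- function(cm, condition, reference = "C",
                           cfg = de_config(), sf = NULL) {
  stopifnot(inherits(cm, "count_matrix"), inherits(cfg, "de_config"))
  cond_j <- which(cm$samples$condition == condition)
  ref_j <- which(cm$samples$condition == reference)
  if (length(cond_j) < 2L || length(ref_j) < 2L) {
    stop("need >= 2 replicates in both '", condition, "' and '", reference,
         "' (found ", length(cond_j), " and ", length(ref_j), ")",
         call. = FALSE)
  }
  if (is.null(sf)) sf <- median_of_ratios(cm)
  norm <- normalize_counts(cm, sf)
  a <- norm[, cond_j, drop = FALSE]
  b <- norm[, ref_j, drop = FALSE]
  pc <- cfg$pseudocount

  mean_a <- rowMeans(a)
  mean_b <- rowMeans(b)
  log2fc <- log2((mean_a + pc) / (mean_b + pc))
  untestable <- mean_a == 0 & mean_b == 0
  pvalue <- welch_rows(log2(a + pc), log2(b + pc))
  log2fc[untestable] <- 0
  pvalue[untestable] <- 1
  padj <- bh_adjust(pvalue)

  res <- data.frame(
    gene_id = rownames(norm),
    base_mean = rowMeans(cbind(a, b)),
    log2fc = log2fc,
    pvalue = pvalue,
    padj = padj,
    stringsAsFactors = FALSE
  )
  res$is_sdeg <- res$padj < cfg$sdeg_alpha
  res$is_high <- res$is_sdeg & abs(res$log2fc) > cfg$high_lfc_threshold
  res$untestable <- untestable
  rownames(res) <- NULL
  res
}

#' Run all stress-vs-control contrasts of a factorial experiment
#'
#' @param cm A [count_matrix()].
#' @param conditions Conditions to contrast against the reference
#'   (default S, H, HS).
#' @param reference Reference condition (default C).
#' @param cfg A [de_config()].
#' @return Named list of [naive_contrast()] tables (shared size factors
#'   computed once from the full matrix).
#' @export
contrast_all <- function(cm, conditions = c("S", "H", "HS"),
                         reference = "C", cfg = de_config()) {
  sf <- median_of_ratios(cm)
  stats::setNames(
    lapply(conditions, naive_contrast, cm = cm, reference = reference,
           cfg = cfg, sf = sf),
    conditions
  )
}

#' PCA of log-normalized counts
#'
#' QC ordination: counts are normalized, log2(x + 1)-transformed, and the
#' samples are ordered by centered principal components. Component signs
#' follow a deterministic convention: within each component the loading of
#' largest magnitude is made positive.
#'
#' @param cm A [count_matrix()].
#' @param sf Size factors (computed when omitted).
#' @param n_components Number of components to return (default 2).
#' @return List with `scores` (samples x components), `variance_fraction`
#'   (per returned component) and the sample sheet.
#' @export
log_pca <- function(cm, sf = median_of_ratios(cm), n_components = 2L) {
  stopifnot(inherits(cm, "count_matrix"))
  n_samp <- ncol(cm$counts)
  if (n_samp < 2L) stop("PCA needs at least 2 samples", call. = FALSE)
  if (n_components > n_samp) {
    stop("requested ", n_components, " components from ", n_samp, " samples",
         call. = FALSE)
  }
  lg <- t(log2(normalize_counts(cm, sf) + 1))
  pc <- stats::prcomp(lg, center = TRUE, scale. = FALSE)
  k <- seq_len(n_components)
  flip <- vapply(k, function(i) {
    v <- pc$rotation[, i]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  scores <- sweep(pc$x[, k, drop = FALSE], 2L, flip, `*`)
  list(scores = scores,
       variance_fraction = (pc$sdev^2 / sum(pc$sdev^2))[k],
       samples = cm$samples)
}
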