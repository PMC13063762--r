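#' Construct a count matrix with sample metadata
#'
#' Container for a gene x sample matrix of raw counts plus the factorial
#' sample sheet (condition C/S/H/HS, tissue, replicate). Counts must be
#' non-negative integers; gene and sample ids must be unique.
#'
#' @param counts Integer-valued matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids).
#' @param samples Data frame with columns `sample_id`, `condition`,
#'   `tissue`, `replicate`; one row per column of `counts`, matched by
#'   `sample_id`.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   and `samples` (samples reordered to the column order of `counts`).
#' @export
count_matrix <- function(counts, samples) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("`counts` needs gene ids as rownames and sample ids as colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicated gene ids in count matrix", call. = FALSE)
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicated sample ids in count matrix", call. = FALSE)
  }
  if (!is.numeric(counts) || any(!is.finite(counts)) ||
      any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be finite non-negative integers", call. = FALSE)
  }
  storage.mode(counts) <- "integer"

  need <- c("sample_id", "condition", "tissue", "replicate")
  if (!is.data.frame(samples) || !all(need %in% names(samples))) {
    stop("`samples` must contain columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (!setequal(samples$sample_id, colnames(counts))) {
    stop("sample sheet ids do not match count matrix columns", call. = FALSE)
  }
  bad_cond <- setdiff(unique(samples$condition), c("C", "S", "H", "HS"))
  if (length(bad_cond)) {
    stop("unknown condition(s): ", paste(bad_cond, collapse = ", "),
         "; expected C, S, H, HS", call. = FALSE)
  }
  samples <- samples[match(colnames(counts), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  samples$replicate <- as.integer(samples$replicate)
  if (any(is.na(samples$replicate)) || any(samples$replicate < 1L)) {
    stop("replicate must be a positive integer", call. = FALSE)
  }

  structure(list(counts = counts, samples = samples), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "genes x", ncol(x$counts), "samples\n")
  cat("conditions:",
      paste(names(table(x$samples$condition)),
            table(x$samples$condition), sep = ":", collapse = "  "), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Filter genes by replicate-level detection
#'
#' Keeps a gene when it has a nonzero count in at least `min_detected_reps`
#' replicates — by default within at least one condition group (the lenient
#' scope, which preserves genes expressed only under a specific stress); the
#' `"all_samples"` scope instead requires the detection count across the
#' whole matrix.
#'
#' @param cm A [count_matrix()].
#' @param cfg A [de_config()]; `cfg$min_detected_reps` sets the threshold.
#' @param scope `"any_condition"` (default) or `"all_samples"`.
#' @return The filtered [count_matrix()], gene order preserved.
#' @export
filter_min_detected <- function(cm, cfg = de_config(),
                                scope = c("any_condition", "all_samples")) {
  stopifnot(inherits(cm, "count_matrix"))
  scope <- match.arg(scope)
  k <- cfg$min_detected_reps
  detected <- cm$counts > 0L
  if (scope == "any_condition") {
    by_cond <- vapply(split(seq_len(ncol(detected)), cm$samples$condition),
                      function(j) rowSums(detected[, j, drop = FALSE]),
                      numeric(nrow(detected)))
    keep <- apply(by_cond >= k, 1L, any)
  } else {
    keep <- rowSums(detected) >= k
  }
  if (!any(keep)) {
    stop("detection filter removed every gene (min_detected_reps = ", k, ")",
         call. = FALSE)
  }
  count_matrix(cm$counts[keep, , drop = FALSE], cm$samples)
}
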