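# All pipeline tables are UTF-8 TSV with a header row, '.' decimal
# separator, NA as empty field, gene id in the first column.

read_tsv_checked <- function(path, what = "table") {
  if (!file.exists(path)) {
    stop(what, " file not found: ", path, call. = FALSE)
  }
  utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                    na.strings = "", check.names = FALSE,
                    stringsAsFactors = FALSE, comment.char = "")
}

write_tsv <- function(x, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(x, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# data line number of row i (header is line 1)
stop_at_line <- function(path, i, msg) {
  stop(path, ", line ", i + 1L, ": ", msg, call. = FALSE)
}

check_unique_ids <- function(ids, path) {
  d <- which(duplicated(ids))
  if (length(d)) {
    stop_at_line(path, d[1],
                 paste0("duplicated gene id '", ids[d[1]], "'"))
  }
}

#' Read a count matrix and its sample sheet
#'
#' @param counts_path TSV, first column gene id, remaining columns one per
#'   sample (integer counts).
#' @param samples_path TSV with columns sample_id, condition, tissue,
#'   replicate.
#' @return A [count_matrix()].
#' @export
read_counts <- function(counts_path, samples_path) {
  tab <- read_tsv_checked(counts_path, "count matrix")
  if (ncol(tab) < 2L) {
    stop(counts_path, ": need a gene-id column plus >= 1 sample column",
         call. = FALSE)
  }
  ids <- as.character(tab[[1]])
  check_unique_ids(ids, counts_path)
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(tab[-1], is.numeric, logical(1)))[1]
    stop(counts_path, ": sample column '", names(tab[-1])[bad],
         "' is not numeric", call. = FALSE)
  }
  nonint <- which(rowSums(m != round(m) | m < 0 | !is.finite(m)) > 0)
  if (length(nonint)) {
    stop_at_line(counts_path, nonint[1],
                 "counts must be non-negative integers")
  }
  rownames(m) <- ids
  samples <- read_tsv_checked(samples_path, "sample sheet")
  count_matrix(m, samples)
}

#' Write a count matrix (and sample sheet) to TSV
#'
#' @param cm A [count_matrix()].
#' @param counts_path,samples_path Output paths.
#' @return The counts path, invisibly.
#' @export
write_counts <- function(cm, counts_path, samples_path) {
  stopifnot(inherits(cm, "count_matrix"))
  tab <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(tab, counts_path)
  write_tsv(cm$samples, samples_path)
  invisible(counts_path)
}

# DESeq2-convention result columns accepted on input
deseq2_column_map <- c(log2FoldChange = "log2fc", pvalue = "pvalue",
                       padj = "padj", baseMean = "base_mean")

#' Read a differential-expression contrast table
#'
#' Accepts this package's own contrast exports as well as DESeq2-style
#' results tables: columns `log2FoldChange`, `pvalue`, `padj` (and
#' `baseMean`) are mapped automatically onto the internal names `log2fc`,
#' `pvalue`, `padj`, `base_mean`. The sDEG and high-regulation flags are
#' recomputed from `cfg` when absent.
#'
#' @param path TSV path; first column gene id.
#' @param cfg A [de_config()] supplying `sdeg_alpha` and
#'   `high_lfc_threshold` for flag computation.
#' @return Contrast data.frame (gene_id, log2fc, pvalue, padj, is_sdeg,
#'   is_high, plus any extra columns present).
#' @export
read_contrast <- function(path, cfg = de_config()) {
  tab <- read_tsv_checked(path, "contrast")
  names(tab)[1] <- "gene_id"
  hit <- names(tab) %in% names(deseq2_column_map)
  names(tab)[hit] <- deseq2_column_map[names(tab)[hit]]
  tab$gene_id <- as.character(tab$gene_id)
  check_unique_ids(tab$gene_id, path)
  for (col in c("log2fc", "pvalue", "padj")) {
    if (!col %in% names(tab)) {
      stop(path, ": missing required column '", col,
           "' (or its DESeq2 equivalent)", call. = FALSE)
    }
    if (!is.numeric(tab[[col]])) {
      stop(path, ": column '", col, "' is not numeric", call. = FALSE)
    }
  }
  if (!"is_sdeg" %in% names(tab)) {
    tab$is_sdeg <- !is.na(tab$padj) & tab$padj < cfg$sdeg_alpha
  } else {
    tab$is_sdeg <- as.logical(tab$is_sdeg)
  }
  if (!"is_high" %in% names(tab)) {
    tab$is_high <- tab$is_sdeg & !is.na(tab$log2fc) &
      abs(tab$log2fc) > cfg$high_lfc_threshold
  } else {
    tab$is_high <- as.logical(tab$is_high)
  }
  tab
}

#' Write a contrast table to TSV
#'
#' @param contrast Contrast data.frame.
#' @param path Output path.
#' @export
write_contrast <- function(contrast, path) {
  write_tsv(contrast, path)
}

#' Read a gene-to-BIN functional annotation
#'
#' Two-column TSV (gene_id, bin_path); a gene may appear on several lines
#' (one per BIN). Compatible with Mercator exports after reducing them to
#' these two columns.
#'
#' @param path TSV path.
#' @return Data frame with gene_id, bin_path (duplicated pairs collapsed).
#' @export
read_annotation <- function(path) {
  tab <- read_tsv_checked(path, "annotation")
  if (ncol(tab) < 2L) {
    stop(path, ": need two columns (gene_id, bin_path)", call. = FALSE)
  }
  out <- data.frame(gene_id = as.character(tab[[1]]),
                    bin_path = as.character(tab[[2]]),
                    stringsAsFactors = FALSE)
  empty <- which(is.na(out$bin_path) | !nzchar(out$bin_path))
  if (length(empty)) {
    stop_at_line(path, empty[1], "empty bin_path")
  }
  out <- out[!duplicated(out[c("gene_id", "bin_path")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a gene-to-BIN annotation
#' @param annotation Data frame with gene_id, bin_path.
#' @param path Output path.
#' @export
write_annotation <- function(annotation, path) {
  write_tsv(annotation[c("gene_id", "bin_path")], path)
}

#' Read a curated gene list
#'
#' Plain text, one gene id per line; `#` starts a comment (full line or
#' trailing); blank lines ignored.
#'
#' @param path File path.
#' @param name Set name; defaults to the file name without extension.
#' @return A [gene_set()].
#' @export
read_gene_list <- function(path, name = NULL) {
  if (!file.exists(path)) {
    stop("gene list file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  ids <- lines[nzchar(lines)]
  if (is.null(name)) {
    name <- sub("\\.[^.]*$", "", basename(path))
  }
  gene_set(name, ids, provenance = paste0("curated list from ", path))
}

#' Write a gene list
#' @param set A [gene_set()].
#' @param path Output path.
#' @export
write_gene_list <- function(set, path) {
  stopifnot(inherits(set, "gene_set"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  writeLines(c(paste0("# ", set$name), set$members), path)
  invisible(path)
}

#' Write an interaction-classification table
#' @param calls A [classify_table()] result.
#' @param path Output path.
#' @export
write_classification <- function(calls, path) {
  out <- calls
  out$label <- as.character(out$label)
  out$sign_combination <- as.character(out$sign_combination)
  write_tsv(out, path)
}

#' Read an interaction-classification table
#' @param path TSV written by [write_classification()].
#' @return Data frame with factor label / sign_combination columns restored.
#' @export
read_classification <- function(path) {
  tab <- read_tsv_checked(path, "classification")
  tab$label <- factor(tab$label, levels = interaction_labels)
  tab$sign_combination <- factor(
    tab$sign_combination,
    levels = c("both_negative", "both_positive", "H_neg_S_pos",
               "H_pos_S_neg", "contains_zero")
  )
  tab
}

#' Read a run configuration
#'
#' YAML file with a flat key hierarchy: top-level `paths` (counts,
#' sample_sheet, annotation, gene_lists, output_dir), `de` (any
#' [de_config()] field), `classifier` (any [classifier_config()] field),
#' `universes` (list of [universe_spec()] field sets), `enrichment`
#' (min_bin_size, level), and `seed`. Missing sections fall back to the
#' package defaults; referenced input paths must exist.
#'
#' @param path YAML file path.
#' @return List with elements `paths`, `de` (a `de_config`), `classifier`
#'   (a `classifier_config`), `universes` (list of `universe_spec`),
#'   `enrichment`, `seed`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  paths <- raw$paths %||% list()
  for (key in setdiff(names(paths), "output_dir")) {
    for (p in unlist(paths[[key]])) {
      if (!file.exists(p)) {
        stop(path, ": paths$", key, " refers to a missing file: ", p,
             call. = FALSE)
      }
    }
  }
  list(
    paths = paths,
    de = do.call(de_config, raw$de %||% list()),
    classifier = do.call(classifier_config, raw$classifier %||% list()),
    universes = lapply(raw$universes %||% list(),
                       function(u) do.call(universe_spec, u)),
    enrichment = raw$enrichment %||% list(min_bin_size = 5L, level = NULL),
    seed = raw$seed %||% 1L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write simulated experiment inputs to a directory
#'
#' Writes, per tissue, `counts_<tissue>.tsv` and `truth_<tissue>.tsv`, plus
#' a combined `sample_sheet.tsv` and one `annotation.tsv` — everything the
#' pipeline needs to run from files alone.
#'
#' @param sim A [simulate_experiment()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_experiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sheets <- list()
  for (tissue in names(sim)) {
    cm <- sim[[tissue]]$counts
    write_counts(cm, file.path(dir, paste0("counts_", tissue, ".tsv")),
                 file.path(dir, paste0("samples_", tissue, ".tsv")))
    write_tsv(sim[[tissue]]$truth,
              file.path(dir, paste0("truth_", tissue, ".tsv")))
    sheets[[tissue]] <- cm$samples
  }
  write_tsv(do.call(rbind, sheets), file.path(dir, "sample_sheet.tsv"))
  truth1 <- sim[[1]]$truth
  write_annotation(truth1[c("gene_id", "bin_path")],
                   file.path(dir, "annotation.tsv"))
  invisible(dir)
}
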