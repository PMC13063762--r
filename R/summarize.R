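#' Summarize interaction classes
#'
#' Counts and percentages of additive / enhanced / divergent calls, overall
#' and per sign combination of the single-stress responses.
#'
#' @param calls A [classify_table()] result.
#' @param universe_name Label recorded in the output (default "universe").
#' @param tissue Optional tissue label recorded in the output.
#' @return List with `classes` (data.frame: universe, tissue, label, n,
#'   percent) and `sign_combinations` (data.frame: sign_combination, label,
#'   n). Percentages are exact fractions x 100; print with one decimal.
#' @export
summarize_classes <- function(calls, universe_name = "universe",
                              tissue = NA_character_) {
  n_total <- nrow(calls)
  tab <- table(calls$label)
  classes <- data.frame(
    universe = universe_name,
    tissue = tissue,
    label = names(tab),
    n = as.integer(tab),
    percent = 100 * as.integer(tab) / n_total,
    stringsAsFactors = FALSE
  )
  sc <- as.data.frame(table(calls$sign_combination, calls$label),
                      stringsAsFactors = FALSE)
  names(sc) <- c("sign_combination", "label", "n")
  list(classes = classes, sign_combinations = sc)
}

#' Per-pathway class breakdown
#'
#' Splits classified genes by top-level functional category (BIN-path prefix
#' at `depth`) and tabulates interaction-class counts and percentages per
#' pathway, mirroring per-pathway additive/enhanced/divergent breakdowns.
#'
#' @param calls A [classify_table()] result.
#' @param annotation Data frame gene_id, bin_path.
#' @param depth Hierarchy depth to roll annotation up to (default 1).
#' @return Data.frame: pathway, label, n, percent (within pathway).
#' @export
summarize_pathways <- function(calls, annotation, depth = 1L) {
  ann <- rollup_bins(annotation, depth)
  ann <- ann[ann$gene_id %in% calls$gene_id, , drop = FALSE]
  if (!nrow(ann)) {
    stop("annotation covers none of the classified genes", call. = FALSE)
  }
  merged <- merge(ann, calls[c("gene_id", "label")], by = "gene_id")
  tab <- as.data.frame(table(merged$bin_path, merged$label),
                       stringsAsFactors = FALSE)
  names(tab) <- c("pathway", "label", "n")
  totals <- stats::ave(tab$n, tab$pathway, FUN = sum)
  tab$percent <- ifelse(totals > 0, 100 * tab$n / totals, 0)
  tab[order(tab$pathway, tab$label), ]
}

#' Scatter-ready export of observed vs expected combined response
#'
#' One row per classified gene: the observed combined log2FC against the
#' back-transformed log2FC of the additive expectation, with class label and
#' sign-combination symbol — everything needed to render the
#' observed-vs-expected scatter from the file alone.
#'
#' @param calls A [classify_table()] result.
#' @return Data.frame: gene_id, log2fc_hs (y), log2fc_expected (x), label,
#'   sign_combination.
#' @export
scatter_table <- function(calls) {
  data.frame(
    gene_id = calls$gene_id,
    log2fc_hs = calls$log2fc_hs,
    log2fc_expected = calls$log2fc_sum_backtransformed,
    label = as.character(calls$label),
    sign_combination = as.character(calls$sign_combination),
    stringsAsFactors = FALSE
  )
}

#' Run the full analysis pipeline on one tissue's count matrix
#'
#' Detection filter, normalization, the three stress-vs-control contrasts,
#' sDEG sets and Venn partition, interaction classification over the
#' configured universes, BIN enrichment of the combined contrast, and the
#' summary tables. This is the programmatic equivalent of running the
#' numbered analysis scripts in order, and the single entry point used by
#' the acceptance script.
#'
#' @param cm A [count_matrix()] (one tissue).
#' @param annotation Optional BIN annotation (gene_id, bin_path); enables
#'   the enrichment stage and pathway summaries.
#' @param universes Named list of [universe_spec()]s to classify; default
#'   all HS sDEGs plus highly regulated HS sDEGs.
#' @param de_cfg A [de_config()].
#' @param cls_cfg A [classifier_config()].
#' @param venn_require_high Apply the |log2FC| high-regulation filter to the
#'   Venn sDEG sets (default FALSE; both filterings are legitimate).
#' @param enrich_min_bin_size,enrich_level Passed to [bin_test()].
#' @return List of class `costress_result`: `contrasts`, `venn`, `universes`
#'   (resolved ids), `classifications`, `summaries`, `pathways`,
#'   `enrichment`, `scatter`, `pca`, `filtered` (the filtered matrix).
#' @export
run_pipeline <- function(cm, annotation = NULL,
                         universes = list(
                           all_hs_sdegs = universe_spec("all_hs_sdegs"),
                           high_hs_sdegs = universe_spec("high_hs_sdegs")
                         ),
                         de_cfg = de_config(),
                         cls_cfg = classifier_config(),
                         venn_require_high = FALSE,
                         enrich_min_bin_size = 5L, enrich_level = 1L) {
  stopifnot(inherits(cm, "count_matrix"))
  tissue <- cm$samples$tissue[1]

  filtered <- filter_min_detected(cm, de_cfg)
  contrasts <- contrast_all(filtered, cfg = de_cfg)
  pca <- log_pca(filtered, n_components = 2L)

  sets <- lapply(c("S", "H", "HS"), function(cond) {
    build_sdeg_set(contrasts[[cond]], cond, require_high = venn_require_high)
  })
  venn <- venn_partition(sets[[1]], sets[[2]], sets[[3]])

  classifications <- list()
  summaries <- list()
  scatters <- list()
  resolved <- list()
  for (uname in names(universes)) {
    ids <- tryCatch(
      select_universe(universes[[uname]], contrasts = contrasts,
                      partition = venn, annotation = annotation),
      warning = function(w) character(0)
    )
    resolved[[uname]] <- ids
    if (!length(ids)) next
    calls <- classify_table(contrasts$H, contrasts$S, contrasts$HS,
                            universe = ids, cfg = cls_cfg)
    classifications[[uname]] <- calls
    summaries[[uname]] <- summarize_classes(calls, uname, tissue)
    scatters[[uname]] <- scatter_table(calls)
  }

  pathways <- NULL
  enrichment <- NULL
  if (!is.null(annotation)) {
    enrichment <- bin_test(contrasts$HS[c("gene_id", "log2fc")], annotation,
                           min_bin_size = enrich_min_bin_size,
                           level = enrich_level)
    first <- names(classifications)[1]
    if (!is.null(first)) {
      pathways <- summarize_pathways(classifications[[first]], annotation)
    }
  }

  structure(
    list(tissue = tissue, filtered = filtered, contrasts = contrasts,
         pca = pca, venn = venn, universes = resolved,
         classifications = classifications, summaries = summaries,
         scatter = scatters, pathways = pathways, enrichment = enrichment),
    class = "costress_result"
  )
}

#' Write every pipeline output table to a directory
#'
#' Produces `summary_classes.tsv`, `summary_pathways.tsv`,
#' `venn_regions.tsv`, `enrichment.tsv`, and per-universe
#' `classification_<universe>.tsv` / `scatter_<universe>.tsv`, plus the
#' per-contrast DE tables.
#'
#' @param result A [run_pipeline()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_pipeline_result <- function(result, dir) {
  stopifnot(inherits(result, "costress_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (cond in names(result$contrasts)) {
    write_contrast(result$contrasts[[cond]],
                   file.path(dir, paste0("de_", cond, ".tsv")))
  }
  write_tsv(result$venn$summary, file.path(dir, "venn_regions.tsv"))
  if (length(result$summaries)) {
    write_tsv(do.call(rbind, lapply(result$summaries, `[[`, "classes")),
              file.path(dir, "summary_classes.tsv"))
  }
  if (!is.null(result$pathways)) {
    write_tsv(result$pathways, file.path(dir, "summary_pathways.tsv"))
  }
  if (!is.null(result$enrichment)) {
    write_tsv(result$enrichment, file.path(dir, "enrichment.tsv"))
  }
  for (uname in names(result$classifications)) {
    write_classification(result$classifications[[uname]],
                         file.path(dir, paste0("classification_", uname,
                                               ".tsv")))
    write_tsv(result$scatter[[uname]],
              file.path(dir, paste0("scatter_", uname, ".tsv")))
  }
  invisible(dir)
}

#' @export
print.costress_result <- function(x, ...) {
  cat("costress pipeline result (tissue:", x$tissue, ")\n")
  cat("  genes after detection filter:", nrow(x$filtered$counts), "\n")
  for (cond in names(x$contrasts)) {
    cat("  sDEGs ", cond, ": ", sum(x$contrasts[[cond]]$is_sdeg), "\n",
        sep = "")
  }
  for (uname in names(x$summaries)) {
    cl <- x$summaries[[uname]]$classes
    cat("  ", uname, ": ",
        paste(sprintf("%s %.1f%%", cl$label, cl$percent), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}
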