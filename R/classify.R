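#' Sign combination of the two single-stress responses
#'
#' Scatter plots of observed vs expected log2FC mark each gene by the signs
#' of its single-stress responses (circle: both negative; square: both
#' positive; plus: H negative, S positive; cross: H positive, S negative).
#' Genes where either single-stress log2FC is exactly zero fall in none of
#' those four quadrants and are reported as `contains_zero`.
#'
#' @param log2fc_h,log2fc_s Numeric vectors of single-stress log2 fold
#'   changes.
#' @return Factor with levels both_negative, both_positive, H_neg_S_pos,
#'   H_pos_S_neg, contains_zero.
#' @export
sign_combination <- function(log2fc_h, log2fc_s) {
  sh <- sign(log2fc_h)
  ss <- sign(log2fc_s)
  out <- rep("contains_zero", length(sh))
  out[sh < 0 & ss < 0] <- "both_negative"
  out[sh > 0 & ss > 0] <- "both_positive"
  out[sh < 0 & ss > 0] <- "H_neg_S_pos"
  out[sh > 0 & ss < 0] <- "H_pos_S_neg"
  factor(out, levels = c("both_negative", "both_positive",
                         "H_neg_S_pos", "H_pos_S_neg", "contains_zero"))
}

#' Classify genes by their combined-stress interaction
#'
#' Full per-gene record of the interaction analysis: the three log2FCs are
#' converted to signed linear fold changes, then to percent expression change
#' (pEX); the combined pEX is compared against the additive expectation
#' pEX(H) + pEX(S) and labelled additive / enhanced / divergent (see
#' [classify_interaction()]). The expectation is also back-transformed to the
#' log2FC axis for plotting.
#'
#' Vectorized: the three inputs are recycled to a common length like ordinary
#' arithmetic (scalars broadcast).
#'
#' @param log2fc_h,log2fc_s,log2fc_hs Numeric vectors of finite log2 fold
#'   changes for hypoxia, salt and combined hypoxia-salt versus control.
#' @param cfg A [classifier_config()].
#' @return A data.frame with columns `log2fc_h`, `log2fc_s`, `log2fc_hs`,
#'   `pex_h`, `pex_s`, `pex_hs`, `pex_sum`, `deviation`, `label`,
#'   `sign_combination`, `log2fc_sum_backtransformed`.
#' @examples
#' classify_gene(1, 1, 1.5)$label    # additive
#' classify_gene(-1, -1, -2)$label   # divergent (stronger joint repression)
#' @export
classify_gene <- function(log2fc_h, log2fc_s, log2fc_hs,
                          cfg = classifier_config()) {
  stopifnot(inherits(cfg, "classifier_config"))
  n <- max(length(log2fc_h), length(log2fc_s), length(log2fc_hs))
  log2fc_h <- rep_len(as.numeric(log2fc_h), n)
  log2fc_s <- rep_len(as.numeric(log2fc_s), n)
  log2fc_hs <- rep_len(as.numeric(log2fc_hs), n)

  pex_h <- percent_change(signed_fold_change(log2fc_h))
  pex_s <- percent_change(signed_fold_change(log2fc_s))
  pex_hs <- percent_change(signed_fold_change(log2fc_hs))
  pex_sum <- additive_expectation(pex_h, pex_s)

  data.frame(
    log2fc_h = log2fc_h,
    log2fc_s = log2fc_s,
    log2fc_hs = log2fc_hs,
    pex_h = pex_h,
    pex_s = pex_s,
    pex_hs = pex_hs,
    pex_sum = pex_sum,
    deviation = pex_hs - pex_sum,
    label = classify_interaction(pex_hs, pex_sum, cfg),
    sign_combination = sign_combination(log2fc_h, log2fc_s),
    log2fc_sum_backtransformed = backtransform_pex(pex_sum),
    stringsAsFactors = FALSE
  )
}

#' Classify a gene universe from three contrast tables
#'
#' Joins the hypoxia, salt and combined contrasts on gene id, restricts to
#' `universe`, and classifies every gene for which all three log2FCs are
#' available and finite. Genes missing from any contrast (or with a missing
#' log2FC) are excluded — never imputed — and reported via the `dropped`
#' attribute.
#'
#' @param contrast_h,contrast_s,contrast_hs Data frames with at least
#'   `gene_id` and `log2fc` columns (e.g. from [naive_contrast()] or
#'   [read_contrast()]). Gene ids must be unique within each table.
#' @param universe Character vector of gene ids to classify. Defaults to the
#'   intersection of the three tables.
#' @param cfg A [classifier_config()].
#' @return A data.frame (one row per classified gene, `gene_id` first,
#'   then the [classify_gene()] columns) with attributes:
#'   * `dropped` — character vector of universe genes that could not be
#'     classified;
#'   * `class_counts` — named integer vector over the three labels;
#'   * `class_fractions` — the counts divided by the number classified.
#' @export
classify_table <- function(contrast_h, contrast_s, contrast_hs,
                           universe = NULL, cfg = classifier_config()) {
  tabs <- list(H = contrast_h, S = contrast_s, HS = contrast_hs)
  for (nm in names(tabs)) {
    tb <- tabs[[nm]]
    if (!is.data.frame(tb) || !all(c("gene_id", "log2fc") %in% names(tb))) {
      stop("contrast ", nm, " must be a data.frame with gene_id and log2fc",
           call. = FALSE)
    }
    dup <- unique(tb$gene_id[duplicated(tb$gene_id)])
    if (length(dup)) {
      stop("duplicated gene id(s) in contrast ", nm, ": ",
           paste(utils::head(dup, 5L), collapse = ", "), call. = FALSE)
    }
  }
  if (is.null(universe)) {
    universe <- Reduce(intersect, lapply(tabs, function(tb) tb$gene_id))
  }
  universe <- unique(as.character(universe))
  if (!length(universe)) {
    stop("empty gene universe: nothing to classify", call. = FALSE)
  }

  lfc <- lapply(tabs, function(tb) {
    tb$log2fc[match(universe, tb$gene_id)]
  })
  ok <- is.finite(lfc$H) & is.finite(lfc$S) & is.finite(lfc$HS)
  dropped <- universe[!ok]
  if (!any(ok)) {
    stop("no universe gene has a finite log2fc in all three contrasts",
         call. = FALSE)
  }

  calls <- classify_gene(lfc$H[ok], lfc$S[ok], lfc$HS[ok], cfg)
  calls <- cbind(gene_id = universe[ok], calls, stringsAsFactors = FALSE)
  rownames(calls) <- NULL

  counts <- table(calls$label)
  counts <- stats::setNames(as.integer(counts), names(counts))
  attr(calls, "dropped") <- dropped
  attr(calls, "class_counts") <- counts
  attr(calls, "class_fractions") <- counts / nrow(calls)
  calls
}
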