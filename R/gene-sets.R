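#' Named gene set
#'
#' @param name Nonempty set name.
#' @param members Character vector of gene ids; duplicates removed.
#' @param provenance Free-text description of how the set was built.
#' @return List of class `gene_set` with elements name, members, provenance.
#' @export
gene_set <- function(name, members, provenance = "") {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("`name` must be a nonempty string", call. = FALSE)
  }
  structure(
    list(name = name,
         members = unique(as.character(members)),
         provenance = provenance),
    class = "gene_set"
  )
}

#' @export
print.gene_set <- function(x, ...) {
  cat("gene_set '", x$name, "': ", length(x$members), " genes",
      if (nzchar(x$provenance)) paste0(" (", x$provenance, ")"), "\n",
      sep = "")
  invisible(x)
}

#' Build an sDEG set from a contrast table
#'
#' @param contrast Contrast data.frame with `gene_id`, `log2fc`, `is_sdeg`,
#'   `is_high` columns.
#' @param name Set name (e.g. `"HS"`).
#' @param direction `"both"` (default), `"up"` (log2fc > 0) or `"down"`.
#' @param require_high If `TRUE`, keep only highly regulated sDEGs
#'   (`is_high`).
#' @return A [gene_set()]. An empty selection is allowed, with a warning.
#' @export
build_sdeg_set <- function(contrast, name,
                           direction = c("both", "up", "down"),
                           require_high = FALSE) {
  direction <- match.arg(direction)
  need <- c("gene_id", "log2fc", "is_sdeg", "is_high")
  if (!all(need %in% names(contrast))) {
    stop("contrast table must contain ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  keep <- contrast$is_sdeg
  if (direction == "up") keep <- keep & contrast$log2fc > 0
  if (direction == "down") keep <- keep & contrast$log2fc < 0
  if (require_high) keep <- keep & contrast$is_high
  members <- contrast$gene_id[keep %in% TRUE]
  if (!length(members)) {
    warning("sDEG set '", name, "' is empty", call. = FALSE)
  }
  gene_set(name, members,
           provenance = paste0("sDEG, direction=", direction,
                               if (require_high) ", high-regulation only"))
}

#' Three-way Venn partition of sDEG sets
#'
#' Splits the union of three gene sets into the 7 disjoint regions of a
#' three-set Venn diagram.
#'
#' @param set_s,set_h,set_hs [gene_set()]s for salt, hypoxia, and combined
#'   hypoxia-salt.
#' @return List of class `venn_partition` with:
#'   * `regions` — named list of 7 character vectors (`S_only`, `H_only`,
#'     `HS_only`, `S_H`, `S_HS`, `H_HS`, `S_H_HS`);
#'   * `summary` — data.frame of region, size, fraction_of_union;
#'   * `sets` — the input member vectors.
#' @export
venn_partition <- function(set_s, set_h, set_hs) {
  stopifnot(inherits(set_s, "gene_set"), inherits(set_h, "gene_set"),
            inherits(set_hs, "gene_set"))
  s <- set_s$members; h <- set_h$members; hs <- set_hs$members
  triple <- intersect(intersect(s, h), hs)
  regions <- list(
    S_only = setdiff(s, union(h, hs)),
    H_only = setdiff(h, union(s, hs)),
    HS_only = setdiff(hs, union(s, h)),
    S_H = setdiff(intersect(s, h), hs),
    S_HS = setdiff(intersect(s, hs), h),
    H_HS = setdiff(intersect(h, hs), s),
    S_H_HS = triple
  )
  union_n <- length(union(union(s, h), hs))
  sizes <- lengths(regions)
  structure(
    list(regions = regions,
         summary = data.frame(
           region = names(regions),
           size = as.integer(sizes),
           fraction_of_union = if (union_n) sizes / union_n else
             rep(0, length(regions)),
           row.names = NULL,
           stringsAsFactors = FALSE
         ),
         sets = list(S = s, H = h, HS = hs)),
    class = "venn_partition"
  )
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("venn_partition over", sum(x$summary$size), "genes:\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Specify a gene universe for interaction classification
#'
#' @param mode One of:
#'   * `"all_hs_sdegs"` — every sDEG of the HS contrast;
#'   * `"high_hs_sdegs"` — HS sDEGs with `is_high`;
#'   * `"unique_hs"` — the HS-only Venn region;
#'   * `"bin_subset"` — genes whose functional BIN path starts with
#'     `bin_prefix`;
#'   * `"curated_list"` — an explicit gene list (intersected with the data).
#' @param bin_prefix BIN-path prefix, required for `"bin_subset"`.
#' @param genes Character vector of gene ids, required for `"curated_list"`.
#' @return List of class `universe_spec`.
#' @export
universe_spec <- function(mode = c("all_hs_sdegs", "high_hs_sdegs",
                                   "unique_hs", "bin_subset",
                                   "curated_list"),
                          bin_prefix = NULL, genes = NULL) {
  mode <- match.arg(mode)
  if (mode == "bin_subset" &&
      (is.null(bin_prefix) || !nzchar(bin_prefix[1]))) {
    stop("mode 'bin_subset' requires a nonempty `bin_prefix`", call. = FALSE)
  }
  if (mode == "curated_list" && is.null(genes)) {
    stop("mode 'curated_list' requires `genes`", call. = FALSE)
  }
  structure(list(mode = mode, bin_prefix = bin_prefix, genes = genes),
            class = "universe_spec")
}

#' Resolve a universe specification to a gene-id set
#'
#' @param spec A [universe_spec()].
#' @param contrasts Named list of contrast tables (needs `HS` for the sDEG
#'   modes).
#' @param partition A [venn_partition()] (needed for `"unique_hs"`).
#' @param annotation BIN annotation data.frame (`gene_id`, `bin_path`;
#'   needed for `"bin_subset"`).
#' @return Character vector of gene ids. For `"curated_list"`, genes absent
#'   from the HS contrast are dropped and reported via the `missing`
#'   attribute. Resolving to an empty set is an error naming the spec.
#' @export
select_universe <- function(spec, contrasts = NULL, partition = NULL,
                            annotation = NULL) {
  stopifnot(inherits(spec, "universe_spec"))
  out <- switch(
    spec$mode,
    all_hs_sdegs = {
      hs <- need_contrast(contrasts, "HS")
      hs$gene_id[hs$is_sdeg %in% TRUE]
    },
    high_hs_sdegs = {
      hs <- need_contrast(contrasts, "HS")
      hs$gene_id[hs$is_high %in% TRUE]
    },
    unique_hs = {
      if (!inherits(partition, "venn_partition")) {
        stop("mode 'unique_hs' needs a venn_partition", call. = FALSE)
      }
      partition$regions$HS_only
    },
    bin_subset = {
      if (is.null(annotation)) {
        stop("mode 'bin_subset' needs a BIN annotation", call. = FALSE)
      }
      hit <- startsWith(annotation$bin_path, spec$bin_prefix)
      if (!any(hit)) {
        stop("no annotated gene matches BIN prefix '", spec$bin_prefix, "'",
             call. = FALSE)
      }
      unique(annotation$gene_id[hit])
    },
    curated_list = {
      avail <- if (!is.null(contrasts) && !is.null(contrasts$HS)) {
        contrasts$HS$gene_id
      } else {
        spec$genes
      }
      present <- intersect(unique(spec$genes), avail)
      missing <- setdiff(unique(spec$genes), avail)
      attr(present, "missing") <- missing
      present
    }
  )
  if (!length(out)) {
    if (spec$mode == "unique_hs") {
      # an empty HS-only Venn region is a legitimate (if unusual) outcome
      warning("universe 'unique_hs' is empty: no gene is significant in HS ",
              "alone", call. = FALSE)
    } else {
      stop("universe spec '", spec$mode, "' resolved to an empty gene set",
           call. = FALSE)
    }
  }
  out
}

need_contrast <- function(contrasts, which) {
  if (is.null(contrasts) || is.null(contrasts[[which]])) {
    stop("this universe mode needs the '", which, "' contrast table",
         call. = FALSE)
  }
  contrasts[[which]]
}
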