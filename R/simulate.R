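#' Simulation configuration for the factorial stress experiment
#'
#' Defaults emulate the design of the motivating experiment: two tissues
#' (shoot, root), four conditions (C, S, H, HS), four replicates, and a
#' detected transcriptome of ~13,000 genes with negative-binomial counts.
#' Interaction classes are planted on the pEX scale, so the generator's
#' ground truth is self-consistent with the classifier by construction.
#'
#' @param n_genes Number of genes (default 13000).
#' @param replicates Replicates per condition (default 4).
#' @param tissues Tissues to simulate (default shoot and root).
#' @param fraction_de Probability that a gene responds to each single stress
#'   (independently; default 0.3, in line with the roughly 23-43% of
#'   detected genes called significant per single stress in comparable
#'   factorial stress experiments).
#' @param class_fractions Named or ordered numeric triple
#'   (additive, enhanced, divergent) for stress-responsive genes; must sum
#'   to 1. Default c(0.82, 0.09, 0.09).
#' @param effect_meanlog,effect_sdlog Lognormal parameters of the
#'   single-stress |log2FC| (default median 1.5 log2 units, sdlog 0.35).
#' @param tolerance Additive-band half-width used for planting (default 0.5,
#'   matching [classifier_config()]).
#' @param boundary_margin Minimum pEX distance of any planted deviation from
#'   the class boundary (default 0.1); must be < `tolerance`.
#' @param baseline_meanlog,baseline_sdlog Lognormal parameters of baseline
#'   mean expression (default median 100 counts, sdlog 1).
#' @param dispersion Negative-binomial dispersion (default 0.1; variance
#'   mu + dispersion * mu^2).
#' @param libsize_range Range of per-sample library-size factors, drawn
#'   uniformly (default 0.7-1.4).
#' @param bin_paths Synthetic functional-BIN hierarchy to assign genes to,
#'   round-robin; default 20 top categories x 5 subcategories.
#' @param shared_truth If `TRUE` all tissues share one truth table; default
#'   `FALSE` (independent truths per tissue).
#' @param seed Base seed; all randomness in [generate_truth()] /
#'   [generate_counts()] derives from it.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_genes = 13000L, replicates = 4L,
                       tissues = c("shoot", "root"),
                       fraction_de = 0.3,
                       class_fractions = c(additive = 0.82,
                                           enhanced = 0.09,
                                           divergent = 0.09),
                       effect_meanlog = log(1.5), effect_sdlog = 0.35,
                       tolerance = 0.5, boundary_margin = 0.1,
                       baseline_meanlog = log(100), baseline_sdlog = 1,
                       dispersion = 0.1, libsize_range = c(0.7, 1.4),
                       bin_paths = NULL, shared_truth = FALSE,
                       seed = 1L) {
  class_fractions <- as.numeric(class_fractions)
  if (length(class_fractions) != 3L || any(class_fractions < 0) ||
      abs(sum(class_fractions) - 1) > 1e-8) {
    stop("class_fractions must be 3 non-negative numbers summing to 1",
         call. = FALSE)
  }
  if (fraction_de < 0 || fraction_de > 1) {
    stop("fraction_de must lie in [0, 1]", call. = FALSE)
  }
  if (boundary_margin < 0 || boundary_margin >= tolerance) {
    stop("need 0 <= boundary_margin < tolerance (the additive band would ",
         "otherwise be empty)", call. = FALSE)
  }
  if (dispersion <= 0) stop("dispersion must be > 0", call. = FALSE)
  if (is.null(bin_paths)) {
    bin_paths <- as.vector(outer(sprintf("category_%02d", 1:20),
                                 sprintf("sub_%d", 1:5), paste, sep = "."))
  }
  structure(
    list(n_genes = as.integer(n_genes), replicates = as.integer(replicates),
         tissues = tissues, fraction_de = fraction_de,
         class_fractions = stats::setNames(class_fractions,
                                           c("additive", "enhanced",
                                             "divergent")),
         effect_meanlog = effect_meanlog, effect_sdlog = effect_sdlog,
         tolerance = tolerance, boundary_margin = boundary_margin,
         baseline_meanlog = baseline_meanlog,
         baseline_sdlog = baseline_sdlog,
         dispersion = dispersion, libsize_range = libsize_range,
         bin_paths = bin_paths, shared_truth = isTRUE(shared_truth),
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Generate a ground-truth table with planted interaction classes
#'
#' Each gene independently responds to each single stress with probability
#' `fraction_de`; responding genes get a log2FC with random sign and
#' lognormal magnitude. Genes responsive to at least one single stress are
#' assigned an interaction class by `class_fractions`, and their combined
#' pEX is planted as the additive expectation plus a class-specific offset:
#' within the additive band (at least `boundary_margin` from its edges) for
#' additive genes, in `(tolerance + margin, tolerance + margin + 2]` above
#' it for enhanced, and symmetrically below for divergent. Null genes have
#' all-zero log2FCs and are additive by definition. The planted label is
#' re-derived through [classify_gene()] before returning, so the table is
#' self-consistent with the classifier by construction.
#'
#' @param cfg A [sim_config()].
#' @param seed Seed override; defaults to `cfg$seed`.
#' @return Data frame with one row per gene: `gene_id`, `de_h`, `de_s`,
#'   `responsive`, `log2fc_h`, `log2fc_s`, `log2fc_hs`, `true_label`,
#'   `bin_path`.
#' @export
generate_truth <- function(cfg = sim_config(), seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed)
  n <- cfg$n_genes
  tol <- cfg$tolerance
  margin <- cfg$boundary_margin

  draw_effect <- function(active) {
    lfc <- numeric(n)
    k <- sum(active)
    lfc[active] <- sample(c(-1, 1), k, replace = TRUE) *
      stats::rlnorm(k, cfg$effect_meanlog, cfg$effect_sdlog)
    lfc
  }
  de_h <- stats::runif(n) < cfg$fraction_de
  de_s <- stats::runif(n) < cfg$fraction_de
  log2fc_h <- draw_effect(de_h)
  log2fc_s <- draw_effect(de_s)
  responsive <- de_h | de_s

  planted <- rep("additive", n)
  n_resp <- sum(responsive)
  planted[responsive] <- sample(names(cfg$class_fractions), n_resp,
                                replace = TRUE, prob = cfg$class_fractions)

  delta <- numeric(n)
  idx_add <- responsive & planted == "additive"
  idx_enh <- planted == "enhanced"
  idx_div <- planted == "divergent"
  delta[idx_add] <- stats::runif(sum(idx_add), -tol + margin, tol - margin)
  delta[idx_enh] <- stats::runif(sum(idx_enh), tol + margin, tol + margin + 2)
  delta[idx_div] <- stats::runif(sum(idx_div), -tol - margin - 2,
                                 -tol - margin)

  pex_sum <- additive_expectation(
    percent_change(signed_fold_change(log2fc_h)),
    percent_change(signed_fold_change(log2fc_s))
  )
  log2fc_hs <- backtransform_pex(pex_sum + delta)
  log2fc_hs[!responsive] <- 0

  truth <- data.frame(
    gene_id = sprintf("gene_%05d", seq_len(n)),
    de_h = de_h,
    de_s = de_s,
    responsive = responsive,
    log2fc_h = log2fc_h,
    log2fc_s = log2fc_s,
    log2fc_hs = log2fc_hs,
    true_label = planted,
    bin_path = rep_len(cfg$bin_paths, n),
    stringsAsFactors = FALSE
  )

  recomputed <- classify_gene(truth$log2fc_h, truth$log2fc_s,
                              truth$log2fc_hs,
                              classifier_config(tolerance = tol))$label
  if (!all(as.character(recomputed) == truth$true_label)) {
    stop("internal error: planted labels are not self-consistent",
         call. = FALSE)  # nocov
  }
  truth
}

#' Generate negative-binomial counts for one tissue
#'
#' Counts are drawn per gene and sample as NB(mu, size = 1/dispersion) with
#' mu = baseline * 2^log2FC(condition) * library factor; condition C uses
#' log2FC = 0. Baselines and library factors are drawn inside this function,
#' seeded by `cfg$seed` plus a tissue offset (its position in
#' `cfg$tissues`), so counts are reproducible and independent of the truth
#' stream.
#'
#' @param truth A [generate_truth()] table.
#' @param cfg The [sim_config()] used for the truth.
#' @param tissue Tissue label (must be one of `cfg$tissues`).
#' @return A [count_matrix()] with samples `<tissue>_<condition>_<rep>`.
#' @export
generate_counts <- function(truth, cfg = sim_config(),
                            tissue = cfg$tissues[1]) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- nrow(truth)  # force `truth` before touching the RNG stream
  t_idx <- match(tissue, cfg$tissues)
  if (is.na(t_idx)) {
    stop("tissue '", tissue, "' is not in cfg$tissues", call. = FALSE)
  }
  set.seed(cfg$seed + t_idx)
  conds <- c("C", "S", "H", "HS")
  reps <- cfg$replicates
  samples <- data.frame(
    sample_id = paste(tissue, rep(conds, each = reps),
                      rep(seq_len(reps), length(conds)), sep = "_"),
    condition = rep(conds, each = reps),
    tissue = tissue,
    replicate = rep(seq_len(reps), length(conds)),
    stringsAsFactors = FALSE
  )

  baseline <- stats::rlnorm(n, cfg$baseline_meanlog, cfg$baseline_sdlog)
  sf <- stats::runif(nrow(samples), cfg$libsize_range[1],
                     cfg$libsize_range[2])
  lfc_by_cond <- cbind(C = 0, S = truth$log2fc_s, H = truth$log2fc_h,
                       HS = truth$log2fc_hs)

  counts <- matrix(0L, n, nrow(samples),
                   dimnames = list(truth$gene_id, samples$sample_id))
  for (j in seq_len(nrow(samples))) {
    mu <- baseline * 2^lfc_by_cond[, samples$condition[j]] * sf[j]
    counts[, j] <- stats::rnbinom(n, mu = mu, size = 1 / cfg$dispersion)
  }
  count_matrix(counts, samples)
}

#' Simulate the full factorial experiment
#'
#' @param cfg A [sim_config()].
#' @return List of class `sim_experiment`: per tissue, a list with `truth`
#'   and `counts`. With `cfg$shared_truth` the same truth table underlies
#'   every tissue; otherwise each tissue draws its own (seeded
#'   `cfg$seed + 100 * tissue_index`).
#' @export
simulate_experiment <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  out <- lapply(seq_along(cfg$tissues), function(t_idx) {
    truth_seed <- if (cfg$shared_truth) cfg$seed else cfg$seed + 100L * t_idx
    truth <- generate_truth(cfg, seed = truth_seed)
    list(truth = truth,
         counts = generate_counts(truth, cfg, tissue = cfg$tissues[t_idx]))
  })
  structure(stats::setNames(out, cfg$tissues),
            class = "sim_experiment", config = cfg)
}
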