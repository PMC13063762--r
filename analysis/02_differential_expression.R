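#!/usr/bin/env Rscript
# Detection filtering, median-of-ratios normalization, and the three
# stress-vs-control contrasts per tissue (Welch test on log-normalized
# counts, BH-corrected; sDEG = padj < 0.01, high regulation = |log2FC| > 2).
# Also runs the log-PCA QC. Reads results/sim/, writes results/de/.

library(costress)

cfg <- de_config()
for (tissue in c("shoot", "root")) {
  cm <- read_counts(file.path("results/sim", paste0("counts_", tissue, ".tsv")),
                    file.path("results/sim", paste0("samples_", tissue, ".tsv")))
  cm <- filter_min_detected(cm, cfg)
  contrasts <- contrast_all(cm, cfg = cfg)
  for (cond in names(contrasts)) {
    write_contrast(contrasts[[cond]],
                   file.path("results/de",
                             sprintf("de_%s_%s.tsv", tissue, cond)))
    cat(sprintf("%s %s vs C: %d sDEGs (%d highly regulated)\n",
                tissue, cond, sum(contrasts[[cond]]$is_sdeg),
                sum(contrasts[[cond]]$is_high)))
  }
  pca <- log_pca(cm)
  qc <- data.frame(pca$samples, pca$scores)
  utils::write.table(qc, file.path("results/de",
                                   sprintf("pca_%s.tsv", tissue)),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s PCA: PC1 %.1f%%, PC2 %.1f%% of variance\n", tissue,
              100 * pca$variance_fraction[1], 100 * pca$variance_fraction[2]))
}
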