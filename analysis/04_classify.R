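#!/usr/bin/env Rscript
# The core question: is each gene's combined hypoxia-salt response additive,
# enhanced, or divergent relative to the sum of its single-stress responses?
# Classifies three universes per tissue (all HS sDEGs, highly regulated HS
# sDEGs, uniquely-HS sDEGs) and writes per-gene calls plus scatter-ready
# observed-vs-expected tables under results/classify/.

library(costress)

dir.create("results/classify", recursive = TRUE, showWarnings = FALSE)
cls <- classifier_config()  # tolerance 0.5 pEX, closed band, directional

for (tissue in c("shoot", "root")) {
  contrasts <- lapply(c(S = "S", H = "H", HS = "HS"), function(cond) {
    read_contrast(file.path("results/de",
                            sprintf("de_%s_%s.tsv", tissue, cond)))
  })
  venn <- venn_partition(build_sdeg_set(contrasts$S, "S"),
                         build_sdeg_set(contrasts$H, "H"),
                         build_sdeg_set(contrasts$HS, "HS"))
  universes <- list(all_hs_sdegs = universe_spec("all_hs_sdegs"),
                    high_hs_sdegs = universe_spec("high_hs_sdegs"),
                    unique_hs = universe_spec("unique_hs"))
  for (uname in names(universes)) {
    ids <- select_universe(universes[[uname]], contrasts, venn)
    if (!length(ids)) next
    calls <- classify_table(contrasts$H, contrasts$S, contrasts$HS,
                            universe = ids, cfg = cls)
    write_classification(calls,
                         file.path("results/classify",
                                   sprintf("classification_%s_%s.tsv",
                                           tissue, uname)))
    utils::write.table(scatter_table(calls),
                       file.path("results/classify",
                                 sprintf("scatter_%s_%s.tsv", tissue, uname)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    pct <- 100 * attr(calls, "class_fractions")
    cat(sprintf(
      "%s / %s (%d genes): additive %.1f%%, enhanced %.1f%%, divergent %.1f%%\n",
      tissue, uname, nrow(calls), pct["additive"], pct["enhanced"],
      pct["divergent"]))
  }
}
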