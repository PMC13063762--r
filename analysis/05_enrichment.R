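#!/usr/bin/env Rscript
# Functional-category (BIN) enrichment: per top-level category, a two-sided
# Wilcoxon rank-sum test of member log2FCs (HS vs control) against all other
# annotated genes, BH-corrected. Writes results/enrichment/.

library(costress)

dir.create("results/enrichment", recursive = TRUE, showWarnings = FALSE)
annotation <- read_annotation("results/sim/annotation.tsv")

for (tissue in c("shoot", "root")) {
  hs <- read_contrast(file.path("results/de",
                                sprintf("de_%s_HS.tsv", tissue)))
  res <- bin_test(hs[c("gene_id", "log2fc")], annotation, level = 1L)
  utils::write.table(res,
                     file.path("results/enrichment",
                               sprintf("enrichment_%s.tsv", tissue)),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s: %d categories tested, %d with padj < 0.05\n",
              tissue, nrow(res), sum(res$padj < 0.05)))
}
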