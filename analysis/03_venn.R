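#!/usr/bin/env Rscript
# Three-way overlap of the S / H / HS sDEG sets per tissue: how much of the
# combined-stress response is shared with, or unique beyond, the single
# stresses. Writes the 7-region partition tables under results/venn/.

library(costress)

dir.create("results/venn", recursive = TRUE, showWarnings = FALSE)
for (tissue in c("shoot", "root")) {
  contrasts <- lapply(c(S = "S", H = "H", HS = "HS"), function(cond) {
    read_contrast(file.path("results/de",
                            sprintf("de_%s_%s.tsv", tissue, cond)))
  })
  sets <- lapply(names(contrasts), function(cond) {
    build_sdeg_set(contrasts[[cond]], cond)
  })
  venn <- venn_partition(sets[[1]], sets[[2]], sets[[3]])
  utils::write.table(venn$summary,
                     file.path("results/venn",
                               sprintf("venn_regions_%s.tsv", tissue)),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cat(tissue, "sDEG overlap:\n")
  print(venn$summary, row.names = FALSE)
}
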