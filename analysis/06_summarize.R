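#!/usr/bin/env Rscript
# Summary tables mirroring the result structure of the analysis: interaction
# class counts/percentages per universe and tissue, the per-pathway class
# breakdown, the sign-combination breakdown, and a comparison of recovered
# vs planted class fractions on the simulated truth. Writes results/summary/.

library(costress)

dir.create("results/summary", recursive = TRUE, showWarnings = FALSE)
annotation <- read_annotation("results/sim/annotation.tsv")

class_rows <- list()
sign_rows <- list()
path_rows <- list()
recov_rows <- list()

for (tissue in c("shoot", "root")) {
  truth <- utils::read.delim(file.path("results/sim",
                                       sprintf("truth_%s.tsv", tissue)))
  for (uname in c("all_hs_sdegs", "high_hs_sdegs", "unique_hs")) {
    f <- file.path("results/classify",
                   sprintf("classification_%s_%s.tsv", tissue, uname))
    if (!file.exists(f)) next
    calls <- read_classification(f)
    s <- summarize_classes(calls, uname, tissue)
    class_rows[[paste(tissue, uname)]] <- s$classes
    sc <- s$sign_combinations
    sc$universe <- uname
    sc$tissue <- tissue
    sign_rows[[paste(tissue, uname)]] <- sc
    if (uname == "all_hs_sdegs") {
      pw <- summarize_pathways(calls, annotation)
      pw$tissue <- tissue
      path_rows[[tissue]] <- pw
      # recovered vs planted interaction-class fractions on this universe
      m <- merge(calls[c("gene_id", "label")],
                 truth[c("gene_id", "true_label")], by = "gene_id")
      recov_rows[[tissue]] <- data.frame(
        tissue = tissue,
        label = levels(m$label),
        planted_fraction = as.vector(prop.table(table(
          factor(m$true_label, levels = levels(m$label))))),
        recovered_fraction = as.vector(prop.table(table(m$label))),
        agreement = mean(as.character(m$label) == m$true_label)
      )
    }
  }
}

wt <- function(x, f) utils::write.table(do.call(rbind, x),
                                        file.path("results/summary", f),
                                        sep = "\t", quote = FALSE,
                                        row.names = FALSE)
wt(class_rows, "summary_classes.tsv")
wt(sign_rows, "summary_sign_combinations.tsv")
wt(path_rows, "summary_pathways.tsv")
wt(recov_rows, "recovery_vs_truth.tsv")

cat("interaction-class summary:\n")
print(do.call(rbind, class_rows), row.names = FALSE)
cat("\nrecovered vs planted (all HS sDEGs universe):\n")
print(do.call(rbind, recov_rows), row.names = FALSE)
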