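Package: costress
Title: Additive, Enhanced and Divergent Interaction Classification for
    Combined-Stress Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies each gene's transcriptional response to a combined
    stress (hypoxia plus salt) as additive, enhanced, or divergent relative
    to the sum of the single-stress responses, on a percent-expression-change
    (pEX) scale derived from signed linear fold changes. Includes a
    lightweight differential-expression stage (detection filtering,
    median-of-ratios normalization, Welch test on log-normalized counts,
    Benjamini-Hochberg correction), sDEG set construction with three-way
    Venn partitioning, MapMan-BIN-style rank-sum functional-category
    enrichment, a negative-binomial factorial-design simulator with planted
    interaction classes, and tab-separated readers and writers for every
    table the pipeline touches.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    jsonlite
Config/testthat/edition: 3
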