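---
title: "Classifying combined-stress transcriptional responses as additive, enhanced or divergent"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying combined-stress transcriptional responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(costress)
```

## The question and the statistic

When a plant experiences two stresses at once — here hypoxia (H) imposed on
top of salt (S), as happens to a halophyte submerged by a tide — its
transcriptional response need not be the sum of the single-stress
responses. For each gene with log2 fold changes `log2FC(H)`, `log2FC(S)`
and `log2FC(HS)` versus a common control, the package asks whether the
combined response is predictable from the single ones, on a linearized
scale:

1. **Signed fold change.** `FC = 2^log2FC` for up-regulation and
   `FC = -(2^|log2FC|)` for down-regulation, so `|FC| >= 1` always and
   `FC = -2` reads "halved". The open interval (-1, 1) does not exist on
   this scale.
2. **Percent expression change (pEX).** `pEX = FC - 1` for positive FC,
   `pEX = FC + 1` for negative FC. Doubling is +1 (+100%), halving is -1,
   no change is exactly 0. The negative branch is the unique choice that
   makes pEX continuous and sign-symmetric through zero; a naive
   `-(FC) + 1` with an unsigned FC magnitude gives the same values, which
   is how the two branches are usually written.
3. **Additive expectation.** `pEX(H+S) = pEX(H) + pEX(S)`.
4. **Classification.** With tolerance `t` (default 0.5 pEX units, i.e. half
   a linear fold-change unit):
   additive if `pEX(HS)` lies in the closed band `[pEX(H+S) - t,
   pEX(H+S) + t]`; *enhanced* if above; *divergent* if below.
5. **Back-transform.** For plotting, `pEX(H+S)` is mapped back to the
   log2FC axis (`backtransform_pex()`), so observed `log2FC(HS)` can be
   drawn against the expectation with the additive diagonal as reference.

The classification is **directional**: a jointly repressed gene whose
combined repression is *stronger* than the sum lies below the band and is
called divergent, even though its response is larger in magnitude.
Discussion-style readings that treat any larger-than-expected response as
"enhanced" correspond to the optional
`classifier_config(mode = "magnitude")`, which classifies on `|pEX|`; it is
provided for exploration and never used in the standard output. Boundary
ties are resolved by the closed interval exactly, with no epsilon fuzz:
deviation `== t` is additive, `t + 1e-12` is not.

## The pipeline around the statistic

**Detection filter.** A gene is kept when it has nonzero counts in at least
3 of the 4 replicates of at least one condition. The per-condition scope is
deliberately lenient so that genes expressed only under one stress survive;
a strict across-all-samples mode exists
(`filter_min_detected(scope = "all_samples")`).

**Normalization.** Median-of-ratios size factors
(`median_of_ratios()`): the reference is the per-gene geometric mean over
samples, computed over genes with strictly positive counts everywhere; each
sample's factor is the median ratio to that reference. The median is taken
in log space, which matches DESeq2's implementation exactly (geometric
rather than arithmetic interpolation when the number of reference genes is
even). A consequence worth knowing: scaling one sample's library by `c`
moves *ratios* of size factors by exactly `c`, while the factors themselves
absorb a common `c^(1/n)` through the reference.

**Differential expression.** `naive_contrast()` is an intentionally simple
stand-in for a negative-binomial GLM: log2FC is the log-ratio of mean
normalized counts (pseudocount 1), the p-value a Welch t-test on
`log2(normalized + 1)`, BH-adjusted per contrast. sDEGs are `padj < 0.01`;
highly regulated sDEGs additionally have `|log2FC| > 2`. Both thresholds
are parameters of `de_config()` (an FDR of 0.05 is the other conventional
choice; 0.01 is the operative default here because the downstream set and
interaction analyses are defined on it). Tables from dedicated DE tools are
first-class inputs: `read_contrast()` maps DESeq2-style columns
automatically, and everything downstream is agnostic to where the log2FCs
came from. No shrinkage is applied anywhere in this package; shrunk
estimates, if wanted, must come in via external tables.

**Gene universes.** Which genes to classify is a real analytical choice, so
it is explicit (`universe_spec()`): all HS sDEGs, highly regulated HS
sDEGs, the uniquely-HS Venn region, a functional-category subset by BIN
prefix, or a curated list. Genes missing a finite log2FC in any of the
three contrasts are dropped and reported, never imputed.

**Enrichment.** Per functional BIN, a two-sided Wilcoxon rank-sum test of
member log2FCs against all other annotated genes, BH-corrected across bins.
Unannotated genes stay out of the background; multi-BIN genes count in each
of their bins. The hierarchy level is a parameter (`level = 1` tests
top-level categories) because enrichment at leaf versus top level answers
different questions. The test is exact for small tie-free bins
(`n_in <= 25`, complement < 1000 — the second bound only caps the cost of
the exact distribution); otherwise the normal approximation with tie and
continuity correction is used.

## The simulator and what passing tests mean

`sim_config()` defaults emulate the motivating design: 2 tissues x 4
conditions x 4 replicates, 13,000 genes, NB dispersion 0.1, baseline means
lognormal with median 100, library factors in 0.7-1.4. Each gene responds
to each single stress with probability 0.3 (single-stress sDEG fractions in
comparable factorial experiments run roughly 23-43% of detected genes);
responses have random sign and lognormal magnitude with median 1.5 log2
units (sdlog 0.35, i.e. mostly 0.8-3 log2 units). Genes responsive to at
least one single stress receive an interaction class with probabilities
(0.82, 0.09, 0.09) — a realistic design point, not a reproduction target —
and their combined pEX is planted as the additive expectation plus an
offset that stays at least `boundary_margin` (default 0.1) away from the
class boundary. The planted label is re-derived through the classifier
before the truth table is returned, so truth and classifier cannot drift
apart. Tissues are independent draws by default (`shared_truth = TRUE`
links them), and genes DE in HS but in neither single stress are not
modelled, so the uniquely-HS Venn region of simulated data contains only
estimation noise.

Two recovery regimes must be kept apart when interpreting tests:

* **Noise-free**: feeding the *true* log2FCs into `classify_table()`
  recovers the planted labels gene-for-gene, exactly. This validates the
  statistic's algebra and is asserted at n = 5,000.
* **Noisy**: estimating log2FCs from counts first. At dispersion 0.1 with
  4 replicates the log2FC standard error is about 0.34 regardless of
  sequencing depth, and on the pEX scale that error is amplified by
  `ln(2) * 2^|log2FC|` — roughly 1 pEX unit for a typical planted effect,
  i.e. twice the half-band. Class fractions recovered from estimated
  log2FCs are therefore strongly biased toward the two unbounded classes
  (measured: additive 0.82 planted, ~0.3-0.4 recovered), symmetrically in
  enhanced/divergent, as expected for unbiased estimation noise around a
  closed band. This is a property of the statistic at this replication
  level, not of the implementation; any real analysis at n = 4 faces the
  same inflation of apparent non-additivity, which is one reason shrunk
  fold changes are attractive upstream. The package reports the recovery
  error openly (`analysis/06_summarize.R`, the acceptance script) rather
  than hiding it.

Features of real data the simulator does not attempt: gene-gene
correlation, condition-dependent dispersion, isoform structure, HS-only
responders, batch effects. Passing tests therefore demonstrate algebraic
correctness, calibration of the null tests, and honest propagation of
estimation noise — not biological realism.

## Numerical and design choices

* Tolerance 0.5 pEX and the closed interval follow the statistic's standard
  definition; both are configurable, and the boundary is tested at
  `+/- (t + 1e-12)`.
* Welch rather than equal-variance t: group variances after normalization
  are not equal by construction. Degenerate rows (zero variance in both
  groups) get p = 1 when means agree, else p = 0; all-zero rows are flagged
  `untestable` with log2FC 0 and p = 1.
* BH is `stats::p.adjust(method = "BH")`, applied per contrast and per
  enrichment run; tests pin it against a literal step-up implementation.
* PCA signs follow a fixed convention (largest-magnitude loading positive)
  so reruns are bit-identical.
* Seeds: `generate_truth()` seeds from `cfg$seed` (per-tissue offsets of
  +100, +200, ... when tissues are independent); `generate_counts()` from
  `cfg$seed` plus the tissue index, so the truth and count streams never
  interleave.
* Problem sizes in the test suite (up to 13,000 genes in the scripts,
  2,000-10,000 in tests, 3 seeds for the noisy-recovery property) were
  chosen to make Monte-Carlo assertions stable at interactive runtimes.

## Known limitations

The DE stage is a stand-in: it is well-calibrated under the null and
recovers planted effects with slope ~1, but it has less power than an NB
GLM at n = 4 and its unshrunk log2FCs inflate pEX-scale noise (see above).
The enrichment test assumes exchangeability across genes within a contrast,
ignoring inter-gene correlation, as the rank-sum-on-BINs approach always
does. The interaction statistic itself is per-gene and threshold-based; it
carries no uncertainty statement, so a gene just outside the band is
"enhanced" with no confidence attached — treat the class fractions as
descriptive, not inferential.
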