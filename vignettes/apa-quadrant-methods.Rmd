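---
title: "Methods: copy-number-driven APA analysis and its synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: copy-number-driven APA analysis and its synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apacnv)
```

## Overview

`apacnv` analyses genomic alterations of the 16 core cleavage and
polyadenylation (CPA) genes in a tumor cohort and their downstream
consequences: mutation landscape, copy-number landscape, amplification
co-occurrence between co-localized genes, copy-number-stratified survival,
and the central ΔPDUI analysis relating an index gene's copy number to
genome-wide alternative polyadenylation and expression. This vignette
documents the models, the parameters that matter, the numerical choices,
and what the synthetic cohort does and does not emulate.

## The ΔPDUI model

PDUI (percentage of distal poly(A) site usage index) is a per-gene,
per-sample value in [0, 1]; high PDUI means preferential distal poly(A)
site usage, i.e. a long 3′UTR. The pipeline asks whether samples with high
copy number of an index gene (default CPSF1, the polyadenylation-signal
recognition subunit) show systematic PDUI shifts:

1. **Confounder exclusion.** CPSF1 lies on 8q24 next to MYC and the two are
   frequently co-amplified. Samples non-diploid for the confounder gene are
   removed first, so any association cannot be carried by the neighbour's
   amplification.
2. **Group definition.** Remaining samples are split by the index gene's
   continuous copy number: high = at or above the 75th percentile, low = at
   or below the 25th percentile. Quantiles use linear interpolation of
   order statistics (R type 7) throughout the package; boundaries are
   inclusive on both sides, matching the "≥ 75th / ≤ 25th percentile"
   definition. If all values are equal the stratification is degenerate and
   an error is raised.
3. **Per-gene statistic.** ΔPDUI = median(high) − median(low) after
   dropping missing values per group. Genes with fewer than `min_group_n`
   (default 10) non-missing values in either group are *untested*: PDUI
   matrices produced by DaPars-style estimation have coverage-driven
   missingness, and medians over a handful of values are unstable.
4. **Testing.** A two-sided Wilcoxon rank-sum test per tested gene; exact
   enumeration when the pooled sample is ≤ 12 and tie-free, otherwise the
   normal approximation with tie-corrected variance and continuity
   correction. BH adjustment is applied across *tested* genes only —
   untested genes carry no p-value and including them in the correction
   universe would be meaningless.
5. **Classification.** `lengthened` requires ΔPDUI ≥ 0.15 **and**
   q < 0.05; `shortened` requires ΔPDUI ≤ −0.15 and q < 0.05. The
   magnitude threshold of 0.15 suppresses statistically significant but
   biologically negligible shifts; significance alone is never enough.
6. **Expression integration.** ΔZ-score = mean(high) − mean(low) of
   expression Z-scores per gene. Quadrants: Q1 lengthened/ΔZ < 0, Q2
   lengthened/ΔZ > 0, Q3 shortened/ΔZ < 0, Q4 shortened/ΔZ > 0. The
   inequalities are strict: ΔZ exactly 0 (or missing) assigns no quadrant.
7. **Enrichment.** Each quadrant's genes are tested for over-representation
   in a gene-set collection by the upper hypergeometric tail (one-sided
   Fisher's exact test), BH-adjusted across sets. The default universe is
   the set of tested genes from the APA step: a self-contained analysis
   needs an explicit background, and "genes that could have been called"
   is the defensible one. Depletion is not tested.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `high_quantile` / `low_quantile` | 0.75 / 0.25 | copy-number group cut-offs |
| `delta_threshold` | 0.15 | minimum \|ΔPDUI\| (PDUI units) for an APA call |
| `fdr_alpha` | 0.05 | BH-adjusted significance level |
| `min_group_n` | 10 | minimum non-missing PDUI values per group per gene |

Survival stratification uses a median split of the continuous copy-number
value: strictly above the median is "high", ties at the median go to "low"
("above the median" read strictly). With discrete calls whose median is 0,
"high" is therefore calls ≥ 1. Kaplan–Meier estimation and the log-rank
test delegate to the `survival` package; the KM median is the smallest time
at which the curve reaches 0.5 or below, undefined when never reached.
Log-rank p-values come from the asymptotic χ²(1) reference; no exact
log-rank is attempted.

Co-occurrence between two genes uses call == 2 (high-level amplification)
as "amplified" by default — gain-level alterations are deliberately
excluded, and the call treated as "altered" is a parameter so deep-deletion
overlap can be studied the same way. The reported odds ratio is the sample
odds ratio n11·n00/(n10·n01) (`Inf` on a zero denominator with a non-zero
numerator), not the conditional MLE, so it matches the printed 2×2 table
directly.

## The synthetic cohort

The generator (`sim_config()` + `simulate_cohort()`) emulates the
statistical structure every downstream stage assumes; its defaults are the
study conditions used throughout the tests.

* **Copy number.** Index-gene calls are drawn from
  (0.002, 0.059, 0.51, 0.373, 0.056) over (−2, −1, 0, 1, 2) — the reported
  pan-cancer CPSF1 landscape (5.6% amplification, 37.3% gain). The partner
  gene is amplified with probability 0.847 given index amplification and
  0.0354 otherwise; the background value is the unique rate at which the
  two reported conditional overlaps (84.7% and 58.7%) coexist with a 5.6%
  index amplification rate. Non-amplified partner calls are drawn mostly
  diploid (0.7) with some gain (0.2) and shallow deletion (0.1), giving the
  confounder-diploid filter a realistic retention rate. All other CPA genes
  are diploid. Continuous values are uniform within fixed disjoint
  per-call intervals (−2 → [−2, −1.5), −1 → [−1.5, −0.25),
  0 → [−0.25, 0.25), 1 → [0.25, 1.5), 2 → [1.5, 2.5)); GISTIC2's actual
  thresholds are not public in this form, and bijective call↔value
  decoding makes exact consistency tests possible.
* **PDUI.** Baseline Beta(5, 5) per cell (mean 0.5, realistic spread for
  gene-level PDUI). Planted shortened/lengthened genes shift by ∓/±0.3 in
  samples within the top quartile of the index gene's continuous copy
  number, clipped to [0, 1]; 5% of cells are set missing. Shifts are
  applied by quartile of the continuous value — the same grouping the
  downstream analysis uses — so parameter recovery is a clean oracle.
* **Expression.** Z-scores are Normal with unit noise; planted genes in
  high-copy samples shift by +1 (shortened) or −1 (lengthened) — 3′UTR
  shortening removes repressive 3′UTR elements and associates with higher
  expression — with 20% of planted genes flipped in sign so that all four
  quadrants are populated.
* **Survival.** Exponential event times with hazard
  0.01 · exp(0.5 · copy-number) per month and independent exponential
  censoring at 0.005/month, drawn separately for OS and PFS. This is the
  simplest model consistent with "higher copy number, worse outcome"; the
  analysis itself fits no survival model, it only compares curves.
* **Mutations.** Each CPA gene mutates per sample with probability 0.0075,
  putting the expected any-CPA-mutation rate at 1 − (1 − 0.0075)¹⁶ ≈ 11.4%
  of subjects. Variant classes follow the reported mixture (61.6% missense,
  26.4% nonsense, the remainder spread over the other nonsilent classes);
  protein positions are uniform over per-gene protein lengths (plausible
  UniProt-scale constants, synthetic).

Each simulator stage seeds its own stream (`seed` plus a fixed per-stage
offset), so a cohort is reproducible element-by-element and `run_all()`
output is byte-identical across runs with one seed.

**What the generator does not emulate:** per-cancer-type heterogeneity,
tumor purity, genome-wide CNV correlation structure beyond the single
index/partner coupling, mutation hotspots (positions are uniform), or
PDUI missingness that correlates with expression. Tests passing on this
cohort therefore demonstrate correctness of the statistical machinery under
the planted model, not robustness to every artefact of real TCGA data.

## Numerical and design choices

* One quantile convention (type 7) is fixed package-wide so the APA group
  boundaries and survival median splits are consistent.
* The exact/approximate rank-sum switch at pooled n = 12 keeps exact
  enumeration where it is cheap and the approximation accurate elsewhere;
  fully tied (zero-information) comparisons return p = 1.
* Non-numeric cells in matrix inputs become missing rather than aborting,
  mirroring the standard preprocessing of GISTIC2 exports; domain
  violations (a PDUI of 1.2, a call of 3) abort with coordinates, because
  they indicate a mis-declared file rather than dirty cells.
* Sample barcodes are truncated to 15 characters (TCGA sample level) before
  joining tables whose sources use different barcode depths.
* Silent mutations are dropped by default (nonsilent landscapes are the
  oncoplot convention); a flag restores them.
* Subcomplex "mutation rate" is implemented as the share of mutation
  occurrences per subcomplex, the only denominator under which the four
  shares sum to 100%.
* Mutation frequencies count a subject once per gene however many mutations
  it carries; occurrence counts are used only for variant-class and
  subcomplex shares.
* Sample universes are intersected per stage, not globally: the mutation,
  CNV and APA cohorts legitimately differ in size, as they do in the real
  data sources.

## Calibration experiments

The test suite checks type-I error of the three shared tests at α = 0.05
over 1,000 null replicates, requiring the rejection rate within three
binomial standard errors of 0.05. The Fisher co-occurrence calibration uses
400 samples with a 25% per-gene alteration probability: the exact test is
conservative by construction, and its size only approaches the nominal
level when the 2×2 margins are dense; 25% is in the range of gain-level
alteration frequencies of the most altered CPA genes, where the
co-occurrence question is realistic. Rank-sum calibration uses two
samples of 20 normals; log-rank calibration uses null cohorts
(log HR = 0) of 200 samples. Planted-effect recovery runs at the study
scale used throughout: 400 samples, 1,000 genes, 50 + 50 planted effects of
magnitude 0.3; survival power uses 200 replicates of 1,000-sample cohorts
at log HR 0.5.

## Known limitations

* PDUI values are consumed, never computed: the DaPars step from RNA-seq
  BAMs is upstream and out of scope, as is GISTIC2 itself.
* No Cox regression or multivariable adjustment; the survival module
  compares curves, which is all the quadrant analysis requires.
* Genome-wide mutual-exclusivity screening is out of scope; only
  user-specified gene pairs are tested.
* Enrichment results depend on the chosen universe; with a different
  background (e.g. a web service's internal one) rankings will differ.
* The pan-cancer pooling masks per-type heterogeneity; per-type runs are
  possible by passing per-type sample subsets, but no stratified
  meta-analysis is provided.
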