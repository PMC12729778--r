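# apacnv

Copy-number-driven alternative polyadenylation (APA) analysis for tumor
cohorts.

## The problem

The cleavage and polyadenylation (CPA) machinery — the CPSF, CSTF, CFIm and
CFIIm subcomplexes, 16 core genes in all — controls where pre-mRNAs are
cleaved and polyadenylated. Alternative poly(A) site choice changes 3′UTR
length, and widespread 3′UTR shortening of oncogenes is a recurrent feature
of cancer transcriptomes. `apacnv` provides a tested pipeline for asking
whether *genomic* alterations of the CPA genes themselves (somatic mutations
and gene-level copy-number changes) are frequent, whether they matter
clinically, and whether amplification of an index CPA gene (CPSF1, which
sits on 8q24 next to MYC) shifts genome-wide APA patterns independently of
its co-amplified neighbour.

It is aimed at computational biologists working with TCGA-style inputs: an
MC3-dialect MAF of somatic mutations, GISTIC2 gene-level copy-number tables
(discrete calls in {−2,−1,0,1,2} and continuous values), DaPars/TC3A PDUI
matrices, expression Z-score tables, Xena-style clinical survival tables and
MSigDB GMT gene sets. A synthetic cohort generator emulates the statistical
structure of all of these, so every stage is testable offline.

## The core statistic

For a chosen index gene, samples are restricted to those diploid for a
confounder gene (MYC), then split into high (≥ 75th percentile) and low
(≤ 25th percentile) groups by the index gene's continuous copy number. For
each gene *g* with PDUI values (percentage of distal poly(A) site usage,
in [0, 1]; high = long 3′UTR):

    ΔPDUI(g) = median(PDUI_g in high) − median(PDUI_g in low)

with a two-sided Wilcoxon rank-sum test per gene and Benjamini–Hochberg
adjustment across tested genes. A gene is called **lengthened** when
ΔPDUI ≥ 0.15 with q < 0.05, **shortened** when ΔPDUI ≤ −0.15 with q < 0.05.
Expression is integrated through ΔZ-score (difference of group means), and
genes fall into quadrants: Q1 = lengthened & ΔZ < 0, Q2 = lengthened &
ΔZ > 0, Q3 = shortened & ΔZ < 0, Q4 = shortened & ΔZ > 0. Each quadrant's
gene list is tested for over-representation in a gene-set collection by the
one-sided Fisher's exact (hypergeometric tail) test with BH adjustment.

Around this sit the landscape stages: per-gene mutation frequencies on two
denominators (altered subjects and all subjects), variant-class and
subcomplex occurrence shares, per-position lollipop tables,
mutation-vs-expression rank-sum comparisons, GISTIC2 category frequency
tables, amplification co-occurrence (conditional overlap percentages plus a
Fisher test), and Kaplan–Meier / log-rank survival comparison of
median-split copy-number groups.

## Worked example

```r
library(apacnv)
cohort <- simulate_cohort(sim_config(n_samples = 400, seed = 42))

ov <- fisher_cooccurrence(
  amplification_overlap(cohort$cnv_calls, "CPSF1", "MYC"))
print(ov)
#> amplification overlap CPSF1 / MYC: n11=26 n10=5 n01=14 n00=355
#>   83.9% of CPSF1-amplified also MYC-amplified; 65.0% of MYC-amplified also CPSF1-amplified
#>   OR = 132, one-sided p = 6.74e-26

res <- run_apa_pipeline(cohort$cnv_calls, cohort$cnv_continuous,
                        cohort$pdui, cohort$zscore)
table(res$apa_class)
#> lengthened  shortened  unchanged
#>         50         49        901
table(res$quadrant)
#> none   Q1   Q2   Q3   Q4
#>  901   40   10   10   39

g <- stratify_by_value(cohort$cnv_continuous["CPSF1", ])
compare_survival(cohort$clinical, g, "OS")
#> OS comparison (log-rank chi2 = 5.598, p = 0.018)
#>   high: n = 200, median = 49.7
#>   low: n = 200, median = 59.5
```

The simulated cohort plants 50 3′UTR-shortened and 50 lengthened genes
(ΔPDUI magnitude 0.3) among 900 null genes; the pipeline recovers 99 of the
100 planted genes here with no false APA calls, and the planted
copy-number hazard (log HR 0.5 per copy unit) shows up as shorter median
survival in the high-copy group. `run_all()` executes every stage and
writes provenance-stamped TSVs that are byte-identical across runs with the
same seed.

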