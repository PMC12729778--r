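Package: apacnv
Title: Copy-Number-Driven Alternative Polyadenylation Analysis for Tumor Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize genomic alterations of the cleavage and
    polyadenylation (CPA) machinery in tumor cohorts and their downstream
    consequences. Summarizes somatic mutation landscapes from MAF files,
    computes gene-level copy-number (GISTIC2-style) alteration frequencies,
    tests amplification co-occurrence between co-localized genes (e.g. CPSF1
    and MYC on 8q24), stratifies Kaplan-Meier survival by copy number, and
    quantifies alternative-polyadenylation shifts (delta PDUI between
    copy-number quartile groups) with expression Z-score integration, quadrant
    classification and Fisher's-exact gene-set enrichment. Includes a
    synthetic cohort generator emulating the statistical structure of
    TCGA-like inputs so the full pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    survival,
    rlang
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
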