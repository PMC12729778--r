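#' Configuration for the APA quadrant analysis
#'
#' Parameters of the delta-PDUI analysis: the copy-number quantile cut-offs
#' defining the high and low groups (75th/25th percentiles), the
#' delta-PDUI magnitude threshold (0.15, chosen to suppress false
#' positive/negative APA calls), the FDR level for the per-gene rank-sum
#' tests (0.05), and the minimum number of non-missing PDUI values required
#' per group before a gene is tested (guards against coverage-driven
#' missingness in DaPars-style PDUI matrices).
#'
#' @param high_quantile Quantile at/above which samples are "high" copy
#'   number (default 0.75).
#' @param low_quantile Quantile at/below which samples are "low" (default
#'   0.25).
#' @param delta_threshold Minimum |delta PDUI| to call an APA event
#'   (default 0.15).
#' @param fdr_alpha BH-adjusted significance level (default 0.05).
#' @param min_group_n Minimum non-missing PDUI values per group per gene
#'   (default 10).
#' @return A validated list of class `apa_config`.
#' @export
apa_config <- function(high_quantile = 0.75, low_quantile = 0.25,
                       delta_threshold = 0.15, fdr_alpha = 0.05,
                       min_group_n = 10) {
  stopifnot(
    low_quantile >= 0, high_quantile <= 1, low_quantile < high_quantile,
    delta_threshold > 0, fdr_alpha > 0, fdr_alpha < 1, min_group_n >= 1
  )
  structure(list(high_quantile = high_quantile, low_quantile = low_quantile,
                 delta_threshold = delta_threshold, fdr_alpha = fdr_alpha,
                 min_group_n = as.integer(min_group_n)),
            class = "apa_config")
}

#' Define high / low copy-number sample groups
#'
#' Splits samples by the index gene's continuous copy number: "high" samples
#' sit at or above the `high_quantile` quantile, "low" at or below the
#' `low_quantile` quantile (boundaries inclusive on both sides, matching the
#' ">= 75th percentile" / "<= 25th percentile" definition; quantiles by the
#' package-wide linear-interpolation convention, [quantile_lin()]).
#'
#' @param values Named numeric vector of per-sample continuous copy number.
#' @param config An [apa_config()].
#' @return List with character vectors `high` and `low` of sample names.
#' @export
define_groups <- function(values, config = apa_config()) {
  values <- values[!is.na(values)]
  if (length(values) < 4L) {
    stop("need at least 4 samples with non-missing values to define groups")
  }
  if (length(unique(values)) == 1L) {
    stop("all copy-number values are equal: degenerate stratification")
  }
  hi_cut <- quantile_lin(values, config$high_quantile)
  lo_cut <- quantile_lin(values, config$low_quantile)
  list(high = names(values)[values >= hi_cut],
       low = names(values)[values <= lo_cut])
}

#' Restrict samples to those diploid for a confounder gene
#'
#' Removes samples carrying any copy-number alteration of the confounder
#' (e.g. MYC), so that an association attributed to the index gene cannot be
#' driven by co-amplification of its neighbour. Delegates to
#' [filter_diploid()].
#'
#' @param cnv A `cnv_call` [gene_matrix()].
#' @param samples Candidate sample identifiers.
#' @param confounder_gene Gene whose non-diploid samples are dropped.
#' @return The subset of `samples` diploid for `confounder_gene`.
#' @export
exclude_confounder <- function(cnv, samples, confounder_gene) {
  intersect(samples, filter_diploid(cnv, confounder_gene))
}

#' Per-gene delta PDUI between sample groups
#'
#' For every gene, `delta_pdui = median(PDUI in high) - median(PDUI in low)`
#' after dropping missing values per group. Genes with fewer than
#' `min_group_n` non-missing values in either group are marked untested
#' (`NA` delta).
#'
#' @param pdui A `pdui` [gene_matrix()].
#' @param high,low Disjoint, non-empty character vectors of sample names.
#' @param config An [apa_config()].
#' @return `data.frame` with columns `gene`, `delta_pdui`, `n_high`, `n_low`,
#'   `tested`.
#' @export
delta_pdui <- function(pdui, high, low, config = apa_config()) {
  check_groups(pdui, high, low)
  hm <- pdui[, intersect(high, colnames(pdui)), drop = FALSE]
  lm <- pdui[, intersect(low, colnames(pdui)), drop = FALSE]
  n_high <- rowSums(!is.na(hm))
  n_low <- rowSums(!is.na(lm))
  tested <- n_high >= config$min_group_n & n_low >= config$min_group_n
  med <- function(m) apply(m, 1L, stats::median, na.rm = TRUE)
  delta <- ifelse(tested, med(hm) - med(lm), NA_real_)
  data.frame(gene = rownames(pdui), delta_pdui = unname(delta),
             n_high = unname(n_high), n_low = unname(n_low),
             tested = unname(tested), stringsAsFactors = FALSE)
}

check_groups <- function(gm, high, low) {
  if (length(high) == 0L || length(low) == 0L) {
    stop("both sample groups must be non-empty")
  }
  if (length(intersect(high, low)) > 0L) {
    stop("high and low sample groups overlap")
  }
  invisible(TRUE)
}

#' Per-gene rank-sum test of PDUI between groups
#'
#' Two-sided Wilcoxon rank-sum p-value per tested gene ([ranksum()]: exact
#' for small tie-free samples, tie-corrected normal approximation with
#' continuity correction otherwise), BH-adjusted across the tested genes
#' only.
#'
#' @inheritParams delta_pdui
#' @return `data.frame` with columns `gene`, `p_raw`, `q_bh` (both `NA` for
#'   untested genes).
#' @export
test_apa <- function(pdui, high, low, config = apa_config()) {
  check_groups(pdui, high, low)
  hm <- pdui[, intersect(high, colnames(pdui)), drop = FALSE]
  lm <- pdui[, intersect(low, colnames(pdui)), drop = FALSE]
  p <- vapply(seq_len(nrow(pdui)), function(i) {
    x <- hm[i, ]; x <- x[!is.na(x)]
    y <- lm[i, ]; y <- y[!is.na(y)]
    if (length(x) < config$min_group_n || length(y) < config$min_group_n) {
      return(NA_real_)
    }
    ranksum(x, y, "two.sided")$p_value
  }, numeric(1L))
  data.frame(gene = rownames(pdui), p_raw = p, q_bh = bh_adjust(p),
             stringsAsFactors = FALSE)
}

#' Classify a gene's APA status
#'
#' A gene is `lengthened` when `delta_pdui >= delta_threshold` with
#' `q_bh < fdr_alpha`, `shortened` when `delta_pdui <= -delta_threshold`
#' with `q_bh < fdr_alpha`, `untested` when it was not tested, and
#' `unchanged` otherwise — both the magnitude threshold and the adjusted
#' significance are required for an APA call.
#'
#' @param delta Vector of delta-PDUI values (`NA` = untested).
#' @param q Vector of BH-adjusted p-values.
#' @param config An [apa_config()].
#' @return Character vector in \{lengthened, shortened, unchanged,
#'   untested\}.
#' @export
classify_apa <- function(delta, q, config = apa_config()) {
  ifelse(is.na(delta) | is.na(q), "untested",
    ifelse(delta >= config$delta_threshold & q < config$fdr_alpha,
           "lengthened",
      ifelse(delta <= -config$delta_threshold & q < config$fdr_alpha,
             "shortened", "unchanged")))
}

#' Per-gene delta Z-score between groups
#'
#' `delta_z = mean(Z in high) - mean(Z in low)` per gene, missing values
#' dropped per group; genes absent from the expression matrix get `NA`.
#'
#' @param expr A `zscore` [gene_matrix()].
#' @param high,low Sample groups as in [delta_pdui()].
#' @param genes Genes to report (default: rows of `expr`).
#' @return Named numeric vector of delta Z-scores over `genes`.
#' @export
delta_zscore <- function(expr, high, low, genes = rownames(expr)) {
  check_groups(expr, high, low)
  hm <- expr[, intersect(high, colnames(expr)), drop = FALSE]
  lm <- expr[, intersect(low, colnames(expr)), drop = FALSE]
  dz <- rowMeans(hm, na.rm = TRUE) - rowMeans(lm, na.rm = TRUE)
  dz[is.nan(dz)] <- NA_real_
  out <- stats::setNames(rep(NA_real_, length(genes)), genes)
  present <- intersect(genes, rownames(expr))
  out[present] <- dz[present]
  out
}

#' Assign the APA-by-expression quadrant
#'
#' Joint classification of APA class and expression change: Q1 = lengthened
#' with lower expression (delta Z < 0), Q2 = lengthened with higher
#' expression, Q3 = shortened with lower expression, Q4 = shortened with
#' higher expression. Anything else — unchanged or untested APA, missing or
#' exactly zero delta Z — gets `none` (the quadrant definitions use strict
#' inequalities).
#'
#' @param apa_class Character vector from [classify_apa()].
#' @param delta_z Numeric vector of delta Z-scores.
#' @return Character vector in \{Q1, Q2, Q3, Q4, none\}.
#' @export
assign_quadrant <- function(apa_class, delta_z) {
  out <- rep("none", length(apa_class))
  ok <- !is.na(delta_z) & delta_z != 0
  out[ok & apa_class == "lengthened" & delta_z < 0] <- "Q1"
  out[ok & apa_class == "lengthened" & delta_z > 0] <- "Q2"
  out[ok & apa_class == "shortened" & delta_z < 0] <- "Q3"
  out[ok & apa_class == "shortened" & delta_z > 0] <- "Q4"
  out
}

#' Run the full APA quadrant pipeline
#'
#' Composes the delta-PDUI analysis end-to-end: restrict to samples diploid
#' for the confounder gene, split the remainder into high / low groups by
#' the index gene's continuous copy number, compute per-gene delta PDUI and
#' rank-sum p with BH adjustment, classify APA status against the magnitude
#' and FDR thresholds, compute per-gene delta Z-scores, and assign
#' quadrants. Deterministic given its inputs.
#'
#' @param cnv_calls A `cnv_call` [gene_matrix()] (used for the confounder
#'   filter).
#' @param cnv_continuous A `cnv_continuous` [gene_matrix()] (used for the
#'   group split).
#' @param pdui A `pdui` [gene_matrix()].
#' @param expr Optional `zscore` [gene_matrix()]; when `NULL`, delta
#'   Z-scores are `NA` and all quadrants `none`.
#' @param index_gene Copy-number index gene (e.g. `"CPSF1"`).
#' @param confounder_gene Confounder to hold diploid (e.g. `"MYC"`); `NULL`
#'   disables the filter.
#' @param config An [apa_config()].
#' @return `data.frame`, one row per PDUI gene, with columns `gene`,
#'   `delta_pdui`, `n_high`, `n_low`, `p_raw`, `q_bh`, `apa_class`,
#'   `delta_zscore`, `quadrant`; attributes `high_samples` / `low_samples`
#'   record the groups used.
#' @export
run_apa_pipeline <- function(cnv_calls, cnv_continuous, pdui, expr = NULL,
                             index_gene = "CPSF1", confounder_gene = "MYC",
                             config = apa_config()) {
  if (nrow(pdui) == 0L) {
    return(data.frame(gene = character(), delta_pdui = numeric(),
                      n_high = integer(), n_low = integer(),
                      p_raw = numeric(), q_bh = numeric(),
                      apa_class = character(), delta_zscore = numeric(),
                      quadrant = character(), stringsAsFactors = FALSE))
  }
  samples <- intersect(colnames(cnv_continuous), colnames(pdui))
  if (!is.null(confounder_gene)) {
    samples <- exclude_confounder(cnv_calls, samples, confounder_gene)
  }
  if (!index_gene %in% rownames(cnv_continuous)) {
    stop("index gene '", index_gene, "' absent from continuous CNV matrix")
  }
  cn <- cnv_continuous[index_gene, samples]
  groups <- define_groups(cn, config)
  dp <- delta_pdui(pdui, groups$high, groups$low, config)
  tp <- test_apa(pdui, groups$high, groups$low, config)
  out <- merge(dp, tp, by = "gene", sort = FALSE)
  out$apa_class <- classify_apa(out$delta_pdui, out$q_bh, config)
  out$delta_zscore <- if (!is.null(expr)) {
    unname(delta_zscore(expr, groups$high, groups$low, genes = out$gene))
  } else {
    NA_real_
  }
  out$quadrant <- assign_quadrant(out$apa_class, out$delta_zscore)
  out$tested <- NULL
  out <- out[match(rownames(pdui), out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "high_samples") <- groups$high
  attr(out, "low_samples") <- groups$low
  out
}
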