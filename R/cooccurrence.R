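#' Amplification overlap between two genes
#'
#' Cross-tabulates the amplification status (call equal to `amplified_call`,
#' by default the high-level GISTIC2 amplification 2) of two genes over the
#' samples with non-missing calls in both, and reports the two conditional
#' overlap percentages: the share of gene-a-amplified samples that also carry
#' gene-b amplification, and vice versa.
#'
#' @param cnv A `cnv_call` [gene_matrix()].
#' @param gene_a,gene_b Gene symbols present in `cnv`.
#' @param amplified_call Which call counts as amplified (default 2); set to
#'   -2 to study deep-deletion overlap instead.
#' @return A list of class `overlap_result` with `gene_a`, `gene_b`, counts
#'   `n11`, `n10`, `n01`, `n00`, `pct_b_given_a`, `pct_a_given_b` (0 when
#'   the conditioning count is 0), `odds_ratio`, `p_value`, `q_bh` (the last
#'   three `NA` until [fisher_cooccurrence()] / [cooccurrence_screen()]).
#' @export
amplification_overlap <- function(cnv, gene_a, gene_b, amplified_call = 2) {
  if (matrix_domain(cnv) != "cnv_call") {
    stop("amplification_overlap requires a cnv_call matrix")
  }
  for (g in c(gene_a, gene_b)) {
    if (!g %in% rownames(cnv)) stop("gene '", g, "' absent from CNV matrix")
  }
  a <- cnv[gene_a, ]
  b <- cnv[gene_b, ]
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep] == amplified_call
  b <- b[keep] == amplified_call
  n11 <- sum(a & b); n10 <- sum(a & !b)
  n01 <- sum(!a & b); n00 <- sum(!a & !b)
  structure(list(
    gene_a = gene_a, gene_b = gene_b,
    n11 = n11, n10 = n10, n01 = n01, n00 = n00,
    pct_b_given_a = if (n11 + n10 > 0) 100 * n11 / (n11 + n10) else 0,
    pct_a_given_b = if (n11 + n01 > 0) 100 * n11 / (n11 + n01) else 0,
    odds_ratio = NA_real_, p_value = NA_real_, q_bh = NA_real_
  ), class = "overlap_result")
}

#' Fisher's-exact co-occurrence test on an overlap table
#'
#' One-sided test for enrichment of joint amplification: the p-value is the
#' upper hypergeometric tail of `n11` given the table margins (identical to
#' `fisher.test(alternative = "greater")`). The odds ratio is the sample odds
#' ratio `n11 * n00 / (n10 * n01)`, reported as `Inf` when a denominator cell
#' is 0 while `n11 * n00 > 0`, and `NaN` for the fully degenerate table.
#'
#' @param result An `overlap_result` from [amplification_overlap()].
#' @param sidedness `"cooccurrence"` (one-sided enrichment, default) or
#'   `"two.sided"`.
#' @return The `overlap_result` with `odds_ratio` and `p_value` filled.
#' @export
fisher_cooccurrence <- function(result,
                                sidedness = c("cooccurrence", "two.sided")) {
  sidedness <- match.arg(sidedness)
  n11 <- result$n11; n10 <- result$n10
  n01 <- result$n01; n00 <- result$n00
  num <- n11 * n00
  den <- n10 * n01
  result$odds_ratio <- if (den > 0) num / den else if (num > 0) Inf else NaN
  N <- n11 + n10 + n01 + n00
  if (sidedness == "cooccurrence") {
    result$p_value <- hypergeom_upper_tail(n11, N = N, K = n11 + n01,
                                           n = n11 + n10)
  } else {
    tab <- matrix(c(n11, n01, n10, n00), nrow = 2)
    result$p_value <- stats::fisher.test(tab)$p.value
  }
  result
}

#' Screen a list of gene pairs for amplification co-occurrence
#'
#' Runs [amplification_overlap()] and [fisher_cooccurrence()] for each pair
#' and adjusts the p-values across pairs with Benjamini-Hochberg.
#'
#' @param cnv A `cnv_call` [gene_matrix()].
#' @param gene_pairs List of length-2 character vectors, or a two-column
#'   matrix / data.frame of gene symbols.
#' @param amplified_call As in [amplification_overlap()].
#' @return `data.frame`, one row per pair with all overlap fields plus
#'   `p_value` and `q_bh`, sorted by `q_bh` then `p_value`.
#' @export
cooccurrence_screen <- function(cnv, gene_pairs, amplified_call = 2) {
  if (is.matrix(gene_pairs) || is.data.frame(gene_pairs)) {
    gene_pairs <- lapply(seq_len(nrow(gene_pairs)),
                         function(i) as.character(unlist(gene_pairs[i, ])))
  }
  if (length(gene_pairs) == 0L) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      n11 = integer(), n10 = integer(), n01 = integer(),
                      n00 = integer(), pct_b_given_a = numeric(),
                      pct_a_given_b = numeric(), odds_ratio = numeric(),
                      p_value = numeric(), q_bh = numeric(),
                      stringsAsFactors = FALSE))
  }
  res <- lapply(gene_pairs, function(pr) {
    fisher_cooccurrence(
      amplification_overlap(cnv, pr[1L], pr[2L], amplified_call)
    )
  })
  out <- do.call(rbind, lapply(res, function(r) {
    data.frame(gene_a = r$gene_a, gene_b = r$gene_b, n11 = r$n11,
               n10 = r$n10, n01 = r$n01, n00 = r$n00,
               pct_b_given_a = r$pct_b_given_a,
               pct_a_given_b = r$pct_a_given_b,
               odds_ratio = r$odds_ratio, p_value = r$p_value,
               stringsAsFactors = FALSE)
  }))
  out$q_bh <- bh_adjust(out$p_value)
  out <- out[order(out$q_bh, out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    paste0("amplification overlap %s / %s: n11=%d n10=%d n01=%d n00=%d\n",
           "  %.1f%% of %s-amplified also %s-amplified; ",
           "%.1f%% of %s-amplified also %s-amplified\n"),
    x$gene_a, x$gene_b, x$n11, x$n10, x$n01, x$n00,
    x$pct_b_given_a, x$gene_a, x$gene_b,
    x$pct_a_given_b, x$gene_b, x$gene_a
  ))
  if (!is.na(x$p_value)) {
    cat(sprintf("  OR = %.3g, one-sided p = %.3g\n", x$odds_ratio, x$p_value))
  }
  invisible(x)
}
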