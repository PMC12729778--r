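#' Per-gene copy-number category frequencies
#'
#' For each requested gene, the percentage of samples in each GISTIC2 call
#' category — amplification (2), gain (1), diploid (0), shallow deletion
#' (-1), deep deletion (-2) — plus the any-alteration percentage (non-zero
#' calls). The denominator is the number of samples with a non-missing call
#' for that gene; category percentages sum to exactly 100 before any
#' rounding, and `pct_any_alteration = 100 - pct_diploid`.
#'
#' @param cnv A [gene_matrix()] with domain `cnv_call`.
#' @param genes Genes to report (default: all rows).
#' @param missing_gene `"error"` (default) fails on an all-missing gene row;
#'   `"flag"` reports it with `n_samples_with_data = 0` and `NA` percentages.
#' @return `data.frame` with columns `gene`, `pct_amplification`, `pct_gain`,
#'   `pct_diploid`, `pct_shallow_deletion`, `pct_deep_deletion`,
#'   `pct_any_alteration`, `n_samples_with_data`.
#' @export
cnv_frequencies <- function(cnv, genes = rownames(cnv),
                            missing_gene = c("error", "flag")) {
  missing_gene <- match.arg(missing_gene)
  if (matrix_domain(cnv) != "cnv_call") {
    stop("cnv_frequencies requires a cnv_call matrix")
  }
  absent <- setdiff(genes, rownames(cnv))
  if (length(absent) > 0L) {
    stop("gene(s) absent from the CNV matrix: ",
         paste(absent, collapse = ", "))
  }
  cats <- c(pct_amplification = 2, pct_gain = 1, pct_diploid = 0,
            pct_shallow_deletion = -1, pct_deep_deletion = -2)
  rows <- lapply(genes, function(g) {
    v <- cnv[g, ]
    v <- v[!is.na(v)]
    n <- length(v)
    if (n == 0L) {
      if (missing_gene == "error") {
        stop("gene '", g, "' has no non-missing calls")
      }
      pct <- stats::setNames(rep(NA_real_, 5L), names(cats))
      any_alt <- NA_real_
    } else {
      pct <- vapply(cats, function(cc) 100 * sum(v == cc) / n, numeric(1L))
      any_alt <- 100 * sum(v != 0) / n
    }
    cbind(data.frame(gene = g, stringsAsFactors = FALSE),
          as.data.frame(as.list(pct)),
          data.frame(pct_any_alteration = any_alt,
                     n_samples_with_data = n))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rank genes by combined alteration percentage
#'
#' Sums the percentages of the requested call categories per gene (e.g.
#' amplification + deep deletion for the high-level alteration ranking) and
#' orders genes descending, ties broken alphabetically.
#'
#' @param rows Output of [cnv_frequencies()].
#' @param categories Integer subset of \{-2, -1, 0, 1, 2\}.
#' @return `data.frame` with columns `gene`, `combined_pct`, ordered.
#' @export
rank_by_category <- function(rows, categories) {
  stopifnot(all(categories %in% c(-2, -1, 0, 1, 2)))
  colmap <- c(`2` = "pct_amplification", `1` = "pct_gain", `0` = "pct_diploid",
              `-1` = "pct_shallow_deletion", `-2` = "pct_deep_deletion")
  cols <- colmap[as.character(categories)]
  combined <- rowSums(rows[, cols, drop = FALSE])
  out <- data.frame(gene = rows$gene, combined_pct = unname(combined),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$combined_pct, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
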