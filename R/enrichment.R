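#' Fisher's-exact over-representation of one gene set
#'
#' One-sided over-representation test of a query gene list against a single
#' gene set within an explicit universe: with `N` universe genes, `K` of
#' them in the set, `n` in the query and `k` in both, the p-value is the
#' upper hypergeometric tail `P(X >= k)`. Query genes outside the universe
#' are dropped (count reported); the set is intersected with the universe.
#'
#' @param query Character vector of query gene symbols.
#' @param gene_set Character vector of set members.
#' @param universe Character vector defining the background.
#' @return One-row `data.frame` with `k`, `K`, `n`, `N`, `odds_ratio`
#'   (sample OR of the 2x2 table, `Inf`/`NaN` on zero cells), `p_raw`;
#'   attribute `n_query_outside_universe`.
#' @export
fisher_enrichment <- function(query, gene_set, universe) {
  universe <- unique(universe)
  query <- unique(query)
  outside <- setdiff(query, universe)
  query <- intersect(query, universe)
  gene_set <- intersect(unique(gene_set), universe)
  N <- length(universe)
  K <- length(gene_set)
  n <- length(query)
  k <- length(intersect(query, gene_set))
  n11 <- k
  n10 <- n - k
  n01 <- K - k
  n00 <- N - K - n + k
  num <- n11 * n00
  den <- n10 * n01
  or <- if (den > 0) num / den else if (num > 0) Inf else NaN
  out <- data.frame(k = k, K = K, n = n, N = N, odds_ratio = or,
                    p_raw = hypergeom_upper_tail(k, N, K, n))
  attr(out, "n_query_outside_universe") <- length(outside)
  out
}

#' Enrichment of a query against a gene-set collection
#'
#' Runs [fisher_enrichment()] for every set in the collection and adjusts
#' across sets with Benjamini-Hochberg.
#'
#' @param query Character vector of query genes.
#' @param collection Named list of gene sets (e.g. from [read_gmt()]).
#' @param universe Background gene list; must contain the query.
#' @param alpha Significance level on the adjusted p (default 0.05).
#' @return `data.frame` with columns `set_name`, `k`, `K`, `n`, `N`,
#'   `odds_ratio`, `p_raw`, `q_bh`, `significant`, sorted by `q_bh` then
#'   `p_raw`.
#' @export
enrich_collection <- function(query, collection, universe, alpha = 0.05) {
  rows <- lapply(names(collection), function(nm) {
    r <- fisher_enrichment(query, collection[[nm]], universe)
    cbind(data.frame(set_name = nm, stringsAsFactors = FALSE), r)
  })
  if (length(rows) == 0L) {
    return(data.frame(set_name = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), odds_ratio = numeric(),
                      p_raw = numeric(), q_bh = numeric(),
                      significant = logical(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$q_bh <- bh_adjust(out$p_raw)
  out$significant <- out$q_bh < alpha
  out <- out[order(out$q_bh, out$p_raw), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-quadrant gene-set enrichment
#'
#' Runs [enrich_collection()] once per quadrant Q1-Q4, using that quadrant's
#' genes (from an APA result table) as the query. The default universe is
#' all tested genes in the APA table — the statistically defensible
#' background for a self-contained analysis.
#'
#' @param apa_results `data.frame` from [run_apa_pipeline()].
#' @param collection Named list of gene sets.
#' @param universe Background genes (default: genes with a non-`NA` p in
#'   `apa_results`).
#' @param alpha Adjusted-p significance level.
#' @return Named list of four enrichment `data.frame`s (`Q1`..`Q4`).
#' @export
quadrant_enrichment <- function(apa_results, collection,
                                universe = NULL, alpha = 0.05) {
  if (is.null(universe)) {
    universe <- apa_results$gene[!is.na(apa_results$p_raw)]
  }
  out <- lapply(c("Q1", "Q2", "Q3", "Q4"), function(qd) {
    qgenes <- apa_results$gene[apa_results$quadrant == qd]
    if (length(qgenes) > length(unique(universe))) {
      stop("universe is smaller than the ", qd, " query")
    }
    enrich_collection(qgenes, collection, universe, alpha)
  })
  names(out) <- c("Q1", "Q2", "Q3", "Q4")
  out
}
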