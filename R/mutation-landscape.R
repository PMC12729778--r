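#' Per-gene mutation frequency on two denominators
#'
#' Counts, for each tracked gene, the distinct subjects carrying at least one
#' qualifying mutation (subjects count once per gene regardless of
#' multiplicity, the oncoplot convention) and reports the frequency both
#' relative to altered subjects — those with a mutation in any tracked gene —
#' and relative to the full cohort.
#'
#' @param records Mutation `data.frame` from [read_maf()] or
#'   [simulate_mutations()].
#' @param tracked_genes Character vector of genes to report.
#' @param n_total Total number of subjects in the cohort (must be at least
#'   the number of distinct subjects in `records`).
#' @return A `data.frame` with columns `gene`, `n_mutated_subjects`,
#'   `pct_of_altered`, `pct_of_all`, sorted descending by `pct_of_altered`
#'   (ties alphabetical), plus an attribute `n_altered_subjects`.
#' @export
mutation_frequency <- function(records, tracked_genes, n_total) {
  if (n_total <= 0) stop("n_total must be a positive subject count")
  records <- records[records$gene %in% tracked_genes, , drop = FALSE]
  n_distinct <- length(unique(records$sample_id))
  if (n_total < n_distinct) {
    stop("n_total (", n_total, ") is smaller than the number of distinct ",
         "mutated subjects (", n_distinct, ")")
  }
  if (nrow(records) == 0L) {
    out <- data.frame(gene = character(), n_mutated_subjects = integer(),
                      pct_of_altered = numeric(), pct_of_all = numeric(),
                      stringsAsFactors = FALSE)
    attr(out, "n_altered_subjects") <- 0L
    return(out)
  }
  n_altered <- length(unique(records$sample_id))
  per_gene <- vapply(tracked_genes, function(g) {
    length(unique(records$sample_id[records$gene == g]))
  }, integer(1L))
  out <- data.frame(
    gene = tracked_genes,
    n_mutated_subjects = unname(per_gene),
    pct_of_altered = 100 * unname(per_gene) / n_altered,
    pct_of_all = 100 * unname(per_gene) / n_total,
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$pct_of_altered, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_altered_subjects") <- n_altered
  out
}

#' Tally mutation occurrences by variant class
#'
#' Occurrence counts (every record counts, not subject-deduplicated) and
#' their percentage of all occurrences, e.g. the share of missense mutations
#' in the cohort's CPA mutation burden.
#'
#' @param records Mutation `data.frame`.
#' @return `data.frame` with columns `variant_classification`, `count`,
#'   `percent`, sorted descending by count; zero rows for empty input.
#' @export
variant_class_tally <- function(records) {
  if (nrow(records) == 0L) {
    return(data.frame(variant_classification = character(),
                      count = integer(), percent = numeric(),
                      stringsAsFactors = FALSE))
  }
  tab <- table(records$variant_classification)
  out <- data.frame(
    variant_classification = names(tab),
    count = as.integer(tab),
    percent = 100 * as.integer(tab) / sum(tab),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$count, out$variant_classification), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Share of mutation occurrences per CPA subcomplex
#'
#' Attributes each mutation occurrence to its gene's subcomplex and reports
#' the percentage share per subcomplex (shares sum to 100). Records in genes
#' absent from the map are dropped and their count reported as an attribute.
#'
#' @param records Mutation `data.frame`.
#' @param complex_map Named vector gene -> subcomplex; defaults to
#'   [cpa_complex_map()].
#' @return `data.frame` with columns `complex`, `count`, `percent`; attribute
#'   `n_unmapped` counts dropped records.
#' @export
complex_share <- function(records, complex_map = cpa_complex_map()) {
  mapped <- records$gene %in% names(complex_map)
  records <- records[mapped, , drop = FALSE]
  if (nrow(records) == 0L) {
    out <- data.frame(complex = character(), count = integer(),
                      percent = numeric(), stringsAsFactors = FALSE)
    attr(out, "n_unmapped") <- sum(!mapped)
    return(out)
  }
  cx <- complex_map[records$gene]
  tab <- table(cx)
  out <- data.frame(
    complex = names(tab),
    count = as.integer(tab),
    percent = 100 * as.integer(tab) / sum(tab),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$count, out$complex), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_unmapped") <- sum(!mapped)
  out
}

#' Per-position mutation counts for one gene (lollipop table)
#'
#' Counts mutations at each protein position, broken down by variant class.
#' Records with missing position are excluded and their count reported.
#'
#' @param records Mutation `data.frame`.
#' @param gene Gene symbol.
#' @return `data.frame` with columns `protein_position`,
#'   `variant_classification`, `count`, sorted by position; attribute
#'   `n_excluded` gives the number of positionless records for the gene.
#' @export
position_distribution <- function(records, gene) {
  rec <- records[records$gene == gene, , drop = FALSE]
  n_excluded <- sum(is.na(rec$protein_position))
  rec <- rec[!is.na(rec$protein_position), , drop = FALSE]
  if (nrow(rec) == 0L) {
    out <- data.frame(protein_position = integer(),
                      variant_classification = character(),
                      count = integer(), stringsAsFactors = FALSE)
    attr(out, "n_excluded") <- n_excluded
    return(out)
  }
  agg <- stats::aggregate(
    list(count = rec$protein_position),
    by = list(protein_position = rec$protein_position,
              variant_classification = rec$variant_classification),
    FUN = length
  )
  agg <- agg[order(agg$protein_position, agg$variant_classification), ,
             drop = FALSE]
  rownames(agg) <- NULL
  attr(agg, "n_excluded") <- n_excluded
  agg
}

#' Association between mutation status and expression for one gene
#'
#' Splits samples of an expression matrix into mutant (at least one
#' qualifying mutation in `gene`) and wild type, compares the gene's
#' expression between the groups with a two-sided rank-sum test, and reports
#' the median-split concordance: the fraction of mutants falling in the
#' high-expression half of the cohort.
#'
#' @param expr A [gene_matrix()] with domain `log2_expression` or `zscore`.
#' @param records Mutation `data.frame`.
#' @param gene Gene symbol (must be a row of `expr`).
#' @return A list with `gene`, `n_mutant`, `n_wildtype`, `median_mutant`,
#'   `median_wildtype`, `p_value` (`NA` with `testable = FALSE` when either
#'   group has fewer than 2 samples), `frac_mutant_high`.
#' @export
expression_by_mutation <- function(expr, records, gene) {
  if (!matrix_domain(expr) %in% c("log2_expression", "zscore")) {
    stop("expr must have domain log2_expression or zscore")
  }
  if (!gene %in% rownames(expr)) {
    stop("gene '", gene, "' absent from the expression matrix")
  }
  vals <- expr[gene, ]
  vals <- vals[!is.na(vals)]
  mut_samples <- unique(records$sample_id[records$gene == gene])
  is_mut <- names(vals) %in% mut_samples
  x <- vals[is_mut]
  y <- vals[!is_mut]
  med <- stats::median(vals)
  testable <- length(x) >= 2L && length(y) >= 2L
  res <- list(
    gene = gene,
    n_mutant = length(x), n_wildtype = length(y),
    median_mutant = if (length(x)) stats::median(x) else NA_real_,
    median_wildtype = if (length(y)) stats::median(y) else NA_real_,
    p_value = NA_real_,
    testable = testable,
    frac_mutant_high = if (length(x)) mean(x > med) else NA_real_
  )
  if (testable) res$p_value <- ranksum(x, y)$p_value
  res
}
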