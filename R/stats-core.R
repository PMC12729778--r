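#' Wilcoxon rank-sum test with a documented exact/approximate switch
#'
#' Two-sample rank-sum (Mann-Whitney) test used for all group comparisons in
#' the package (per-gene PDUI comparisons, mutation-vs-expression). The exact
#' null distribution is enumerated when `n1 + n2 <= 12` and the pooled data
#' contain no ties; otherwise the normal approximation with tie-corrected
#' variance and a 0.5 continuity correction is used. The switch point is fixed
#' so results are reproducible across inputs of different sizes.
#'
#' @param x,y Numeric vectors (missing values dropped).
#' @param sidedness `"two.sided"` (default), `"less"` or `"greater"`,
#'   referring to the location of `x` relative to `y`.
#' @return A list of class `apacnv_test` with elements `statistic` (the
#'   Mann-Whitney U for `x`), `p_value`, `method` (`"exact"` or
#'   `"normal_approx"`), `n1` and `n2`.
#' @examples
#' ranksum(c(1, 2, 3), c(4, 5, 6))$p_value  # exact two-sided 0.1
#' @export
ranksum <- function(x, y, sidedness = c("two.sided", "less", "greater")) {
  sidedness <- match.arg(sidedness)
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  n1 <- length(x)
  n2 <- length(y)
  if (n1 < 1L || n2 < 1L) {
    stop("ranksum requires at least one non-missing value per group")
  }
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (n1 + n2 <= 12L) && !ties
  wt <- suppressWarnings(stats::wilcox.test(
    x, y,
    alternative = sidedness, exact = exact, correct = TRUE
  ))
  # degenerate pooled data (all values tied) carry no rank information
  if (is.nan(wt$p.value)) wt$p.value <- 1
  structure(
    list(
      statistic = unname(wt$statistic),
      p_value = min(wt$p.value, 1),
      method = if (exact) "exact" else "normal_approx",
      n1 = n1, n2 = n2
    ),
    class = "apacnv_test"
  )
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up FDR adjustment: after ascending sort, `q(i) = min_{j >= i}
#' m * p(j) / j`, capped at 1, returned in the input order. `NA` p-values are
#' passed through as `NA` and do not count towards `m`.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  stats::p.adjust(p, method = "BH")
}

#' Upper tail of the hypergeometric distribution
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: drawing `n` items without
#' replacement from a universe of `N` containing `K` successes. This is the
#' one-sided Fisher's-exact enrichment p-value used by the co-occurrence and
#' gene-set modules.
#'
#' @param k Observed success count (integer >= 0).
#' @param N Universe size.
#' @param K Successes in the universe.
#' @param n Sample (query) size.
#' @return The tail probability, 1 when `k <= 0`, 0 when `k > min(K, n)`.
#' @export
hypergeom_upper_tail <- function(k, N, K, n) {
  stopifnot(N >= 0, K >= 0, K <= N, n >= 0, n <= N)
  if (k <= 0) return(1)
  if (k > min(K, n)) return(0)
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Quantile with the package-wide convention
#'
#' All group boundaries in the package (copy-number quartile groups, median
#' splits) use one quantile convention: linear interpolation of the order
#' statistics (type 7, the R default), so `quantile_lin(1:4, 0.5) == 2.5`.
#' Missing values are dropped.
#'
#' @param values Numeric vector.
#' @param q Probability in \[0, 1\].
#' @return The interpolated quantile.
#' @export
quantile_lin <- function(values, q) {
  stopifnot(length(q) == 1L, q >= 0, q <= 1)
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("no non-missing values for quantile")
  unname(stats::quantile(values, probs = q, type = 7, names = FALSE))
}

#' @export
print.apacnv_test <- function(x, ...) {
  cat(sprintf(
    "rank-sum test (%s): U = %g, p = %.4g  [n1 = %d, n2 = %d]\n",
    x$method, x$statistic, x$p_value, x$n1, x$n2
  ))
  invisible(x)
}
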