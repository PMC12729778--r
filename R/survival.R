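#' Median-split stratification of a per-sample value
#'
#' Assigns each sample to `"high"` (value strictly above the median) or
#' `"low"` (at or below — "above the median" read strictly, so ties at the
#' median fall in the low group). Missing values get `NA`. With GISTIC2
#' discrete calls whose median is 0 this makes "high" the samples with calls
#' of 1 or more.
#'
#' @param values Named numeric vector (names are sample identifiers).
#' @param rule Only `"median_split"` is implemented.
#' @return Named character vector of `"high"` / `"low"` / `NA`, with an
#'   attribute `degenerate = TRUE` when all non-missing values are equal (all
#'   samples then fall in "low").
#' @export
stratify_by_value <- function(values, rule = c("median_split")) {
  rule <- match.arg(rule)
  med <- stats::median(values, na.rm = TRUE)
  grp <- ifelse(is.na(values), NA_character_,
                ifelse(values > med, "high", "low"))
  names(grp) <- names(values)
  degenerate <- length(unique(values[!is.na(values)])) <= 1L
  if (degenerate) {
    warning("all values equal: median split is degenerate, no 'high' group")
  }
  attr(grp, "degenerate") <- degenerate
  grp
}

#' Samples diploid for a given gene
#'
#' Returns the samples whose GISTIC2 call for `gene` is 0 — used to remove a
#' confounding amplification (e.g. restrict to MYC-diploid samples before
#' assessing CPSF1 effects, so 8q24 co-amplification cannot drive the
#' result).
#'
#' @param cnv A `cnv_call` [gene_matrix()].
#' @param gene Gene symbol.
#' @return Character vector of sample identifiers (warns when empty).
#' @export
filter_diploid <- function(cnv, gene) {
  if (matrix_domain(cnv) != "cnv_call") {
    stop("filter_diploid requires a cnv_call matrix")
  }
  if (!gene %in% rownames(cnv)) {
    stop("gene '", gene, "' absent from CNV matrix")
  }
  v <- cnv[gene, ]
  out <- colnames(cnv)[!is.na(v) & v == 0]
  if (length(out) == 0L) warning("no samples diploid for ", gene)
  out
}

#' Kaplan-Meier product-limit estimate
#'
#' Standard product-limit estimator (via `survival::survfit`), with the
#' events-before-censoring convention at tied times. The median is the
#' smallest observed time at which the survival curve drops to 0.5 or below,
#' `NA` when the curve never reaches 0.5.
#'
#' @param times Non-negative follow-up times.
#' @param events Event indicators (1 death/progression, 0 censored).
#' @return A list of class `km_fit` with `time` (distinct event/censoring
#'   times), `surv` (survival probability after each time), `n_risk`,
#'   `n_event`, `n` and `median`.
#' @export
km_estimate <- function(times, events) {
  stopifnot(length(times) == length(events), all(times >= 0, na.rm = TRUE))
  keep <- !is.na(times) & !is.na(events)
  times <- times[keep]; events <- events[keep]
  if (length(times) == 0L) stop("no complete (time, event) observations")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "none")
  med <- unname(summary(fit)$table["median"])
  structure(list(
    time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
    n_event = fit$n.event, n = length(times), median = med
  ), class = "km_fit")
}

#' Two-group log-rank test
#'
#' Standard log-rank statistic: at each distinct event time the observed
#' minus hypergeometric-expected event count in group 1 is accumulated and
#' `chi2 = (sum(O - E))^2 / sum(V)`, referred to a chi-square with 1 degree
#' of freedom (via `survival::survdiff`).
#'
#' @param times,events As in [km_estimate()].
#' @param groups Group label per observation (exactly 2 distinct levels).
#' @return List with `chi2`, `p_value`, `n` (per-group sizes).
#' @export
logrank_test <- function(times, events, groups) {
  keep <- !is.na(times) & !is.na(events) & !is.na(groups)
  times <- times[keep]; events <- events[keep]; groups <- groups[keep]
  lev <- unique(groups)
  if (length(lev) != 2L) {
    stop("logrank_test requires exactly 2 groups, got ", length(lev))
  }
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
  chi2 <- unname(sd$chisq)
  list(chi2 = chi2,
       p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       n = stats::setNames(as.integer(sd$n), sub("^groups=", "", names(sd$n))))
}

#' Compare survival between labelled sample groups
#'
#' Joins group labels to a clinical table, drops samples missing the chosen
#' endpoint, fits a Kaplan-Meier curve per group and runs the two-group
#' log-rank test.
#'
#' @param clinical Clinical `data.frame` from [read_clinical()] or
#'   [simulate_survival()].
#' @param groups Named character vector of group labels (names are sample
#'   identifiers), e.g. from [stratify_by_value()].
#' @param endpoint `"OS"` (overall survival, default) or `"PFS"`
#'   (progression-free survival).
#' @return A list of class `survival_comparison` with `endpoint`, `groups`
#'   (per-label list of `km_fit` objects), `n`, `medians`, `logrank_chi2`,
#'   `logrank_p`.
#' @export
compare_survival <- function(clinical, groups, endpoint = c("OS", "PFS")) {
  endpoint <- match.arg(endpoint)
  tcol <- if (endpoint == "OS") "os_time" else "pfs_time"
  ecol <- if (endpoint == "OS") "os_event" else "pfs_event"
  groups <- groups[!is.na(groups)]
  df <- clinical[match(names(groups), clinical$sample_id), , drop = FALSE]
  keep <- !is.na(df$sample_id) & !is.na(df[[tcol]]) & !is.na(df[[ecol]])
  df <- df[keep, , drop = FALSE]
  glab <- groups[keep]
  lev <- sort(unique(groups))
  for (lv in lev) {
    if (sum(glab == lv) == 0L) {
      stop("group '", lv, "' is empty after joining clinical data")
    }
  }
  if (length(lev) < 2L) stop("need at least 2 groups")
  lev <- sort(unique(glab))
  fits <- lapply(lev, function(lv) {
    km_estimate(df[[tcol]][glab == lv], df[[ecol]][glab == lv])
  })
  names(fits) <- lev
  lr <- logrank_test(df[[tcol]], df[[ecol]], glab)
  structure(list(
    endpoint = endpoint,
    groups = fits,
    n = vapply(fits, function(f) f$n, integer(1L)),
    medians = vapply(fits, function(f) {
      if (is.null(f$median) || is.na(f$median)) NA_real_ else f$median
    }, numeric(1L)),
    logrank_chi2 = lr$chi2,
    logrank_p = lr$p_value
  ), class = "survival_comparison")
}

#' @export
print.survival_comparison <- function(x, ...) {
  cat(sprintf("%s comparison (log-rank chi2 = %.3f, p = %.3g)\n",
              x$endpoint, x$logrank_chi2, x$logrank_p))
  for (lv in names(x$groups)) {
    cat(sprintf("  %s: n = %d, median = %s\n", lv, x$n[[lv]],
                if (is.na(x$medians[[lv]])) "not reached"
                else sprintf("%.1f", x$medians[[lv]])))
  }
  invisible(x)
}

#' @export
print.km_fit <- function(x, ...) {
  cat(sprintf("Kaplan-Meier fit: n = %d, median = %s\n", x$n,
              if (is.na(x$median)) "not reached" else sprintf("%.2f", x$median)))
  invisible(x)
}
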