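#' Gene-by-sample matrix with a declared data domain
#'
#' The common carrier for every matrix-valued input in the package: GISTIC2
#' copy-number calls, continuous copy-number values, PDUI (percentage of
#' distal poly(A) site usage, in \[0, 1\]), expression Z-scores and log2
#' expression. A `gene_matrix` is a numeric matrix with unique gene symbols as
#' row names, unique sample identifiers as column names, and a `domain`
#' attribute that fixes which value-range invariant is enforced:
#'
#' * `cnv_call` — every non-missing value in \{-2, -1, 0, 1, 2\}
#'   (GISTIC2 coding: 2 amplification, 1 gain, 0 diploid, -1 shallow
#'   deletion, -2 deep deletion)
#' * `pdui` — every non-missing value in \[0, 1\]
#' * `cnv_continuous`, `zscore`, `log2_expression` — any numeric value
#'
#' @param values Numeric matrix with gene row names and sample column names.
#' @param domain One of `"cnv_call"`, `"cnv_continuous"`, `"pdui"`,
#'   `"zscore"`, `"log2_expression"`.
#' @return An object of class `gene_matrix` (a matrix with a `domain`
#'   attribute).
#' @examples
#' m <- matrix(c(2, 0, 0, -1), 2, 2,
#'             dimnames = list(c("CPSF1", "MYC"), c("S1", "S2")))
#' gm <- gene_matrix(m, "cnv_call")
#' @export
gene_matrix <- function(values,
                        domain = c("cnv_call", "cnv_continuous", "pdui",
                                   "zscore", "log2_expression")) {
  domain <- match.arg(domain)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix")
  }
  genes <- rownames(values)
  samples <- colnames(values)
  if (nrow(values) == 0L && ncol(values) == 0L) {
    dimnames(values) <- list(character(), character())
    genes <- character()
    samples <- character()
  }
  if (is.null(genes) || is.null(samples)) {
    stop("'values' must have gene row names and sample column names")
  }
  if (anyDuplicated(genes)) {
    stop("duplicate gene symbols: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  if (anyDuplicated(samples)) {
    stop("duplicate sample identifiers: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  out <- structure(values, domain = domain, class = c("gene_matrix", "matrix"))
  validate_gene_matrix(out)
  out
}

#' Validate the domain invariant of a gene matrix
#'
#' Checks every non-missing cell against the domain's value range and fails
#' with the offending gene/sample coordinates.
#'
#' @param gm A [gene_matrix()].
#' @return `gm`, invisibly, if valid.
#' @export
validate_gene_matrix <- function(gm) {
  domain <- attr(gm, "domain")
  bad <- switch(domain,
    cnv_call = !is.na(gm) & !(gm %in% c(-2, -1, 0, 1, 2)),
    pdui     = !is.na(gm) & (gm < 0 | gm > 1),
    array(FALSE, dim = dim(gm))
  )
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)
    shown <- utils::head(idx, 5)
    coords <- apply(shown, 1L, function(i) {
      sprintf("%s/%s=%g", rownames(gm)[i[1]], colnames(gm)[i[2]],
              gm[i[1], i[2]])
    })
    stop(sprintf(
      "%d value(s) violate the '%s' domain (gene/sample=value): %s%s",
      sum(bad), domain, paste(coords, collapse = ", "),
      if (nrow(idx) > 5) ", ..." else ""
    ))
  }
  invisible(gm)
}

#' @export
print.gene_matrix <- function(x, ...) {
  cat(sprintf("gene_matrix [%s]: %d genes x %d samples, %.1f%% missing\n",
              attr(x, "domain"), nrow(x), ncol(x), 100 * mean(is.na(x))))
  invisible(x)
}

#' Domain of a gene matrix
#' @param gm A [gene_matrix()].
#' @return The domain string.
#' @export
matrix_domain <- function(gm) attr(gm, "domain")

#' Read a gene-by-sample matrix from TSV
#'
#' Reads a tab-separated table whose first field is the gene symbol (or, when
#' transposed, the sample identifier), coerces non-numeric entries to missing
#' — mirroring the standard preprocessing that filters non-numeric cells from
#' GISTIC2 exports — and validates the requested domain. Orientation is
#' auto-detected by intersecting row labels with `known_genes` when supplied;
#' otherwise rows are assumed to be genes unless `orientation` says otherwise.
#' Lines starting with `#` are treated as comments (provenance headers).
#'
#' @param path Path to a TSV file.
#' @param domain Matrix domain, as in [gene_matrix()].
#' @param orientation `"auto"`, `"genes_in_rows"` or `"genes_in_columns"`.
#' @param known_genes Optional character vector used by `"auto"` orientation
#'   detection.
#' @return A [gene_matrix()].
#' @export
read_gene_matrix <- function(path, domain,
                             orientation = c("auto", "genes_in_rows",
                                             "genes_in_columns"),
                             known_genes = NULL) {
  orientation <- match.arg(orientation)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) < 2L) stop("gene matrix file has no data rows: ", path)
  dt <- data.table::fread(text = lines, sep = "\t", header = TRUE,
                          colClasses = "character", na.strings = NULL)
  if (ncol(dt) < 2L) stop("gene matrix file needs at least two columns: ", path)
  labels <- dt[[1L]]
  body <- as.matrix(dt[, -1L, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  dimnames(vals) <- list(labels, colnames(body))
  if (orientation == "auto") {
    orientation <- "genes_in_rows"
    if (!is.null(known_genes)) {
      in_rows <- length(intersect(labels, known_genes))
      in_cols <- length(intersect(colnames(body), known_genes))
      if (in_cols > in_rows) orientation <- "genes_in_columns"
    }
  }
  if (orientation == "genes_in_columns") vals <- t(vals)
  gene_matrix(vals, domain)
}

#' Write a gene matrix to TSV
#'
#' Writes the matrix gene-by-sample with a `gene` first column; missing
#' values become the literal `NA`. An optional comment-prefixed provenance
#' header is written first. [read_gene_matrix()] round-trips the output.
#'
#' @param gm A [gene_matrix()].
#' @param path Output path.
#' @param header Optional character vector of provenance lines (written with
#'   a leading `# `).
#' @return `path`, invisibly.
#' @export
write_gene_matrix <- function(gm, path, header = NULL) {
  if (!is.null(header)) writeLines(paste0("# ", header), path)
  dt <- data.table::data.table(gene = rownames(gm))
  for (s in colnames(gm)) dt[[s]] <- gm[, s]
  data.table::fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE,
                     append = !is.null(header), col.names = TRUE)
  invisible(path)
}
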