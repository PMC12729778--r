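#' The 16 core cleavage-and-polyadenylation genes by subcomplex
#'
#' Default mapping from CPA gene symbol to subcomplex. The CPSF complex
#' recognizes the polyadenylation signal and carries the endonuclease
#' (CPSF3); CSTF binds the downstream U/GU-rich element; CFIm (NUDT21,
#' CPSF6/7) and CFIIm (CLP1, PCF11) promote distal and proximal poly(A) site
#' usage respectively.
#'
#' @return Named character vector: names are the 16 gene symbols, values the
#'   subcomplex (`CPSF`, `CSTF`, `CFI`, `CFII`).
#' @export
cpa_complex_map <- function() {
  c(
    CPSF1 = "CPSF", CPSF2 = "CPSF", CPSF3 = "CPSF", CPSF4 = "CPSF",
    WDR33 = "CPSF", SYMPK = "CPSF", FIP1L1 = "CPSF",
    CSTF1 = "CSTF", CSTF2 = "CSTF", CSTF2T = "CSTF", CSTF3 = "CSTF",
    NUDT21 = "CFI", CPSF6 = "CFI", CPSF7 = "CFI",
    CLP1 = "CFII", PCF11 = "CFII"
  )
}

#' The 16 core CPA gene symbols
#' @return Character vector of gene symbols.
#' @export
cpa_genes <- function() names(cpa_complex_map())

# MC3-style nonsilent variant classes, plus Silent and a catch-all.
maf_variant_classes <- function() {
  c("Missense_Mutation", "Nonsense_Mutation", "Frame_Shift_Del",
    "Frame_Shift_Ins", "Splice_Site", "In_Frame_Del", "In_Frame_Ins",
    "Translation_Start_Site", "Nonstop_Mutation", "Silent", "other")
}

# Parse a protein position from Protein_position ("123/456", "123-125/456")
# or HGVSp_Short ("p.R123Q", "p.R123*", "p.X123_splice") fields.
parse_protein_position <- function(protein_position, hgvsp, n = NULL) {
  if (is.null(n)) n <- max(length(protein_position), length(hgvsp))
  pos <- rep(NA_integer_, n)
  if (!is.null(protein_position)) {
    has <- !is.na(protein_position) & grepl("^[0-9]", protein_position)
    pos[has] <- as.integer(sub("^([0-9]+).*$", "\\1",
                               protein_position[has]))
  }
  if (!is.null(hgvsp)) {
    need <- is.na(pos) & !is.na(hgvsp) & grepl("^p\\.", hgvsp)
    pos[need] <- suppressWarnings(
      as.integer(sub("^p\\.[A-Za-z*]+([0-9]+).*$", "\\1", hgvsp[need]))
    )
  }
  pos[!is.na(pos) & pos < 1L] <- NA_integer_
  pos
}

#' Read somatic mutations from a MAF file
#'
#' Reads a Mutation Annotation Format file (tab-separated, MC3 dialect,
#' optionally gzipped) into one record per mutation. Only the columns the
#' downstream summaries need are retained. Sample barcodes are truncated to
#' `barcode_length` characters so that mutation, copy-number and clinical
#' tables sharing TCGA-style barcodes of different depths can be joined at
#' the sample level.
#'
#' @param path Path to a MAF file (`.maf` or `.maf.gz`).
#' @param silent_policy `"drop"` (default) removes `Silent` rows — the
#'   convention for nonsilent mutation landscapes — `"keep"` retains them.
#' @param barcode_length Number of leading barcode characters that identify a
#'   sample (default 15, the TCGA sample level). Use `Inf` to keep barcodes
#'   untouched.
#' @return A `data.frame` with columns `sample_id`, `gene`,
#'   `variant_classification`, `protein_position` (integer, `NA` when
#'   unavailable) and `protein_change`.
#' @export
read_maf <- function(path, silent_policy = c("drop", "keep"),
                     barcode_length = 15) {
  silent_policy <- match.arg(silent_policy)
  dt <- data.table::fread(path, sep = "\t", header = TRUE, quote = "",
                          data.table = TRUE, showProgress = FALSE)
  required <- c("Hugo_Symbol", "Tumor_Sample_Barcode",
                "Variant_Classification")
  missing_cols <- setdiff(required, names(dt))
  if (length(missing_cols) > 0L) {
    stop("MAF file is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (silent_policy == "drop") {
    dt <- dt[dt$Variant_Classification != "Silent", ]
  }
  sample_id <- as.character(dt$Tumor_Sample_Barcode)
  if (is.finite(barcode_length)) {
    sample_id <- substr(sample_id, 1L, barcode_length)
  }
  vc <- as.character(dt$Variant_Classification)
  vc[!(vc %in% maf_variant_classes())] <- "other"
  hgvsp <- if ("HGVSp_Short" %in% names(dt)) as.character(dt$HGVSp_Short)
           else NULL
  ppos <- if ("Protein_position" %in% names(dt))
            as.character(dt$Protein_position) else NULL
  data.frame(
    sample_id = sample_id,
    gene = as.character(dt$Hugo_Symbol),
    variant_classification = vc,
    protein_position = parse_protein_position(ppos, hgvsp,
                                              n = length(sample_id)),
    protein_change = if (!is.null(hgvsp)) hgvsp else NA_character_,
    stringsAsFactors = FALSE
  )
}

#' Read a clinical survival table
#'
#' Reads a tab-separated clinical table in the Xena survival dialect: one row
#' per sample with overall-survival and progression-free-interval time
#' (months or days, kept as given) and event columns. Unparseable time or
#' event fields become missing; the corresponding record is then simply
#' excluded from any analysis using that endpoint.
#'
#' @param path Path to the TSV file.
#' @param columns Named list mapping the logical fields `sample`, `os_time`,
#'   `os_event`, `pfs_time`, `pfs_event` to column names in the file.
#' @return A `data.frame` with columns `sample_id`, `os_time`, `os_event`,
#'   `pfs_time`, `pfs_event`.
#' @export
read_clinical <- function(path,
                          columns = list(sample = "sample",
                                         os_time = "OS.time", os_event = "OS",
                                         pfs_time = "PFI.time",
                                         pfs_event = "PFI")) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          showProgress = FALSE)
  if (!columns$sample %in% names(dt)) {
    stop("clinical file has no sample column '", columns$sample, "'")
  }
  get_num <- function(col) {
    if (!col %in% names(dt)) return(rep(NA_real_, nrow(dt)))
    suppressWarnings(as.numeric(dt[[col]]))
  }
  out <- data.frame(
    sample_id = as.character(dt[[columns$sample]]),
    os_time = get_num(columns$os_time),
    os_event = get_num(columns$os_event),
    pfs_time = get_num(columns$pfs_time),
    pfs_event = get_num(columns$pfs_event),
    stringsAsFactors = FALSE
  )
  for (tcol in c("os_time", "pfs_time")) {
    bad <- !is.na(out[[tcol]]) & out[[tcol]] < 0
    if (any(bad)) {
      stop(sum(bad), " negative ", tcol, " value(s) in ", path)
    }
  }
  for (ecol in c("os_event", "pfs_event")) {
    out[[ecol]][!is.na(out[[ecol]]) & !(out[[ecol]] %in% c(0, 1))] <- NA_real_
  }
  out
}

#' Read a GMT gene-set collection
#'
#' Standard GMT format: one set per line — name, description, then gene
#' symbols, tab-separated. Descriptions are dropped and duplicate genes
#' within a set deduplicated.
#'
#' @param path Path to a `.gmt` file.
#' @return Named list of character vectors (set name -> gene symbols).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L) {
      stop("GMT line with no genes: ", substr(ln, 1, 50))
    }
    genes <- unique(parts[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0L) {
      stop("GMT set '", parts[1L], "' has an empty gene list")
    }
    genes
  })
  names(sets) <- vapply(lines, function(ln) {
    strsplit(ln, "\t", fixed = TRUE)[[1L]][1L]
  }, character(1L), USE.NAMES = FALSE)
  sets
}
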