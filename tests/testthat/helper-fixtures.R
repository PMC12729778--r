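# Programmatic fixtures: tiny files written to tempdir at test time.

write_toy_maf <- function(rows, path = tempfile(fileext = ".maf")) {
  header <- c("Hugo_Symbol", "Tumor_Sample_Barcode",
              "Variant_Classification", "HGVSp_Short")
  lines <- c(paste(header, collapse = "\t"),
             vapply(rows, function(r) paste(r, collapse = "\t"),
                    character(1L)))
  writeLines(lines, path)
  path
}

write_toy_matrix_tsv <- function(mat, path = tempfile(fileext = ".tsv")) {
  lines <- c(
    paste(c("gene", colnames(mat)), collapse = "\t"),
    vapply(seq_len(nrow(mat)), function(i) {
      paste(c(rownames(mat)[i], mat[i, ]), collapse = "\t")
    }, character(1L))
  )
  writeLines(lines, path)
  path
}

toy_cnv <- function(values, genes = NULL, samples = NULL) {
  m <- matrix(values, nrow = if (is.null(genes)) 1L else length(genes),
              byrow = TRUE)
  rownames(m) <- if (is.null(genes)) "G1" else genes
  colnames(m) <- if (is.null(samples)) sprintf("S%d", seq_len(ncol(m)))
                 else samples
  gene_matrix(m, "cnv_call")
}

toy_records <- function(sample_id, gene,
                        vc = "Missense_Mutation", pos = NA_integer_) {
  n <- max(length(sample_id), length(gene))
  if (n == 0L) {
    return(data.frame(sample_id = character(), gene = character(),
                      variant_classification = character(),
                      protein_position = integer(),
                      protein_change = character(),
                      stringsAsFactors = FALSE))
  }
  data.frame(sample_id = rep_len(sample_id, n), gene = rep_len(gene, n),
             variant_classification = rep_len(vc, n),
             protein_position = rep_len(as.integer(pos), n),
             protein_change = NA_character_, stringsAsFactors = FALSE)
}
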