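test_that("MAF reading counts rows and applies the silent policy", {
  path <- write_toy_maf(list(
    c("CPSF1", "TCGA-AA-0001-01A-XXX", "Missense_Mutation", "p.R123Q"),
    c("PCF11", "TCGA-AA-0002-01A-XXX", "Missense_Mutation", "p.G45V"),
    c("WDR33", "TCGA-AA-0003-01A-XXX", "Silent", "")
  ))
  keep <- read_maf(path, silent_policy = "keep")
  expect_equal(nrow(keep), 3L)
  drop <- read_maf(path, silent_policy = "drop")
  expect_equal(nrow(drop), 2L)
  expect_false("Silent" %in% drop$variant_classification)
  # barcode truncated to the 15-character sample level
  expect_equal(drop$sample_id[1], "TCGA-AA-0001-01")
  # protein position parsed from HGVSp_Short by the p.<aa><pos> pattern
  expect_equal(drop$protein_position, c(123L, 45L))
})

test_that("MAF reading fails on a missing mandatory column", {
  path <- tempfile(fileext = ".maf")
  writeLines(c("Hugo_Symbol\tVariant_Classification",
               "CPSF1\tMissense_Mutation"), path)
  expect_error(read_maf(path), "Tumor_Sample_Barcode")
})

test_that("gene matrix TSV reading handles NA cells and validates domains", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tS1\tS2\tS3",
               "CPSF1\t2\t0\tNA",
               "MYC\t0\t-1\t1"), path)
  gm <- read_gene_matrix(path, "cnv_call")
  expect_equal(dim(gm), c(2L, 3L))
  expect_true(is.na(gm["CPSF1", "S3"]))
  expect_equal(unname(gm["MYC", ]), c(0, -1, 1))

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tS1\tS2", "G1\t0.5\t1.2"), bad)
  expect_error(read_gene_matrix(bad, "pdui"), "pdui")
  expect_s3_class(read_gene_matrix(bad, "zscore"), "gene_matrix")
})

test_that("duplicate gene symbols are a format error", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tS1", "G1\t0", "G1\t1"), path)
  expect_error(read_gene_matrix(path, "cnv_call"), "duplicate")
})

test_that("gene matrices round-trip through TSV", {
  set.seed(8)
  m <- matrix(runif(12), 3, 4,
              dimnames = list(c("A", "B", "C"), sprintf("S%d", 1:4)))
  m[2, 3] <- NA
  gm <- gene_matrix(m, "pdui")
  path <- tempfile(fileext = ".tsv")
  write_gene_matrix(gm, path, header = c("tool test", "seed=1"))
  back <- read_gene_matrix(path, "pdui")
  expect_equal(rownames(back), rownames(gm))
  expect_equal(colnames(back), colnames(gm))
  expect_equal(unclass(back), unclass(gm), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_true(is.na(back[2, 3]))
})

test_that("domain validation catches a single bad cell at any coordinate", {
  set.seed(9)
  for (rep in 1:10) {
    nr <- sample(2:6, 1)
    nc <- sample(2:6, 1)
    m <- matrix(sample(c(-2, -1, 0, 1, 2), nr * nc, replace = TRUE), nr, nc,
                dimnames = list(sprintf("G%d", 1:nr), sprintf("S%d", 1:nc)))
    i <- sample(nr, 1)
    j <- sample(nc, 1)
    m[i, j] <- 3
    expect_error(gene_matrix(m, "cnv_call"), "cnv_call")
  }
})

test_that("orientation auto-detection transposes sample-by-gene tables", {
  m <- matrix(c(2, 0, 1, -1, 0, 0), nrow = 3,
              dimnames = list(sprintf("S%d", 1:3), c("CPSF1", "MYC")))
  path <- tempfile(fileext = ".tsv")
  lines <- c(paste(c("sample", colnames(m)), collapse = "\t"),
             vapply(1:3, function(i) {
               paste(c(rownames(m)[i], m[i, ]), collapse = "\t")
             }, character(1)))
  writeLines(lines, path)
  gm <- read_gene_matrix(path, "cnv_call", known_genes = c("CPSF1", "MYC"))
  expect_equal(rownames(gm), c("CPSF1", "MYC"))
  expect_equal(unname(gm["CPSF1", ]), c(2, 0, 1))
})

test_that("clinical tables parse times/events and reject negatives", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("sample\tOS.time\tOS\tPFI.time\tPFI",
               "S1\t10.5\t1\t8\t1",
               "S2\t\t0\t12\t0",
               "S3\t30\t1\t\t"), path)
  cl <- read_clinical(path)
  expect_equal(nrow(cl), 3L)
  expect_true(is.na(cl$os_time[2]))
  expect_true(is.na(cl$pfs_event[3]))
  expect_equal(cl$os_time[1], 10.5)

  neg <- tempfile(fileext = ".tsv")
  writeLines(c("sample\tOS.time\tOS\tPFI.time\tPFI",
               "S1\t-3\t1\t1\t1"), neg)
  expect_error(read_clinical(neg), "negative")
})

test_that("GMT parsing drops descriptions and deduplicates genes", {
  path <- tempfile(fileext = ".gmt")
  writeLines(c("SET_A\tdesc\tG1\tG2\tG3",
               "SET_B\tdesc\tG1\tG4\tG5\tG5\tG6"), path)
  gs <- read_gmt(path)
  expect_equal(names(gs), c("SET_A", "SET_B"))
  expect_equal(lengths(gs), c(SET_A = 3L, SET_B = 4L))

  empty <- tempfile(fileext = ".gmt")
  writeLines("SET_X\tdesc", empty)
  expect_error(read_gmt(empty), "genes")
})

test_that("the CPA complex map covers the 16 genes uniquely", {
  cm <- cpa_complex_map()
  expect_equal(length(cm), 16L)
  expect_false(anyDuplicated(names(cm)) > 0)
  expect_setequal(unique(unname(cm)), c("CPSF", "CSTF", "CFI", "CFII"))
  expect_equal(sum(cm == "CPSF"), 7L)
  expect_equal(sum(cm == "CSTF"), 4L)
})
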