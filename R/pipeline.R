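#' Run the whole analysis as one reproducible pipeline
#'
#' Orchestrates the full study on a synthetic cohort: simulate the cohort,
#' summarize the mutation landscape (per-gene frequencies, variant-class
#' tallies, subcomplex shares), compute copy-number alteration frequencies,
#' test index/partner amplification co-occurrence, compare survival between
#' median-split copy-number groups (all samples and confounder-diploid
#' samples, both endpoints), run the APA quadrant pipeline and, when a
#' gene-set collection is supplied, the per-quadrant enrichment. Every
#' output table is written as TSV with a comment-prefixed provenance header
#' (package version, seed, configuration hash), so repeated runs with the
#' same configuration are byte-identical.
#'
#' @param sim A [sim_config()] describing the cohort.
#' @param outdir Output directory (created if needed).
#' @param apa An [apa_config()].
#' @param collection Optional named list of gene sets for enrichment.
#' @param endpoints Survival endpoints to run (subset of `c("OS", "PFS")`).
#' @return Invisibly, a list with `manifest` (named vector of written file
#'   paths), `summary` (headline statistics) and the in-memory stage
#'   results.
#' @export
run_all <- function(sim = sim_config(), outdir, apa = apa_config(),
                    collection = NULL, endpoints = c("OS", "PFS")) {
  endpoints <- match.arg(endpoints, several.ok = TRUE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  prov <- c(
    sprintf("apacnv %s", as.character(utils::packageVersion("apacnv"))),
    sprintf("seed=%d", sim$seed),
    sprintf("config_hash=%s", rlang::hash(list(sim = unclass(sim),
                                               apa = unclass(apa))))
  )
  manifest <- character()
  emit <- function(df, name) {
    path <- file.path(outdir, name)
    writeLines(paste0("# ", prov), path)
    data.table::fwrite(df, path, sep = "\t", na = "NA", quote = FALSE,
                       append = TRUE, col.names = TRUE)
    manifest[[name]] <<- path
    path
  }

  stage <- "simulate"
  res <- tryCatch({
    cohort <- simulate_cohort(sim)
    write_gene_matrix(cohort$cnv_calls,
                      file.path(outdir, "cnv_calls.tsv"), header = prov)
    manifest[["cnv_calls.tsv"]] <- file.path(outdir, "cnv_calls.tsv")
    write_gene_matrix(cohort$cnv_continuous,
                      file.path(outdir, "cnv_continuous.tsv"), header = prov)
    manifest[["cnv_continuous.tsv"]] <- file.path(outdir,
                                                  "cnv_continuous.tsv")
    write_gene_matrix(cohort$pdui, file.path(outdir, "pdui.tsv"),
                      header = prov)
    manifest[["pdui.tsv"]] <- file.path(outdir, "pdui.tsv")
    write_gene_matrix(cohort$zscore, file.path(outdir, "zscore.tsv"),
                      header = prov)
    manifest[["zscore.tsv"]] <- file.path(outdir, "zscore.tsv")
    emit(cohort$clinical, "clinical.tsv")
    emit(cohort$mutations, "mutations.tsv")
    emit(cohort$truth, "planted_truth.tsv")

    stage <- "mutation_landscape"
    freq <- mutation_frequency(cohort$mutations, cpa_genes(),
                               n_total = sim$n_samples)
    tally <- variant_class_tally(cohort$mutations)
    shares <- complex_share(cohort$mutations)
    emit(freq, "mutation_frequency.tsv")
    emit(tally, "variant_class_tally.tsv")
    emit(shares, "complex_share.tsv")

    stage <- "cnv_landscape"
    cnv_freq <- cnv_frequencies(cohort$cnv_calls)
    emit(cnv_freq, "cnv_frequencies.tsv")

    stage <- "cooccurrence"
    cooc <- cooccurrence_screen(
      cohort$cnv_calls, list(c(sim$index_gene, sim$partner_gene))
    )
    emit(cooc, "cooccurrence.tsv")

    stage <- "survival"
    cn <- cohort$cnv_continuous[sim$index_gene, ]
    groups_all <- suppressWarnings(stratify_by_value(cn))
    dip <- filter_diploid(cohort$cnv_calls, sim$partner_gene)
    groups_dip <- suppressWarnings(stratify_by_value(cn[dip]))
    surv_rows <- list()
    surv <- list()
    for (ep in endpoints) {
      for (co in c("all", "confounder_diploid")) {
        grp <- if (co == "all") groups_all else groups_dip
        cmp <- compare_survival(cohort$clinical, grp, ep)
        surv[[paste(ep, co, sep = "_")]] <- cmp
        surv_rows[[length(surv_rows) + 1L]] <- data.frame(
          endpoint = ep, cohort = co,
          n_high = cmp$n[["high"]], n_low = cmp$n[["low"]],
          median_high = cmp$medians[["high"]],
          median_low = cmp$medians[["low"]],
          logrank_chi2 = cmp$logrank_chi2, logrank_p = cmp$logrank_p,
          stringsAsFactors = FALSE
        )
      }
    }
    emit(do.call(rbind, surv_rows), "survival_summary.tsv")

    stage <- "apa_quadrant"
    apa_res <- run_apa_pipeline(
      cohort$cnv_calls, cohort$cnv_continuous, cohort$pdui, cohort$zscore,
      index_gene = sim$index_gene, confounder_gene = sim$partner_gene,
      config = apa
    )
    emit(apa_res, "apa_results.tsv")

    enr <- NULL
    if (!is.null(collection)) {
      stage <- "enrichment"
      enr <- quadrant_enrichment(apa_res, collection)
      for (qd in names(enr)) {
        emit(enr[[qd]], sprintf("enrichment_%s.tsv", qd))
      }
    }

    list(cohort = cohort, mutation_frequency = freq, variant_tally = tally,
         complex_share = shares, cnv_frequencies = cnv_freq,
         cooccurrence = cooc, survival = surv, apa = apa_res,
         enrichment = enr)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })

  apa_res <- res$apa
  class_counts <- table(factor(apa_res$apa_class,
                               levels = c("lengthened", "shortened",
                                          "unchanged", "untested")))
  summary <- list(
    n_samples = sim$n_samples,
    n_altered_subjects = attr(res$mutation_frequency, "n_altered_subjects"),
    index_amplification_pct =
      res$cnv_frequencies$pct_amplification[
        res$cnv_frequencies$gene == sim$index_gene],
    co_amp_pct_partner_given_index = res$cooccurrence$pct_b_given_a[1L],
    survival = lapply(res$survival, function(s) {
      list(medians = s$medians, logrank_p = s$logrank_p)
    }),
    n_lengthened = unname(class_counts[["lengthened"]]),
    n_shortened = unname(class_counts[["shortened"]]),
    quadrant_counts = table(apa_res$quadrant)
  )
  sm <- data.frame(
    key = c("n_samples", "n_altered_subjects", "index_amplification_pct",
            "co_amp_pct_partner_given_index", "n_lengthened", "n_shortened"),
    value = c(summary$n_samples, summary$n_altered_subjects,
              round(summary$index_amplification_pct, 6),
              round(summary$co_amp_pct_partner_given_index, 6),
              summary$n_lengthened, summary$n_shortened),
    stringsAsFactors = FALSE
  )
  emit(sm, "summary.tsv")
  invisible(list(manifest = manifest, summary = summary, results = res))
}
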