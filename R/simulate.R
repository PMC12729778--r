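#' Configuration for the synthetic tumor cohort
#'
#' Builds and validates the full parameter set for the cohort simulator. The
#' defaults reproduce the statistical structure reported for the TCGA
#' pan-cancer CPA-gene landscape: the index gene (CPSF1-like) has GISTIC2
#' call probabilities (deep deletion, shallow deletion, diploid, gain,
#' amplification) = (0.002, 0.059, 0.51, 0.373, 0.056); the partner gene
#' (MYC-like, co-located on the same amplicon) is amplified with probability
#' 0.847 given index amplification; and the variant-class mixture puts 61.6%
#' on missense and 26.4% on nonsense mutations.
#'
#' `partner_background_amp_prob` defaults to 0.0354, the value at which the
#' two reported conditionals (84.7% partner-given-index and 58.7%
#' index-given-partner amplification) are simultaneously consistent with an
#' index amplification rate of 5.6%.
#'
#' @param n_samples Number of samples (default 400).
#' @param n_genes Number of genes in the PDUI/expression matrices
#'   (default 1000).
#' @param seed Integer seed; every simulator stage derives its stream from it.
#' @param index_gene,partner_gene Symbols of the copy-number index gene and
#'   its co-amplified partner.
#' @param cnv_state_probs Probability vector over calls (-2,-1,0,1,2) for the
#'   index gene.
#' @param co_amp_prob P(partner amplified | index amplified).
#' @param partner_background_amp_prob P(partner amplified | index not
#'   amplified).
#' @param pdui_baseline Beta shape pair `c(a, b)` for baseline PDUI.
#' @param n_shortened,n_lengthened Number of genes with a planted 3'UTR
#'   shortening / lengthening effect.
#' @param delta_effect PDUI shift magnitude in high-copy samples, in (0, 1).
#' @param pdui_missing_rate Probability that a PDUI cell is missing
#'   (DaPars-style coverage dropout).
#' @param expr_coupling Mean Z-score shift in high-copy samples for planted
#'   genes: +`expr_coupling` for shortened genes, -`expr_coupling` for
#'   lengthened genes (shortening raises, lengthening lowers expression).
#' @param expr_flip_frac Fraction of planted genes whose expression shift
#'   takes the opposite sign, populating all four quadrants.
#' @param expr_noise_sd Z-score noise standard deviation.
#' @param log_hr_per_copy_unit Log hazard ratio of death per unit of the
#'   index gene's continuous copy number.
#' @param baseline_hazard Baseline event hazard (events per month).
#' @param censor_rate Independent exponential censoring hazard per month.
#' @param mutation_rate_per_gene Per-sample mutation probability for each CPA
#'   gene.
#' @param variant_class_probs Named probability vector over variant classes.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 400,
                       n_genes = 1000,
                       seed = 1,
                       index_gene = "CPSF1",
                       partner_gene = "MYC",
                       cnv_state_probs = c(0.002, 0.059, 0.51, 0.373, 0.056),
                       co_amp_prob = 0.847,
                       partner_background_amp_prob = 0.0354,
                       pdui_baseline = c(5, 5),
                       n_shortened = 50,
                       n_lengthened = 50,
                       delta_effect = 0.3,
                       pdui_missing_rate = 0.05,
                       expr_coupling = 1,
                       expr_flip_frac = 0.2,
                       expr_noise_sd = 1,
                       log_hr_per_copy_unit = 0.5,
                       baseline_hazard = 0.01,
                       censor_rate = 0.005,
                       mutation_rate_per_gene = 0.0075,
                       variant_class_probs = c(
                         Missense_Mutation = 0.616,
                         Nonsense_Mutation = 0.264,
                         Frame_Shift_Del = 0.03,
                         Frame_Shift_Ins = 0.02,
                         Splice_Site = 0.04,
                         In_Frame_Del = 0.01,
                         In_Frame_Ins = 0.005,
                         Translation_Start_Site = 0.005,
                         Nonstop_Mutation = 0.01
                       )) {
  cfg <- list(
    n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
    seed = as.integer(seed),
    index_gene = index_gene, partner_gene = partner_gene,
    cnv_state_probs = cnv_state_probs, co_amp_prob = co_amp_prob,
    partner_background_amp_prob = partner_background_amp_prob,
    pdui_baseline = pdui_baseline,
    n_shortened = as.integer(n_shortened),
    n_lengthened = as.integer(n_lengthened),
    delta_effect = delta_effect, pdui_missing_rate = pdui_missing_rate,
    expr_coupling = expr_coupling, expr_flip_frac = expr_flip_frac,
    expr_noise_sd = expr_noise_sd,
    log_hr_per_copy_unit = log_hr_per_copy_unit,
    baseline_hazard = baseline_hazard, censor_rate = censor_rate,
    mutation_rate_per_gene = mutation_rate_per_gene,
    variant_class_probs = variant_class_probs
  )
  stopifnot(
    cfg$n_samples >= 1, cfg$n_genes >= 1,
    length(cfg$cnv_state_probs) == 5,
    abs(sum(cfg$cnv_state_probs) - 1) < 1e-9,
    all(cfg$cnv_state_probs >= 0),
    abs(sum(cfg$variant_class_probs) - 1) < 1e-9,
    all(cfg$variant_class_probs >= 0),
    cfg$co_amp_prob >= 0, cfg$co_amp_prob <= 1,
    cfg$partner_background_amp_prob >= 0,
    cfg$partner_background_amp_prob <= 1,
    cfg$delta_effect >= 0, cfg$delta_effect < 1,
    cfg$pdui_missing_rate >= 0, cfg$pdui_missing_rate <= 1,
    cfg$expr_flip_frac >= 0, cfg$expr_flip_frac <= 1,
    cfg$n_shortened + cfg$n_lengthened <= cfg$n_genes,
    all(cfg$pdui_baseline > 0), length(cfg$pdui_baseline) == 2,
    cfg$baseline_hazard > 0, cfg$censor_rate >= 0,
    cfg$mutation_rate_per_gene >= 0, cfg$mutation_rate_per_gene <= 1
  )
  class(cfg) <- "sim_config"
  cfg
}

# Fixed continuous-value intervals per GISTIC2 call; chosen disjoint so the
# discrete call is exactly recoverable from the continuous value.
cnv_call_intervals <- function() {
  data.frame(
    call = c(-2, -1, 0, 1, 2),
    lower = c(-2, -1.5, -0.25, 0.25, 1.5),
    upper = c(-1.5, -0.25, 0.25, 1.5, 2.5)
  )
}

#' Decode continuous copy-number values back to GISTIC2 calls
#'
#' Inverts the fixed call-to-interval mapping used by [simulate_cnv()].
#'
#' @param values Numeric vector or matrix of continuous copy-number values.
#' @return Integer calls in \{-2..2\} (`NA` outside all intervals).
#' @export
decode_cnv_call <- function(values) {
  iv <- cnv_call_intervals()
  out <- array(NA_real_, dim = if (is.null(dim(values))) length(values)
                               else dim(values))
  for (i in seq_len(nrow(iv))) {
    hit <- !is.na(values) & values >= iv$lower[i] & values < iv$upper[i]
    out[hit] <- iv$call[i]
  }
  if (!is.null(dim(values))) {
    dimnames(out) <- dimnames(values)
  } else {
    out <- as.vector(out)
  }
  out
}

sample_ids <- function(n) sprintf("SYN-%04d", seq_len(n))

#' Simulate gene-level copy number
#'
#' Draws GISTIC2-style calls for every tracked CPA gene plus the partner
#' gene. The index gene's calls follow `cnv_state_probs`; the partner gene is
#' amplified with probability `co_amp_prob` when the index gene is amplified
#' and `partner_background_amp_prob` otherwise (non-amplified partner calls
#' are drawn mostly diploid); the other CPA genes are diploid. A matching
#' continuous-value matrix is drawn uniformly within fixed per-call intervals
#' (call -2 in \[-2,-1.5), -1 in \[-1.5,-0.25), 0 in \[-0.25,0.25),
#' 1 in \[0.25,1.5), 2 in \[1.5,2.5)) so [decode_cnv_call()] recovers the
#' calls exactly.
#'
#' @param config A [sim_config()].
#' @return List with `calls` and `continuous`, both [gene_matrix()] objects
#'   over the 16 CPA genes plus the partner gene.
#' @export
simulate_cnv <- function(config) {
  set.seed(config$seed + 101L)
  n <- config$n_samples
  samples <- sample_ids(n)
  genes <- union(cpa_genes(), c(config$index_gene, config$partner_gene))
  calls <- matrix(0, nrow = length(genes), ncol = n,
                  dimnames = list(genes, samples))
  states <- c(-2, -1, 0, 1, 2)
  idx_call <- sample(states, n, replace = TRUE, prob = config$cnv_state_probs)
  calls[config$index_gene, ] <- idx_call
  amp <- idx_call == 2
  p_amp <- ifelse(amp, config$co_amp_prob, config$partner_background_amp_prob)
  partner_amp <- stats::runif(n) < p_amp
  # non-amplified partner: mostly diploid with some gain/shallow deletion
  partner_rest <- sample(c(-1, 0, 1), n, replace = TRUE,
                         prob = c(0.1, 0.7, 0.2))
  calls[config$partner_gene, ] <- ifelse(partner_amp, 2, partner_rest)
  iv <- cnv_call_intervals()
  cont <- calls
  for (i in seq_len(nrow(iv))) {
    hit <- calls == iv$call[i]
    cont[hit] <- stats::runif(sum(hit), iv$lower[i], iv$upper[i])
  }
  list(
    calls = gene_matrix(calls, "cnv_call"),
    continuous = gene_matrix(cont, "cnv_continuous")
  )
}

# Samples in the top quartile of the index gene's continuous copy number --
# the "high-copy" samples that receive planted APA/expression effects.
high_copy_samples <- function(config, cnv_continuous) {
  v <- cnv_continuous[config$index_gene, ]
  colnames(cnv_continuous)[!is.na(v) & v >= quantile_lin(v, 0.75)]
}

#' Simulate a PDUI matrix with planted APA shifts
#'
#' Baseline PDUI is Beta(a, b) per cell. For the `n_shortened` planted genes,
#' samples in the top quartile of the index gene's continuous copy number
#' have PDUI reduced by `delta_effect` (3'UTR shortening under high copy
#' number); lengthened genes get `+delta_effect`. Values are clipped to
#' \[0, 1\] and cells are set missing independently at `pdui_missing_rate`.
#'
#' @param config A [sim_config()].
#' @param cnv_continuous Continuous copy-number [gene_matrix()] from
#'   [simulate_cnv()].
#' @return List with `pdui` (a [gene_matrix()]) and `truth` (data.frame with
#'   columns `gene`, `planted_class` in \{shortened, lengthened, unchanged\}).
#' @export
simulate_pdui <- function(config, cnv_continuous) {
  set.seed(config$seed + 202L)
  n <- config$n_samples
  samples <- colnames(cnv_continuous)
  genes <- sprintf("GENE%04d", seq_len(config$n_genes))
  a <- config$pdui_baseline[1]
  b <- config$pdui_baseline[2]
  pdui <- matrix(stats::rbeta(config$n_genes * n, a, b),
                 nrow = config$n_genes, ncol = n,
                 dimnames = list(genes, samples))
  planted_class <- rep("unchanged", config$n_genes)
  if (config$n_shortened > 0) {
    planted_class[seq_len(config$n_shortened)] <- "shortened"
  }
  if (config$n_lengthened > 0) {
    planted_class[config$n_shortened + seq_len(config$n_lengthened)] <-
      "lengthened"
  }
  high <- high_copy_samples(config, cnv_continuous)
  if (config$delta_effect > 0 && length(high) > 0) {
    shift <- ifelse(planted_class == "shortened", -config$delta_effect,
                    ifelse(planted_class == "lengthened",
                           config$delta_effect, 0))
    pdui[, high] <- pdui[, high] + shift
    pdui[pdui < 0] <- 0
    pdui[pdui > 1] <- 1
  }
  if (config$pdui_missing_rate > 0) {
    drop <- stats::runif(length(pdui)) < config$pdui_missing_rate
    pdui[drop] <- NA_real_
  }
  list(
    pdui = gene_matrix(pdui, "pdui"),
    truth = data.frame(gene = genes, planted_class = planted_class,
                       stringsAsFactors = FALSE)
  )
}

#' Simulate expression Z-scores coupled to planted APA shifts
#'
#' Z-scores are Normal(mu, `expr_noise_sd`) with mu = 0 everywhere except
#' planted genes in high-copy samples: `+expr_coupling` for shortened genes
#' and `-expr_coupling` for lengthened genes (3'UTR shortening raising and
#' lengthening lowering expression), with an `expr_flip_frac` fraction of
#' planted genes receiving the opposite sign so that all four
#' APA-by-expression quadrants are populated.
#'
#' @param config A [sim_config()].
#' @param truth Planted-truth table from [simulate_pdui()].
#' @param cnv_continuous Continuous copy-number matrix from [simulate_cnv()].
#' @return A `zscore` [gene_matrix()] over the same genes and samples.
#' @export
simulate_expression <- function(config, truth, cnv_continuous) {
  set.seed(config$seed + 303L)
  n <- config$n_samples
  samples <- colnames(cnv_continuous)
  genes <- truth$gene
  mu <- matrix(0, nrow = length(genes), ncol = n,
               dimnames = list(genes, samples))
  flipped <- rep(FALSE, length(genes))
  if (config$expr_flip_frac > 0) {
    for (cls in c("shortened", "lengthened")) {
      members <- which(truth$planted_class == cls)
      n_flip <- floor(length(members) * config$expr_flip_frac)
      flipped[members[seq_len(n_flip)]] <- TRUE
    }
  }
  high <- high_copy_samples(config, cnv_continuous)
  if (length(high) > 0) {
    base_shift <- ifelse(truth$planted_class == "shortened",
                         config$expr_coupling,
                         ifelse(truth$planted_class == "lengthened",
                                -config$expr_coupling, 0))
    base_shift[flipped] <- -base_shift[flipped]
    mu[, high] <- base_shift
  }
  z <- mu + stats::rnorm(length(mu), sd = config$expr_noise_sd)
  dimnames(z) <- dimnames(mu)
  gene_matrix(z, "zscore")
}

#' Simulate right-censored survival coupled to copy number
#'
#' Event times are exponential with hazard `baseline_hazard *
#' exp(log_hr_per_copy_unit * c)` where `c` is the sample's continuous copy
#' number of the index gene; censoring times are exponential at
#' `censor_rate` (no censoring when 0). Observed time is the minimum,
#' in months. OS and PFS are drawn independently from the same model.
#'
#' @param config A [sim_config()].
#' @param cnv_continuous Continuous copy-number matrix from [simulate_cnv()].
#' @return A clinical `data.frame` as returned by [read_clinical()].
#' @export
simulate_survival <- function(config, cnv_continuous) {
  set.seed(config$seed + 404L)
  n <- config$n_samples
  cn <- cnv_continuous[config$index_gene, ]
  hazard <- config$baseline_hazard * exp(config$log_hr_per_copy_unit * cn)
  draw <- function() {
    t_event <- stats::rexp(n, rate = hazard)
    t_cens <- if (config$censor_rate > 0) {
      stats::rexp(n, rate = config$censor_rate)
    } else {
      rep(Inf, n)
    }
    list(time = pmin(t_event, t_cens),
         event = as.numeric(t_event <= t_cens))
  }
  os <- draw()
  pfs <- draw()
  data.frame(
    sample_id = colnames(cnv_continuous),
    os_time = os$time, os_event = os$event,
    pfs_time = pfs$time, pfs_event = pfs$event,
    stringsAsFactors = FALSE
  )
}

# Plausible protein lengths (aa) for the CPA genes, used as the support of
# the uniform mutation-position draw. Synthetic defaults, UniProt-scale.
cpa_protein_lengths <- function() {
  c(CPSF1 = 1443, CPSF2 = 782, CPSF3 = 684, CPSF4 = 269, WDR33 = 1336,
    SYMPK = 1274, FIP1L1 = 594, CSTF1 = 431, CSTF2 = 577, CSTF2T = 616,
    CSTF3 = 717, NUDT21 = 227, CPSF6 = 551, CPSF7 = 471, CLP1 = 425,
    PCF11 = 1555)
}

#' Simulate MAF-style somatic mutation records
#'
#' Each sample mutates each CPA gene independently with probability
#' `mutation_rate_per_gene`; the variant class is drawn from
#' `variant_class_probs` and the protein position uniformly over the gene's
#' protein length.
#'
#' @param config A [sim_config()].
#' @return A mutation `data.frame` in the shape returned by [read_maf()].
#' @export
simulate_mutations <- function(config) {
  set.seed(config$seed + 505L)
  samples <- sample_ids(config$n_samples)
  genes <- cpa_genes()
  lens <- cpa_protein_lengths()
  hit <- matrix(stats::runif(length(genes) * length(samples)) <
                  config$mutation_rate_per_gene,
                nrow = length(genes),
                dimnames = list(genes, samples))
  idx <- which(hit, arr.ind = TRUE)
  n_mut <- nrow(idx)
  if (n_mut == 0L) {
    return(data.frame(sample_id = character(), gene = character(),
                      variant_classification = character(),
                      protein_position = integer(),
                      protein_change = character(),
                      stringsAsFactors = FALSE))
  }
  gene <- genes[idx[, 1L]]
  vc <- sample(names(config$variant_class_probs), n_mut, replace = TRUE,
               prob = config$variant_class_probs)
  pos <- vapply(gene, function(g) sample.int(lens[[g]], 1L), integer(1L),
                USE.NAMES = FALSE)
  data.frame(
    sample_id = samples[idx[, 2L]],
    gene = gene,
    variant_classification = vc,
    protein_position = pos,
    protein_change = sprintf("p.X%d*", pos),
    stringsAsFactors = FALSE
  )
}

#' Simulate a complete synthetic cohort
#'
#' Runs every simulator stage in a fixed order, each on its own seed stream
#' derived from `config$seed`, so the full cohort is reproducible
#' element-by-element.
#'
#' @param config A [sim_config()].
#' @return List with `cnv_calls`, `cnv_continuous`, `pdui`, `truth`,
#'   `zscore`, `clinical`, `mutations` and the `config` itself.
#' @export
simulate_cohort <- function(config = sim_config()) {
  cnv <- simulate_cnv(config)
  ap <- simulate_pdui(config, cnv$continuous)
  z <- simulate_expression(config, ap$truth, cnv$continuous)
  clin <- simulate_survival(config, cnv$continuous)
  mut <- simulate_mutations(config)
  list(
    cnv_calls = cnv$calls, cnv_continuous = cnv$continuous,
    pdui = ap$pdui, truth = ap$truth, zscore = z,
    clinical = clin, mutations = mut, config = config
  )
}
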