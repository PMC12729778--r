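test_that("group definition follows the inclusive quantile convention", {
  v <- setNames(1:8, sprintf("S%d", 1:8))
  g <- define_groups(v, apa_config())
  # type-7 quantiles of 1..8: 75th = 6.25, 25th = 2.75
  expect_equal(g$high, c("S7", "S8"))
  expect_equal(g$low, c("S1", "S2"))

  v4 <- setNames(c(10, 20, 30, 40), sprintf("S%d", 1:4))
  g4 <- define_groups(v4, apa_config())
  # 75th = 37.5, 25th = 17.5
  expect_equal(g4$high, "S4")
  expect_equal(g4$low, "S1")

  expect_error(define_groups(setNames(rep(1, 6), sprintf("S%d", 1:6))),
               "degenerate")
  expect_error(define_groups(setNames(1:3, sprintf("S%d", 1:3))),
               "4 samples")
})

test_that("confounder exclusion keeps only diploid samples", {
  cnv <- toy_cnv(c(2, 0, -1, 0), genes = "MYC")
  out <- exclude_confounder(cnv, sprintf("S%d", 1:4), "MYC")
  expect_equal(out, c("S2", "S4"))
  expect_equal(exclude_confounder(cnv, c("S2", "S3"), "MYC"), "S2")
})

test_that("delta PDUI is the difference of group medians", {
  m <- matrix(c(0.2, 0.3, 0.4, 0.6, 0.7, 0.8), nrow = 1,
              dimnames = list("g1", sprintf("S%d", 1:6)))
  pdui <- gene_matrix(m, "pdui")
  cfg <- apa_config(min_group_n = 3)
  out <- delta_pdui(pdui, high = c("S1", "S2", "S3"),
                    low = c("S4", "S5", "S6"), cfg)
  expect_equal(out$delta_pdui, -0.4, tolerance = 1e-12)  # 0.3 - 0.7
  expect_equal(out$n_high, 3L)

  # gene entirely missing in the high group is untested
  m2 <- rbind(m, g2 = c(NA, NA, NA, 0.5, 0.5, 0.5))
  rownames(m2) <- c("g1", "g2")
  out2 <- delta_pdui(gene_matrix(m2, "pdui"), c("S1", "S2", "S3"),
                     c("S4", "S5", "S6"), cfg)
  expect_false(out2$tested[out2$gene == "g2"])
  expect_true(is.na(out2$delta_pdui[out2$gene == "g2"]))

  expect_error(delta_pdui(pdui, c("S1", "S2"), c("S2", "S3"), cfg),
               "overlap")
  expect_error(delta_pdui(pdui, character(), c("S1"), cfg), "non-empty")
})

test_that("per-gene rank-sum p matches enumeration and BH spans tested genes", {
  m <- matrix(c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6), nrow = 1,
              dimnames = list("g1", sprintf("S%d", 1:6)))
  pdui <- gene_matrix(m, "pdui")
  cfg <- apa_config(min_group_n = 3)
  out <- test_apa(pdui, c("S1", "S2", "S3"), c("S4", "S5", "S6"), cfg)
  expect_equal(out$p_raw, 0.1, tolerance = 1e-9)
  expect_equal(out$q_bh, out$p_raw)  # single tested gene
})

test_that("APA classification requires both magnitude and significance", {
  cfg <- apa_config()
  expect_equal(classify_apa(-0.3, 0.01, cfg), "shortened")
  expect_equal(classify_apa(-0.3, 0.2, cfg), "unchanged")
  expect_equal(classify_apa(0.1, 0.001, cfg), "unchanged")
  expect_equal(classify_apa(0.3, 0.01, cfg), "lengthened")
  expect_equal(classify_apa(NA, NA, cfg), "untested")
  expect_equal(classify_apa(0.15, 0.049, cfg), "lengthened")  # inclusive
})

test_that("delta Z-score is the difference of group means", {
  m <- matrix(c(1.5, 1.5, 1.0, 1.0), nrow = 1,
              dimnames = list("g1", sprintf("S%d", 1:4)))
  expr <- gene_matrix(m, "zscore")
  dz <- delta_zscore(expr, c("S1", "S2"), c("S3", "S4"))
  expect_equal(unname(dz), 0.5)
  dz0 <- delta_zscore(expr, c("S1", "S3"), c("S2", "S4"))
  expect_equal(unname(dz0), 0)
  dz_missing <- delta_zscore(expr, c("S1", "S2"), c("S3", "S4"),
                             genes = c("g1", "gX"))
  expect_true(is.na(dz_missing["gX"]))
})

test_that("quadrants follow the sign conventions with strict inequalities", {
  expect_equal(assign_quadrant("lengthened", -1.1), "Q1")
  expect_equal(assign_quadrant("lengthened", 0.4), "Q2")
  expect_equal(assign_quadrant("shortened", -0.5), "Q3")
  expect_equal(assign_quadrant("shortened", 0.8), "Q4")
  expect_equal(assign_quadrant("unchanged", 2.0), "none")
  expect_equal(assign_quadrant("shortened", 0), "none")
  expect_equal(assign_quadrant("shortened", NA), "none")
  expect_equal(assign_quadrant("untested", -1), "none")
})

test_that("swapping high and low groups negates deltas and keeps p-values", {
  set.seed(60)
  cfg_sim <- sim_config(n_samples = 120, n_genes = 40, seed = 61,
                        n_shortened = 5, n_lengthened = 5,
                        pdui_missing_rate = 0.05)
  co <- simulate_cohort(cfg_sim)
  cn <- co$cnv_continuous["CPSF1", ]
  g <- define_groups(cn, apa_config())
  cfg <- apa_config(min_group_n = 5)
  d1 <- delta_pdui(co$pdui, g$high, g$low, cfg)
  d2 <- delta_pdui(co$pdui, g$low, g$high, cfg)
  expect_equal(d1$delta_pdui, -d2$delta_pdui, tolerance = 1e-12)
  p1 <- test_apa(co$pdui, g$high, g$low, cfg)
  p2 <- test_apa(co$pdui, g$low, g$high, cfg)
  expect_equal(p1$p_raw, p2$p_raw, tolerance = 1e-9)
  z1 <- delta_zscore(co$zscore, g$high, g$low)
  z2 <- delta_zscore(co$zscore, g$low, g$high)
  expect_equal(unname(z1), -unname(z2), tolerance = 1e-12)
})

test_that("the pipeline classes partition the gene list", {
  co <- simulate_cohort(sim_config(n_samples = 150, n_genes = 60, seed = 62,
                                   n_shortened = 8, n_lengthened = 8))
  res <- run_apa_pipeline(co$cnv_calls, co$cnv_continuous, co$pdui,
                          co$zscore)
  expect_equal(nrow(res), 60L)
  expect_true(all(res$apa_class %in% c("lengthened", "shortened",
                                       "unchanged", "untested")))
  # no quadrant without a significant APA class
  expect_true(all(res$apa_class[res$quadrant != "none"] %in%
                    c("lengthened", "shortened")))
  # empty PDUI matrix gives an empty result
  empty <- gene_matrix(matrix(numeric(), 0, 0,
                              dimnames = list(character(), character())),
                       "pdui")
  expect_equal(nrow(run_apa_pipeline(co$cnv_calls, co$cnv_continuous,
                                     empty, NULL)), 0L)
})

test_that("the pipeline recovers planted APA effects", {
  co <- simulate_cohort(sim_config(n_samples = 300, n_genes = 200, seed = 63,
                                   n_shortened = 20, n_lengthened = 20))
  res <- run_apa_pipeline(co$cnv_calls, co$cnv_continuous, co$pdui,
                          co$zscore)
  merged <- merge(res, co$truth, by = "gene")
  planted <- merged$planted_class != "unchanged"
  correct <- merged$apa_class == merged$planted_class
  expect_gte(mean(correct[planted]), 0.9)
  called <- merged$apa_class %in% c("shortened", "lengthened")
  fdp <- if (any(called)) mean(merged$planted_class[called] == "unchanged")
         else 0
  expect_lte(fdp, 0.1)
})
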