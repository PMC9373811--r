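test_that("immune panel has exact dimensions and class counts", {
  cfg <- sim_config(seed = 5)   # defaults: 19 types x 5 lines, 2000 lncRNAs
  panel <- generate_immune_panel(cfg)
  expect_equal(dim(panel$expr), c(2000L, 95L))
  counts <- table(panel$ground_truth$lnc_class)
  expect_equal(unname(counts["general_immune"]), floor(0.015 * 2000),
               ignore_attr = TRUE)
  expect_equal(unname(counts["cell_type_specific"]), floor(0.15 * 2000),
               ignore_attr = TRUE)
  expect_equal(unname(counts["tumor_enriched"]), floor(0.05 * 2000),
               ignore_attr = TRUE)
  expect_equal(sum(counts), 2000L)
  expect_equal(nrow(panel$annotation), 95L)
  expect_equal(length(unique(panel$annotation$cell_type)), 19L)
  # planted betas only on general-immune lncRNAs, balanced in sign
  gt <- panel$ground_truth
  expect_true(all(gt$lnc_class[gt$planted_beta != 0] == "general_immune"))
  expect_equal(sum(sign(gt$planted_beta)), 0)
})

test_that("generators are bit-identical under the same seed", {
  cfg <- small_sim_config(seed = 9)
  a <- generate_immune_panel(cfg)
  b <- generate_immune_panel(cfg)
  expect_identical(as.vector(a$expr), as.vector(b$expr))
  expect_identical(a$ground_truth$planted_beta, b$ground_truth$planted_beta)
  expect_identical(as.vector(generate_tumor_lines(cfg, a$ground_truth)),
                   as.vector(generate_tumor_lines(cfg, b$ground_truth)))
  c1 <- generate_bulk_cohort(cfg, a$ground_truth, 1L)
  c2 <- generate_bulk_cohort(cfg, a$ground_truth, 1L)
  expect_identical(as.vector(c1$expr), as.vector(c2$expr))
  expect_identical(c1$time, c2$time)
  expect_identical(c1$event, c2$event)
  # different cohort index gives a different draw
  c3 <- generate_bulk_cohort(cfg, a$ground_truth, 2L)
  expect_false(identical(c1$time, c3$time))
})

test_that("removing the specific class removes high-TSI generated lncRNAs", {
  cfg <- small_sim_config(seed = 21, frac_specific = 0)
  panel <- generate_immune_panel(cfg)
  expect_false(any(panel$ground_truth$lnc_class == "cell_type_specific"))
  tt <- tsi(panel$expr, panel$annotation)
  high <- panel$ground_truth$lnc_class == "general_immune"
  expect_true(mean(tt$table$tsi[high] < 0.2) > 0.9)
})

test_that("tumor lines shift the immune-general class down", {
  cfg <- small_sim_config(seed = 33)
  panel <- generate_immune_panel(cfg)
  tumor <- generate_tumor_lines(cfg, panel$ground_truth)
  gt <- panel$ground_truth
  gen <- gt$lnc_class == "general_immune"
  diff <- rowMeans(panel$expr) - rowMeans(tumor)
  expect_true(all(diff[gen] > 1))         # planted 3-log2 depletion
  tum <- gt$lnc_class == "tumor_enriched"
  expect_true(all(diff[tum] < -1))        # tumor-enriched go the other way
  # mismatched universe is a dimension error
  cfg2 <- small_sim_config(seed = 33, n_lnc = 100L, n_prognostic = 0L)
  expect_error(generate_tumor_lines(cfg2, panel$ground_truth), "universe")
})

test_that("bulk survival follows the planted proportional-hazards model", {
  # no censoring: every event observed
  cfg0 <- small_sim_config(seed = 11, censoring_rate = 0)
  st0 <- generate_bulk_cohort(cfg0, generate_immune_panel(cfg0)$ground_truth, 1L)
  expect_true(all(st0$event == 1))
  expect_true(all(st0$time > 0))
  expect_true(all(st0$infiltration >= 0 & st0$infiltration <= 1))

  # all betas zero: the true linear predictor carries no information
  cfg_null <- small_sim_config(seed = 12, n_prognostic = 0L, n_patients = 500L)
  panel <- generate_immune_panel(cfg_null)
  co <- generate_bulk_cohort(cfg_null, panel$ground_truth, 1L)
  expect_true(all(co$true_lp == 0))
  set.seed(1)
  fake_lp <- stats::rnorm(500)
  c0 <- concordance_index(fake_lp, surv_data(co$time, co$event))
  expect_lt(abs(c0 - 0.5), 0.05)

  # a strongly planted lncRNA is recovered by univariate Cox with its sign
  cfg1 <- small_sim_config(seed = 13, n_prognostic = 2L, beta_magnitude = 1,
                           n_patients = 500L)
  panel1 <- generate_immune_panel(cfg1)
  co1 <- generate_bulk_cohort(cfg1, panel1$ground_truth, 1L)
  gt <- panel1$ground_truth
  pos <- gt$lnc_ids[gt$planted_beta > 0][1L]
  scr <- univariate_cox_screen(co1, pos, alpha = 0.05)
  expect_equal(scr$selected, pos)
  expect_gt(scr$stats$hr, 1)
})

test_that("censoring calibration hits the configured fraction", {
  cfg <- small_sim_config(seed = 44, n_patients = 600L, censoring_rate = 0.4)
  co <- generate_bulk_cohort(cfg, generate_immune_panel(cfg)$ground_truth, 1L)
  expect_lt(abs(mean(1 - co$event) - 0.4), 0.07)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(seed = 1, frac_general = 0.6, frac_specific = 0.5),
               "fractions")
  expect_error(sim_config(seed = 1, n_lnc = 0), "positive")
  expect_error(sim_config(seed = 1, n_prognostic = 10000), "exceeds")
  expect_error(sim_config(), "seed")
})
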