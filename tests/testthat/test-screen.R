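test_that("top-expression marks the ceiling count per line and unions them", {
  set.seed(71)
  m <- make_expr(matrix(stats::rnorm(100 * 4), 100, 4))
  cand <- top_expressed_candidates(m, fraction = 0.15)
  expect_true(all(attr(cand, "per_line_count") == 15L))  # ceiling(0.15 * 100)

  # a lncRNA maximal in every line is always selected
  m2v <- as.vector(m)
  m2 <- make_expr(rbind(matrix(m2v, 100, 4), 99), features = c(paste0("g", 1:100), "top"))
  expect_true("top" %in% top_expressed_candidates(m2, fraction = 0.15))

  # union equals a brute-force per-column sort on a random 50 x 10 matrix
  set.seed(72)
  r <- make_expr(matrix(stats::rnorm(500), 50, 10))
  cand_r <- top_expressed_candidates(r, fraction = 0.15)
  k <- ceiling(0.15 * 50)
  brute <- unique(unlist(lapply(1:10, function(j)
    rownames(r)[order(r[, j], decreasing = TRUE)[1:k]])))
  expect_setequal(cand_r, brute)

  # intersection mode is never larger than the union
  inter <- top_expressed_candidates(r, fraction = 0.15, aggregate = "intersection")
  expect_true(all(inter %in% cand_r))
  expect_error(top_expressed_candidates(r, fraction = 1.2), "fraction")
})

test_that("TSI hits its analytic endpoints and the worked three-type case", {
  ann <- data.frame(sample_id = paste0("t", 1:19), cell_type = paste0("ct", 1:19))
  uniform <- make_expr(matrix(7, 1, 19), scale = "linear_tpm",
                       features = "u", samples = paste0("t", 1:19))
  expect_equal(tsi(uniform, ann)$table$tsi, 0)

  single <- make_expr(matrix(c(5, rep(0, 18)), 1, 19), scale = "linear_tpm",
                      features = "s", samples = paste0("t", 1:19))
  expect_equal(tsi(single, ann)$table$tsi, 1)

  ann3 <- data.frame(sample_id = c("a", "b", "c"), cell_type = c("x", "y", "z"))
  prof <- make_expr(matrix(c(1, 0.5, 0), 1, 3), scale = "linear_tpm",
                    features = "p", samples = c("a", "b", "c"))
  expect_equal(tsi(prof, ann3)$table$tsi, 0.75)
})

test_that("TSI is scale-invariant, bounded, and averages replicates on the linear scale", {
  set.seed(73)
  ann <- data.frame(sample_id = paste0("s", 1:12),
                    cell_type = rep(paste0("ct", 1:4), each = 3))
  vals <- matrix(stats::rexp(10 * 12, 0.2), 10, 12)
  m <- make_expr(vals, scale = "linear_tpm", samples = paste0("s", 1:12))
  tt <- tsi(m, ann)
  expect_true(all(tt$table$tsi >= 0 & tt$table$tsi <= 1))
  expect_true(all(abs(apply(tt$x_profile, 1, max) - 1) < 1e-12))

  scaled <- make_expr(vals * rep(stats::runif(10, 0.5, 20), 12),
                      scale = "linear_tpm", samples = paste0("s", 1:12))
  expect_equal(tsi(scaled, ann)$table$tsi, tt$table$tsi, tolerance = 1e-12)

  # replicate averaging: a log2 matrix is un-logged before averaging
  ann2 <- data.frame(sample_id = c("r1", "r2", "q1", "q2"),
                     cell_type = c("A", "A", "B", "B"))
  lg <- make_expr(matrix(c(3, 5, 0, 0), 1, 4), scale = "log2",
                  features = "g", samples = c("r1", "r2", "q1", "q2"))
  profA <- mean(2^c(3, 5) - 1)
  expected <- (1 - profA / profA + 1 - 0 / profA) / 1
  expect_equal(tsi(lg, ann2)$table$tsi, expected)

  zero <- make_expr(matrix(0, 1, 4), scale = "linear_tpm",
                    features = "z", samples = c("r1", "r2", "q1", "q2"))
  expect_warning(tz <- tsi(zero, ann2), "undefined")
  expect_true(is.na(tz$table$tsi))
})

test_that("the TSI generality threshold is strict", {
  tt <- structure(list(table = data.frame(lnc_id = c("a", "b", "c", "d"),
                                          tsi = c(0, 0.19, 0.2, 0.75)),
                       x_profile = NULL, n_types = 19),
                  class = "tsi_table")
  expect_equal(select_general_ilncs(tt, c("a", "b", "c", "d"), 0.2), c("a", "b"))
  expect_equal(select_general_ilncs(tt, c("a", "b", "c", "d"), 1.0),
               c("a", "b", "c", "d"))
  expect_equal(select_general_ilncs(tt, character(0), 0.2), character(0))
})

test_that("differential filter retains planted shifts and respects the null", {
  # planted +3 log2 shift in immune, 95 vs 10 lines
  set.seed(74)
  imm <- make_expr(rbind(shifted = stats::rnorm(95, 8, 0.5),
                         flat = stats::rnorm(95, 5, 0.5)),
                   samples = paste0("i", 1:95))
  tum <- make_expr(rbind(shifted = stats::rnorm(10, 5, 0.5),
                         flat = stats::rnorm(10, 5, 0.5)),
                   samples = paste0("t", 1:10))
  out <- differential_filter(imm, tum, c("shifted", "flat"))
  expect_true("shifted" %in% out$selected)
  expect_false("flat" %in% out$selected)
  expect_true(all(c("statistic", "p_value", "adj_p", "log2_fc") %in%
                  names(out$stats)))

  # identical group means at scale: retained fraction at most ~alpha
  set.seed(75)
  nn <- 60
  imm0 <- make_expr(matrix(stats::rnorm(nn * 40, 5), nn, 40),
                    features = paste0("n", 1:nn), samples = paste0("i", 1:40))
  tum0 <- make_expr(matrix(stats::rnorm(nn * 40, 5), nn, 40),
                    features = paste0("n", 1:nn), samples = paste0("t", 1:40))
  out0 <- differential_filter(imm0, tum0, paste0("n", 1:nn))
  expect_lte(length(out0$selected) / nn, 0.05)

  tiny <- make_expr(matrix(1, 1, 1), features = "n1", samples = "only")
  expect_error(differential_filter(imm0, tiny, "n1"), "at least 2")
})

test_that("Benjamini-Hochberg matches the step-up definition", {
  set.seed(76)
  p <- stats::runif(20)^2
  expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
})

test_that("univariate Cox screen recovers planted effects and calibrates on null", {
  cfg <- small_sim_config(seed = 77, n_prognostic = 2L, beta_magnitude = 1,
                          n_patients = 400L)
  panel <- generate_immune_panel(cfg)
  co <- generate_bulk_cohort(cfg, panel$ground_truth, 1L)
  gt <- panel$ground_truth
  planted <- gt$lnc_ids[gt$planted_beta != 0]
  scr <- univariate_cox_screen(co, planted)
  expect_setequal(scr$selected, planted)
  signs <- sign(scr$stats$beta[match(planted, scr$stats$lnc_id)])
  expect_equal(signs, sign(gt$planted_beta[gt$planted_beta != 0]))

  # null calibration: background lncRNAs are retained at about alpha
  bg <- gt$lnc_ids[gt$lnc_class == "background"][1:100]
  scr0 <- univariate_cox_screen(co, bg)
  expect_lte(length(scr0$selected) / 100, 0.11)

  expect_equal(univariate_cox_screen(co, character(0))$selected, character(0))
})

test_that("the full screen trace is nested and recovers the planted class", {
  cfg <- small_sim_config(seed = 78, n_patients = 400L)
  st <- simulate_study(cfg)
  tr <- run_screen(st$panel, st$annotation, st$tumor, st$cohorts[[1]])
  sizes_in <- vapply(tr$stages, `[[`, 0, "n_in")
  sizes_out <- vapply(tr$stages, `[[`, 0, "n_out")
  expect_true(all(sizes_out <= sizes_in))
  # each stage's output is a subset of its input stage
  for (i in 2:length(tr$stages))
    expect_true(all(tr$stages[[i]]$selected %in% tr$stages[[i - 1]]$selected))
  gt <- st$ground_truth
  planted <- gt$lnc_ids[gt$planted_beta != 0]
  expect_gte(mean(planted %in% tr$selected), 0.5)

  dir <- withr::local_tempdir()
  write_screen_trace(tr, dir)
  expect_true(file.exists(file.path(dir, "screen_summary.json")))
  expect_length(list.files(dir, pattern = "^stage_.*tsv$"), 4L)
})
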