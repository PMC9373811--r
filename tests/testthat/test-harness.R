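toy_registry <- function() {
  risk_of <- function(model) function(x) stats::predict(model, x)
  list(
    cox = learner_spec("cox", "cox", "predictor", function(data, seed, k) {
      m <- fit_cox(data)
      list(model = m, selected = colnames(data$x), risk = risk_of(m))
    }),
    coxboost = learner_spec("coxboost", "coxboost", c("selector", "predictor"),
      function(data, seed, k) {
        m <- fit_coxboost(data, n_steps = 30)
        list(model = m, selected = m$selected, risk = risk_of(m))
      }))
}

# two small cohorts with a shared planted signal
toy_cohorts <- function(seed, n = 150, p = 6, beta = c(1, -0.8, rep(0, 4))) {
  lapply(1:2, function(i) {
    d <- make_ph_data(n, beta, seed = seed + i)
    expr <- expr_matrix(t(d$x) + 5, scale = "log2",
                        feature_ids = paste0("lnc", seq_len(p)),
                        sample_ids = paste0("c", i, "_s", seq_len(n)))
    surv_cohort(expr, d$time, d$event, name = paste0("cohort", i))
  })
}

test_that("combination enumeration follows the singles + cross-family rule", {
  reg <- toy_registry()
  combos <- enumerate_combinations(reg)
  # 2 predictors + 1 selector: 2 singles + 1 cross-family composition
  expect_setequal(combos$combo_id, c("cox", "coxboost", "coxboost>cox"))
  expect_equal(nrow(combos), 3L)

  # 2 predictors + 1 pure selector of a third family: 2 singles + 2 compositions
  reg3 <- c(reg["cox"],
            list(ridge = learner_spec("ridge", "pencox_l2", "predictor",
                                      reg$cox$fit),
                 lasso = learner_spec("lasso", "pencox_l1", "selector",
                                      reg$cox$fit)))
  expect_equal(nrow(enumerate_combinations(reg3)), 4L)

  one <- enumerate_combinations(reg["cox"])
  expect_equal(one$combo_id, "cox")
  expect_error(enumerate_combinations(list()), "empty")

  # deterministic lexicographic order
  expect_identical(combos$combo_id, sort(combos$combo_id))
  # full default registry: singles + 4 selectors x cross-family predictors
  full <- enumerate_combinations(default_registry())
  expect_identical(full, enumerate_combinations(default_registry()))
  expect_gt(nrow(full), 50)
})

test_that("same-family compositions are excluded", {
  reg <- toy_registry()
  combos <- enumerate_combinations(reg)
  comp <- combos[!is.na(combos$selector), ]
  expect_false(any(mapply(function(s, p)
    reg[[s]]$family == reg[[p]]$family, comp$selector, comp$predictor)))
})

test_that("run_combo is deterministic and evaluates validation concordance", {
  cohorts <- toy_cohorts(81)
  reg <- toy_registry()
  combos <- enumerate_combinations(reg)
  row <- combos[combos$combo_id == "coxboost>cox", ]
  r1 <- run_combo(row, cohorts[[1]], cohorts[2], reg, k = 5, seed = 82)
  r2 <- run_combo(row, cohorts[[1]], cohorts[2], reg, k = 5, seed = 82)
  expect_identical(r1$val_cindex, r2$val_cindex)
  expect_false(r1$failed)
  expect_gt(r1$mean_val_cindex, 0.6)   # planted signal transfers
  expect_true(all(r1$features %in% rownames(cohorts[[1]]$expr)))
})

test_that("a pure-noise combination scores near chance on validation", {
  cohorts <- toy_cohorts(83, beta = rep(0, 6))
  reg <- toy_registry()
  row <- enumerate_combinations(reg)[1, ]   # single cox predictor
  r <- run_combo(row, cohorts[[1]], cohorts[2], reg, k = 5, seed = 84)
  expect_lt(abs(r$mean_val_cindex - 0.5), 0.07)
})

test_that("select_best ranks by mean C, then parsimony, then id, order-free", {
  mk <- function(id, c, nf) structure(list(combo_id = id, failed = FALSE,
                                           mean_val_cindex = c, n_features = nf),
                                      class = "combo_result")
  a <- mk("alpha", 0.80, 30)
  b <- mk("beta", 0.75, 5)
  expect_equal(select_best(list(a, b)), "alpha")
  tie1 <- mk("big", 0.8, 30); tie2 <- mk("small", 0.8, 16)
  expect_equal(select_best(list(tie1, tie2)), "small")
  expect_equal(select_best(list(tie2, tie1)), "small")
  idtie <- mk("aaa", 0.8, 16)
  expect_equal(select_best(list(tie2, idtie)), "aaa")
  expect_equal(select_best(list(a)), "alpha")
  failed <- structure(list(combo_id = "x", failed = TRUE), class = "combo_result")
  expect_error(select_best(list(failed)), "failed")
})

test_that("signature scoring reproduces training scores and flags absentees", {
  cohorts <- toy_cohorts(85)
  reg <- toy_registry()
  sig <- build_signature(cohorts[[1]], "coxboost", "cox", reg, k = 5, seed = 86)
  sc <- score_cohort(sig, cohorts[[1]])
  sc2 <- score_cohort(sig, cohorts[[1]])
  expect_identical(sc, sc2)

  # duplicated sample scores identically
  dup <- cohorts[[2]]
  expect_equal(unname(score_cohort(sig, dup)[1]),
               unname(score_cohort(sig, dup)[1]))

  # a feature-wise constant shift leaves ranks intact under re-standardization
  shifted <- cohorts[[2]]
  shifted$expr <- expr_matrix(as.matrix(shifted$expr) +
                                stats::rnorm(nrow(shifted$expr)),
                              scale = "log2")
  base_rank <- rank(score_cohort(sig, cohorts[[2]], restandardize = TRUE))
  shift_rank <- rank(score_cohort(sig, shifted, restandardize = TRUE))
  expect_equal(base_rank, shift_rank, ignore_attr = TRUE)

  missing <- cohorts[[2]]
  missing$expr <- missing$expr[-match(sig$features[1], rownames(missing$expr)), ]
  expect_error(score_cohort(sig, missing), "lacks feature")
})

test_that("signature JSON round-trips with identical scores", {
  cohorts <- toy_cohorts(87)
  reg <- default_registry(rsf_trees = 40L)
  for (combo in list(c("coxboost", "cox"), c(NA, "rsf"))) {
    sig <- build_signature(cohorts[[1]], combo[1], combo[2], reg,
                           k = 5, seed = 88)
    path <- withr::local_tempfile(fileext = ".json")
    save_signature(sig, path)
    back <- load_signature(path)
    expect_equal(score_cohort(back, cohorts[[2]]),
                 score_cohort(sig, cohorts[[2]]), tolerance = 1e-12)
    expect_identical(back$features, sig$features)
    expect_equal(back$cutpoint, sig$cutpoint, tolerance = 1e-12)
  }
})

test_that("optimal cutpoint maximizes the log-rank statistic exhaustively", {
  # well-separated planted risk groups: the cutpoint falls between them
  set.seed(89)
  n <- 60
  grp <- rep(c(0, 1), each = n / 2)
  time <- stats::rexp(n, 0.05 * exp(2 * grp))
  d <- surv_data(time, rep(1, n))
  scores <- grp * 3 + stats::rnorm(n, sd = 0.3)
  cut <- optimal_cutpoint(scores, d)
  expect_gt(cut$cutpoint, max(scores[grp == 0 & scores < 1.5]) - 1)
  expect_lt(cut$cutpoint, 3)

  # n = 10: argmax matches exhaustive enumeration honoring minprop
  set.seed(90)
  s10 <- stats::rnorm(10)
  d10 <- surv_data(stats::rexp(10) + 0.1, stats::rbinom(10, 1, 0.8))
  sc <- logrank_scores(d10)
  xs <- sort(unique(s10))
  cuts <- (xs[-1] + xs[-length(xs)]) / 2
  min_side <- 1L   # minprop 0.1 of 10
  vals <- vapply(cuts, function(cc) {
    n1 <- sum(s10 <= cc)
    if (n1 < min_side || 10 - n1 < min_side) return(NA_real_)
    logrank_score_split(s10, sc, cc)
  }, 0)
  best <- optimal_cutpoint(s10, d10, minprop = 0.1)
  expect_equal(best$cutpoint, cuts[which.max(abs(vals))], tolerance = 1e-12)

  expect_error(optimal_cutpoint(rep(1, 10), d10), "all scores equal")
})

test_that("stratification tests separate planted risk groups and swap on negation", {
  set.seed(91)
  n <- 120
  scores <- stats::rnorm(n)
  time <- stats::rexp(n, 0.05 * exp(scores))
  d <- surv_data(time, rep(1, n))
  cut <- optimal_cutpoint(scores, d)
  st <- stratify_and_test(scores, cut$cutpoint, d)
  expect_lt(st$test$p_value, 0.05)
  km_high <- st$km$high; km_low <- st$km$low
  t_mid <- stats::median(time)
  expect_lt(km_surv_at(km_high, t_mid), km_surv_at(km_low, t_mid))

  neg <- stratify_and_test(-scores, -cut$cutpoint - 1e-12, d)
  expect_equal(unname(table(st$groups)["high"]), unname(table(neg$groups)["low"]))
  expect_error(stratify_and_test(scores, max(scores) + 1, d), "strictly inside")
})

test_that("response association detects shifted responders and matches rank sums", {
  set.seed(92)
  resp <- rep(c("NR", "R"), each = 25)
  scores <- stats::rnorm(50) + 2 * (resp == "R")
  out <- response_association(scores, resp)
  expect_lt(out$p_value, 0.01)
  expect_equal(dim(out$contingency), c(2L, 2L))

  # rank-sum statistic equals the exhaustive rank computation on n = 12
  set.seed(93)
  s12 <- stats::rnorm(12)
  r12 <- rep(c("a", "b"), 6)
  out12 <- response_association(s12, r12)
  ranks <- rank(s12)
  w_oracle <- sum(ranks[r12 == "a"]) - sum(r12 == "a") * (sum(r12 == "a") + 1) / 2
  expect_equal(out12$statistic, w_oracle)
  expect_error(response_association(s12, rep("a", 12)), "2 response labels")
})
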