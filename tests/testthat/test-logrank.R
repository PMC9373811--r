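test_that("log-rank scores match the hand-computed three-subject case", {
  s <- logrank_scores(surv_data(c(1, 2, 3), c(1, 1, 1)))
  expect_equal(s$a, c(2 / 3, 1 / 6, -5 / 6), tolerance = 1e-12)
  expect_equal(sum(s$a), 0, tolerance = 1e-10)
})

test_that("all-censored data gives zero scores", {
  s <- logrank_scores(surv_data(c(3, 1, 2, 5), c(0, 0, 0, 0)))
  expect_equal(s$a, rep(0, 4))
})

test_that("scores agree with a direct-summation oracle on random censored data", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 10
    time <- round(stats::rexp(n, 0.2), 2) + 0.01
    event <- stats::rbinom(n, 1, 0.7)
    if (sum(event) == 0) event[1] <- 1
    s <- logrank_scores(surv_data(time, event))
    expect_equal(s$a, logrank_scores_oracle(time, event), tolerance = 1e-12)
  }
  # uncensored scores always sum to zero
  set.seed(99)
  time <- stats::rexp(25)
  s <- logrank_scores(surv_data(time, rep(1, 25)))
  expect_equal(sum(s$a), 0, tolerance = 1e-10)
})

test_that("split statistic matches the direct formula and exhaustive argmax", {
  set.seed(7)
  n <- 8
  time <- stats::rexp(n) + 0.1
  event <- c(1, 1, 0, 1, 1, 1, 0, 1)
  x <- stats::rnorm(n)
  d <- surv_data(time, event)
  sc <- logrank_scores(d)
  # direct formula at one cutpoint
  c0 <- stats::median(x)
  L <- x <= c0
  n1 <- sum(L)
  expected <- (sum(sc$a[L]) - n1 * mean(sc$a)) /
    sqrt(n1 * (1 - n1 / n) * stats::var(sc$a))
  expect_equal(logrank_score_split(x, sc, c0), expected, tolerance = 1e-12)

  # exhaustive enumeration over all midpoints
  xs <- sort(unique(x))
  cuts <- (xs[-1] + xs[-length(xs)]) / 2
  vals <- vapply(cuts, function(cc) logrank_score_split(x, sc, cc), 0)
  best <- best_logrank_split(x, sc)
  expect_equal(best$cutpoint, cuts[which.max(abs(vals))], tolerance = 1e-12)
  expect_equal(abs(best$statistic), max(abs(vals)), tolerance = 1e-12)
})

test_that("split statistic flips sign when sides are relabeled", {
  set.seed(8)
  x <- stats::rnorm(10)
  d <- surv_data(stats::rexp(10) + 0.1, rep(1, 10))
  sc <- logrank_scores(d)
  c0 <- stats::median(x)
  s1 <- logrank_score_split(x, sc, c0)
  # x -> -x maps {x <= c} onto {x' >= -c}; use a cut just below -c0
  s2 <- logrank_score_split(-x, sc, -c0 - 1e-9)
  n1 <- sum(x <= c0)
  skip_if(n1 != sum(-x <= -c0 - 1e-9) && n1 + sum(-x <= -c0 - 1e-9) != 10)
  expect_equal(s1 + s2, 0, tolerance = 1e-9)
})

test_that("constant scores make a split undefined", {
  sc <- logrank_scores(surv_data(c(1, 2, 3, 4), c(0, 0, 0, 0)))
  expect_true(is.na(logrank_score_split(c(1, 2, 3, 4), sc, 2.5)))
  expect_null(best_logrank_split(c(1, 2, 3, 4), sc))
})

test_that("Kaplan-Meier estimate matches the survival package", {
  skip_if_not_installed("survival")
  set.seed(9)
  n <- 60
  time <- round(stats::rexp(n, 0.3), 1) + 0.1
  event <- stats::rbinom(n, 1, 0.6)
  d <- surv_data(time, event)
  km <- km_estimate(d)
  ref <- survival::survfit(survival::Surv(time, event) ~ 1)
  expect_equal(km_surv_at(km, ref$time), ref$surv, tolerance = 1e-12)
  # no events: survival stays at 1
  km0 <- km_estimate(surv_data(c(1, 2, 3), c(0, 0, 0)))
  expect_true(all(km0$surv == 1))
})

test_that("log-rank test matches a hand oracle and survdiff", {
  skip_if_not_installed("survival")
  # identical groups by construction: statistic is zero
  d <- surv_data(rep(c(1, 2, 3, 4), 2), rep(c(1, 1, 0, 1), 2))
  same <- logrank_test(d, rep(c("a", "b"), each = 4))
  expect_equal(same$chisq, 0, tolerance = 1e-10)

  set.seed(10)
  n <- 8
  time <- c(1, 2, 3, 4, 5, 6, 7, 8)
  event <- c(1, 1, 1, 0, 1, 1, 0, 1)
  g <- c(1, 2, 1, 2, 1, 2, 1, 2)
  lt <- logrank_test(surv_data(time, event), g)
  ref <- survival::survdiff(survival::Surv(time, event) ~ g)
  expect_equal(lt$chisq, ref$chisq, tolerance = 1e-8)
  expect_equal(unname(lt$observed), unname(ref$obs), tolerance = 1e-10)
  expect_equal(unname(lt$expected), unname(ref$exp), tolerance = 1e-10)

  # larger random case with censoring
  set.seed(11)
  time2 <- stats::rexp(40) + 0.05
  event2 <- stats::rbinom(40, 1, 0.7)
  g2 <- rep(1:2, 20)
  lt2 <- logrank_test(surv_data(time2, event2), g2)
  ref2 <- survival::survdiff(survival::Surv(time2, event2) ~ g2)
  expect_equal(lt2$chisq, ref2$chisq, tolerance = 1e-8)
  expect_error(logrank_test(surv_data(1:3, c(1, 1, 1)), c(1, 1, 1)), "2 groups")
})
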