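# fixture builders shared across test files; everything is generated in code

# simple exponential proportional-hazards data with known coefficients
make_ph_data <- function(n, beta, seed, censor_rate = 0.3, h0 = 0.1) {
  set.seed(seed)
  p <- length(beta)
  x <- matrix(stats::rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("v", seq_len(p))))
  lp <- drop(x %*% beta)
  t_event <- stats::rexp(n, rate = h0 * exp(lp))
  t_cens <- if (censor_rate > 0) {
    r <- censoring_rate_solve_oracle(h0 * exp(lp), censor_rate)
    stats::rexp(n, rate = r)
  } else rep(Inf, n)
  surv_data(pmin(t_event, t_cens), as.numeric(t_event <= t_cens), x)
}

# independent closed-form censoring-rate solver (oracle for the generator's)
censoring_rate_solve_oracle <- function(hz, target) {
  f <- function(r) mean(r / (r + hz)) - target
  stats::uniroot(f, c(1e-10, 1e6), tol = 1e-12)$root
}

# small expression matrix with named features/samples
make_expr <- function(values, scale = "log2", features = NULL, samples = NULL) {
  values <- as.matrix(values)
  if (is.null(features))
    features <- if (!is.null(rownames(values))) rownames(values)
                else paste0("g", seq_len(nrow(values)))
  if (is.null(samples))
    samples <- if (!is.null(colnames(values))) colnames(values)
               else paste0("s", seq_len(ncol(values)))
  dimnames(values) <- list(features, samples)
  expr_matrix(values, scale = scale)
}

# brute-force Harrell C over all ordered pairs
cindex_oracle <- function(risk, time, event) {
  num <- den <- 0
  n <- length(time)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (time[i] < time[j] && event[i] == 1) {
      den <- den + 1
      if (risk[i] > risk[j]) num <- num + 1
      else if (risk[i] == risk[j]) num <- num + 0.5
    }
  }
  num / den
}

# direct-summation log-rank (Savage) scores oracle
logrank_scores_oracle <- function(time, event) {
  n <- length(time)
  ord <- order(time, seq_len(n))
  ts <- time[ord]; ds <- event[ord]
  gamma <- vapply(seq_len(n), function(k) sum(ts <= ts[k]), 0L)
  a_s <- vapply(seq_len(n), function(j) {
    tot <- 0
    for (k in seq_len(gamma[j])) tot <- tot + ds[k] / (n - gamma[k] + 1)
    ds[j] - tot
  }, 0)
  a <- numeric(n)
  a[ord] <- a_s
  a
}

# Benjamini-Hochberg step-up from the definition
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, p[ord[i]] * m / i)
    adj[ord[i]] <- prev
  }
  adj
}

# default synthetic study at reduced size for fast tests
small_sim_config <- function(seed, ...) {
  args <- list(n_lnc = 400L, n_patients = 150L, n_cohorts = 2L,
               n_prognostic = 4L, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}
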