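#' Simulation configuration
#'
#' Parameters of the synthetic study: a panel of purified immune cell lines
#' (19 cell types with replicate lines, mirroring the scale of published
#' purified-immune-cell compendia), a small set of tumor cell lines, and bulk
#' tumor cohorts whose expression is an infiltration-weighted mixture of the
#' immune and tumor prototypes and whose survival follows a proportional
#' hazards model with planted coefficients.
#'
#' Expression is log2-normal: each lncRNA has per-cell-type mean levels
#' (class base + type-level spread) and replicate lines add noise of SD
#' \code{sd_rep}. The general-immune class uses a tight type-level spread
#' (\code{sd_type_general}) because uniform expression across cell types is
#' what defines the class; all other classes use \code{sd_type_other}.
#' Planted prognostic effects live on the first \code{n_prognostic}
#' general-immune lncRNAs with alternating signs of size \code{beta_magnitude};
#' keeping \code{n_prognostic} even makes the signed coefficients sum to zero,
#' so the cohort-wide infiltration component cancels out of the true risk and
#' non-prognostic immune lncRNAs stay null in univariate screens.
#'
#' @param n_cell_types number of immune cell types (default 19).
#' @param lines_per_type replicate purified lines per type (default 5).
#' @param n_lnc number of lncRNAs (default 2000).
#' @param n_tumor_lines number of tumor cell lines (default 10).
#' @param n_patients bulk samples per cohort (default 250).
#' @param n_cohorts number of bulk cohorts (default 3).
#' @param frac_general,frac_specific,frac_tumor class fractions; counts are
#'   \code{floor(frac * n_lnc)} exactly, the remainder is background.
#' @param n_prognostic number of planted prognostic general-immune lncRNAs.
#' @param beta_magnitude absolute planted log-hazard per SD of expression.
#' @param mean_high,mean_low log2 class base levels (high ~ expressed, low ~
#'   near floor).
#' @param sd_rep replicate-line noise SD (log2).
#' @param sd_type_general,sd_type_other type-level spread SD (log2).
#' @param tumor_shift log2 down-shift of general-immune lncRNAs (and up-shift
#'   of tumor-enriched lncRNAs) in tumor lines.
#' @param bulk_noise_sd residual noise SD in bulk samples (log2).
#' @param batch_sd per-cohort per-lncRNA additive batch shift SD (log2).
#' @param baseline_hazard exponential baseline hazard (per month).
#' @param censoring_rate target fraction of censored subjects in bulk cohorts.
#' @param infiltration_shape1,infiltration_shape2 Beta parameters of the
#'   per-sample immune fraction.
#' @param seed mandatory integer seed; every generator derives its stream
#'   from it.
#' @return a validated list of class \code{sim_config}.
#' @export
sim_config <- function(n_cell_types = 19L, lines_per_type = 5L, n_lnc = 2000L,
                       n_tumor_lines = 10L, n_patients = 400L, n_cohorts = 3L,
                       frac_general = 0.015, frac_specific = 0.15,
                       frac_tumor = 0.05, n_prognostic = 12L,
                       beta_magnitude = 0.55, mean_high = 8, mean_low = 3,
                       sd_rep = 0.2, sd_type_general = 0.03,
                       sd_type_other = 0.5, tumor_shift = 3,
                       bulk_noise_sd = 1.5, batch_sd = 0.3,
                       baseline_hazard = 0.02, censoring_rate = 0.3,
                       infiltration_shape1 = 2, infiltration_shape2 = 2,
                       seed) {
  if (missing(seed) || is.null(seed)) stop("'seed' is mandatory")
  cfg <- list(n_cell_types = as.integer(n_cell_types),
              lines_per_type = as.integer(lines_per_type),
              n_lnc = as.integer(n_lnc), n_tumor_lines = as.integer(n_tumor_lines),
              n_patients = as.integer(n_patients), n_cohorts = as.integer(n_cohorts),
              frac_general = frac_general, frac_specific = frac_specific,
              frac_tumor = frac_tumor, n_prognostic = as.integer(n_prognostic),
              beta_magnitude = beta_magnitude, mean_high = mean_high,
              mean_low = mean_low, sd_rep = sd_rep,
              sd_type_general = sd_type_general, sd_type_other = sd_type_other,
              tumor_shift = tumor_shift, bulk_noise_sd = bulk_noise_sd,
              batch_sd = batch_sd, baseline_hazard = baseline_hazard,
              censoring_rate = censoring_rate,
              infiltration_shape1 = infiltration_shape1,
              infiltration_shape2 = infiltration_shape2,
              seed = as.integer(seed))
  counts <- c(cfg$n_cell_types, cfg$lines_per_type, cfg$n_lnc, cfg$n_tumor_lines,
              cfg$n_patients, cfg$n_cohorts)
  if (any(counts <= 0)) stop("all counts must be positive")
  fr <- c(cfg$frac_general, cfg$frac_specific, cfg$frac_tumor)
  if (any(fr < 0) || sum(fr) > 1)
    stop("class fractions must be nonnegative and sum to at most 1")
  if (cfg$censoring_rate < 0 || cfg$censoring_rate >= 1)
    stop("'censoring_rate' must be in [0, 1)")
  n_general <- floor(cfg$frac_general * cfg$n_lnc)
  if (cfg$n_prognostic > n_general)
    stop("n_prognostic (", cfg$n_prognostic, ") exceeds the general-immune class size (",
         n_general, ")")
  class(cfg) <- "sim_config"
  cfg
}

class_counts <- function(config) {
  n_general <- floor(config$frac_general * config$n_lnc)
  n_specific <- floor(config$frac_specific * config$n_lnc)
  n_tumor <- floor(config$frac_tumor * config$n_lnc)
  c(general_immune = n_general, cell_type_specific = n_specific,
    tumor_enriched = n_tumor,
    background = config$n_lnc - n_general - n_specific - n_tumor)
}

#' Generate the purified immune cell line panel
#'
#' Draws the log2 expression matrix of \code{n_lnc} lncRNAs across
#' \code{n_cell_types * lines_per_type} purified lines, together with the
#' cell-type annotation and the planted ground truth (class labels, specific
#' type assignments, planted Cox coefficients, and the immune/tumor prototype
#' means reused by the other generators).
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with elements \code{expr} (log2 \code{\link{expr_matrix}}),
#'   \code{annotation} (data frame sample_id, cell_type), and
#'   \code{ground_truth}.
#' @export
generate_immune_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cc <- class_counts(config)
  lnc_class <- rep(names(cc), cc)
  ids <- sprintf("lnc%04d", seq_len(config$n_lnc))
  N <- config$n_cell_types

  specific_type <- rep(NA_integer_, config$n_lnc)
  spec_idx <- which(lnc_class == "cell_type_specific")
  if (length(spec_idx))
    specific_type[spec_idx] <- ((seq_along(spec_idx) - 1L) %% N) + 1L

  # per-type mean level of each lncRNA (log2)
  base <- matrix(config$mean_low, config$n_lnc, N)
  base[lnc_class == "general_immune", ] <- config$mean_high
  for (i in spec_idx) base[i, specific_type[i]] <- config$mean_high
  sd_type <- ifelse(lnc_class == "general_immune",
                    config$sd_type_general, config$sd_type_other)
  type_means <- base + matrix(stats::rnorm(config$n_lnc * N), config$n_lnc, N) * sd_type

  L <- config$lines_per_type
  vals <- type_means[, rep(seq_len(N), each = L)] +
    matrix(stats::rnorm(config$n_lnc * N * L, sd = config$sd_rep), config$n_lnc, N * L)
  cell_type <- sprintf("type%02d", rep(seq_len(N), each = L))
  samples <- sprintf("%s_line%d", cell_type, rep(seq_len(L), times = N))
  dimnames(vals) <- list(ids, samples)

  planted_beta <- numeric(config$n_lnc)
  gen_idx <- which(lnc_class == "general_immune")
  if (config$n_prognostic > 0) {
    prog <- gen_idx[seq_len(config$n_prognostic)]
    planted_beta[prog] <- config$beta_magnitude *
      ifelse(seq_len(config$n_prognostic) %% 2L == 1L, 1, -1)
  }

  # tumor-line prototype means: immune-general depleted, tumor-enriched elevated
  mu_tumor <- rep(config$mean_low, config$n_lnc)
  mu_tumor[lnc_class == "general_immune"] <- config$mean_high - config$tumor_shift
  mu_tumor[lnc_class == "tumor_enriched"] <- config$mean_low + config$tumor_shift

  gt <- list(lnc_ids = ids, lnc_class = lnc_class, specific_type = specific_type,
             planted_beta = planted_beta,
             mu_immune = rowMeans(type_means), mu_tumor = mu_tumor,
             config = config)
  class(gt) <- "tiiclnc_ground_truth"
  list(expr = expr_matrix(vals, scale = "log2"),
       annotation = data.frame(sample_id = samples, cell_type = cell_type,
                               stringsAsFactors = FALSE),
       ground_truth = gt)
}

#' Generate tumor cell lines
#'
#' Tumor lines share the lncRNA universe of the immune panel; general-immune
#' lncRNAs are down-shifted by \code{tumor_shift} log2 units and
#' tumor-enriched lncRNAs up-shifted, with replicate noise \code{sd_rep}.
#'
#' @param config a \code{\link{sim_config}}.
#' @param ground_truth output of \code{\link{generate_immune_panel}}.
#' @return a log2 \code{\link{expr_matrix}} with \code{n_tumor_lines} columns.
#' @export
generate_tumor_lines <- function(config, ground_truth) {
  stopifnot(inherits(config, "sim_config"))
  if (!inherits(ground_truth, "tiiclnc_ground_truth") ||
      length(ground_truth$mu_tumor) != config$n_lnc)
    stop("ground truth does not match this configuration's lncRNA universe")
  set.seed(config$seed + 1L)
  n <- config$n_tumor_lines
  vals <- matrix(ground_truth$mu_tumor, config$n_lnc, n) +
    matrix(stats::rnorm(config$n_lnc * n, sd = config$sd_rep), config$n_lnc, n)
  dimnames(vals) <- list(ground_truth$lnc_ids,
                         sprintf("tumor_line%02d", seq_len(n)))
  expr_matrix(vals, scale = "log2")
}

# exponential censoring rate hitting the target censoring fraction:
# with T_i ~ Exp(h_i) and C ~ Exp(r), P(C < T_i) = r / (r + h_i)
censoring_rate_solve <- function(hazards, target) {
  if (target <= 0) return(0)
  f <- function(lr) mean(exp(lr) / (exp(lr) + hazards)) - target
  exp(stats::uniroot(f, c(log(min(hazards)) - 20, log(max(hazards)) + 20),
                     tol = 1e-12)$root)
}

#' Generate a bulk tumor cohort with survival outcomes
#'
#' Bulk expression is an infiltration-weighted mixture of the immune and tumor
#' prototype means, \code{f * mu_immune + (1 - f) * mu_tumor}, plus a
#' per-cohort per-lncRNA batch shift and residual noise. Event times are drawn
#' from an exponential proportional-hazards model
#' \code{h = h0 * exp(sum(planted_beta * z))} on the within-cohort
#' standardized expression \code{z} of the planted lncRNAs; censoring times
#' are independent exponentials with rate solved to hit the configured
#' censoring fraction.
#'
#' @param config a \code{\link{sim_config}}.
#' @param ground_truth output of \code{\link{generate_immune_panel}}.
#' @param cohort_index 1-based cohort number (controls the RNG substream and
#'   batch shift).
#' @return a \code{\link{surv_cohort}} with extra elements
#'   \code{infiltration} (per-sample immune fraction) and \code{true_lp}
#'   (the planted linear predictor).
#' @export
generate_bulk_cohort <- function(config, ground_truth, cohort_index = 1L) {
  stopifnot(inherits(config, "sim_config"))
  if (!inherits(ground_truth, "tiiclnc_ground_truth") ||
      length(ground_truth$mu_immune) != config$n_lnc)
    stop("ground truth does not match this configuration's lncRNA universe")
  set.seed(config$seed + 1000L + as.integer(cohort_index))
  n <- config$n_patients
  f <- stats::rbeta(n, config$infiltration_shape1, config$infiltration_shape2)
  proto <- outer(ground_truth$mu_immune, f) +
    outer(ground_truth$mu_tumor, 1 - f)
  batch <- stats::rnorm(config$n_lnc, sd = config$batch_sd)
  vals <- proto + batch +
    matrix(stats::rnorm(config$n_lnc * n, sd = config$bulk_noise_sd),
           config$n_lnc, n)
  samples <- sprintf("cohort%d_pt%04d", cohort_index, seq_len(n))
  dimnames(vals) <- list(ground_truth$lnc_ids, samples)

  beta <- ground_truth$planted_beta
  idx <- which(beta != 0)
  lp <- if (length(idx)) {
    z <- t(scale(t(vals[idx, , drop = FALSE])))
    drop(crossprod(z, beta[idx]))
  } else rep(0, n)
  hz <- config$baseline_hazard * exp(lp)
  t_event <- stats::rexp(n, rate = hz)
  if (config$censoring_rate > 0) {
    r_cens <- censoring_rate_solve(hz, config$censoring_rate)
    t_cens <- stats::rexp(n, rate = r_cens)
  } else t_cens <- rep(Inf, n)
  time <- pmin(t_event, t_cens)
  event <- as.numeric(t_event <= t_cens)

  out <- surv_cohort(expr_matrix(vals, scale = "log2"), time, event,
                     name = sprintf("cohort%d", cohort_index))
  out$infiltration <- f
  out$true_lp <- lp
  out
}

#' Simulate the full synthetic study
#'
#' Convenience wrapper: immune panel, tumor lines, and \code{n_cohorts} bulk
#' cohorts from one configuration.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{panel}, \code{tumor}, \code{cohorts} (list of
#'   \code{\link{surv_cohort}}), and \code{ground_truth}.
#' @export
simulate_study <- function(config) {
  panel <- generate_immune_panel(config)
  tumor <- generate_tumor_lines(config, panel$ground_truth)
  cohorts <- lapply(seq_len(config$n_cohorts), function(i)
    generate_bulk_cohort(config, panel$ground_truth, i))
  names(cohorts) <- vapply(cohorts, `[[`, "", "name")
  list(panel = panel$expr, annotation = panel$annotation, tumor = tumor,
       cohorts = cohorts, ground_truth = panel$ground_truth)
}

#' Write ground truth as a TSV sidecar
#' @param ground_truth output of \code{\link{generate_immune_panel}}.
#' @param path output file.
#' @export
write_ground_truth_tsv <- function(ground_truth, path) {
  df <- data.frame(lnc_id = ground_truth$lnc_ids,
                   lnc_class = ground_truth$lnc_class,
                   specific_type = ground_truth$specific_type,
                   planted_beta = ground_truth$planted_beta,
                   mu_immune = ground_truth$mu_immune,
                   mu_tumor = ground_truth$mu_tumor)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
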