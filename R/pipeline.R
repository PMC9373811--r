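# End-to-end orchestration driven by a YAML configuration: simulate (or
# ingest) -> screen -> benchmark -> fit/score/evaluate. Every stage writes
# plain TSV/JSON into a stage subdirectory of output_dir and records the
# configuration hash for provenance.

#' Read and validate a pipeline configuration
#'
#' The YAML schema has a mandatory integer \code{seed}, an \code{output_dir},
#' and exactly one of \code{simulation} (arguments of
#' \code{\link{sim_config}}) or \code{inputs} (paths to immune/annotation/
#' tumor/cohort files). Optional blocks \code{screen}, \code{harness} and
#' \code{evaluate} override stage defaults.
#'
#' @param path YAML file.
#' @return validated config list of class \code{pipeline_config} (with
#'   \code{config_hash}).
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) stop("config must set 'seed'")
  if (is.null(cfg$output_dir)) stop("config must set 'output_dir'")
  has_sim <- !is.null(cfg$simulation)
  has_inp <- !is.null(cfg$inputs)
  if (has_sim == has_inp)
    stop("config must have exactly one of 'simulation' or 'inputs'")
  cfg$config_hash <- unname(tools::md5sum(path))
  class(cfg) <- "pipeline_config"
  cfg
}

stage_dir <- function(config, stage, force = FALSE) {
  d <- file.path(config$output_dir, stage)
  if (dir.exists(d) && length(list.files(d)) && !force)
    stop("output directory ", d, " is nonempty; use force = TRUE to overwrite")
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  d
}

manifest_write <- function(dir, config) {
  files <- setdiff(list.files(dir), "manifest.json")
  jsonlite::write_json(
    list(config_hash = config$config_hash,
         files = lapply(files, function(f)
           list(file = f, md5 = unname(tools::md5sum(file.path(dir, f)))))),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
}

#' Pipeline stage: simulate
#'
#' Runs the synthetic-data generator and writes the immune panel, annotation,
#' tumor lines, bulk cohorts, ground truth and a checksum manifest.
#'
#' @param config a \code{\link{read_pipeline_config}} result.
#' @param force overwrite a nonempty stage directory.
#' @return the stage directory, invisibly.
#' @export
pipeline_simulate <- function(config, force = FALSE) {
  if (is.null(config$simulation)) stop("config has no 'simulation' block")
  d <- stage_dir(config, "data", force)
  sim_args <- config$simulation
  sim_args$seed <- config$seed
  sc <- do.call(sim_config, sim_args)
  study <- simulate_study(sc)
  write_expr_tsv(study$panel, file.path(d, "immune_panel.tsv"))
  utils::write.table(study$annotation, file.path(d, "annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_expr_tsv(study$tumor, file.path(d, "tumor_lines.tsv"))
  for (co in study$cohorts)
    write_cohort_tsv(co, file.path(d, paste0(co$name, "_expr.tsv")),
                     file.path(d, paste0(co$name, "_clinical.tsv")))
  write_ground_truth_tsv(study$ground_truth, file.path(d, "ground_truth.tsv"))
  manifest_write(d, config)
  invisible(d)
}

# load immune/annotation/tumor/cohorts either from config$inputs or from the
# simulate stage directory
pipeline_load_data <- function(config) {
  if (!is.null(config$inputs)) {
    inp <- config$inputs
    cohorts <- lapply(inp$cohorts, function(co)
      read_cohort_tsv(co$expr, co$clinical,
                      name = if (is.null(co$name)) basename(co$expr) else co$name))
    names(cohorts) <- vapply(cohorts, `[[`, "", "name")
    list(immune = read_expr_tsv(inp$immune),
         annotation = utils::read.delim(inp$annotation, sep = "\t"),
         tumor = read_expr_tsv(inp$tumor), cohorts = cohorts)
  } else {
    d <- file.path(config$output_dir, "data")
    if (!dir.exists(d)) stop("no simulated data found; run pipeline_simulate first")
    clin <- list.files(d, pattern = "_clinical\\.tsv$")
    names_ <- sub("_clinical\\.tsv$", "", clin)
    cohorts <- lapply(names_, function(nm)
      read_cohort_tsv(file.path(d, paste0(nm, "_expr.tsv")),
                      file.path(d, paste0(nm, "_clinical.tsv")), name = nm))
    names(cohorts) <- names_
    list(immune = read_expr_tsv(file.path(d, "immune_panel.tsv")),
         annotation = utils::read.delim(file.path(d, "annotation.tsv"), sep = "\t"),
         tumor = read_expr_tsv(file.path(d, "tumor_lines.tsv")),
         cohorts = cohorts)
  }
}

#' Pipeline stage: screen
#'
#' Runs the four-stage screen on the first cohort (training) and writes the
#' stage trace TSVs and JSON summary.
#'
#' @inheritParams pipeline_simulate
#' @return the \code{\link{run_screen}} trace, invisibly.
#' @export
pipeline_screen <- function(config, force = FALSE) {
  data <- pipeline_load_data(config)
  p <- config$screen
  trace <- run_screen(data$immune, data$annotation, data$tumor,
                      data$cohorts[[1L]],
                      fraction = p$fraction %||% 0.15,
                      tsi_threshold = p$tsi_threshold %||% 0.2,
                      diff_alpha = p$diff_alpha %||% 0.05,
                      cox_alpha = p$cox_alpha %||% 0.05,
                      aggregate = p$aggregate %||% "union")
  d <- stage_dir(config, "screen", force)
  write_screen_trace(trace, d)
  manifest_write(d, config)
  invisible(trace)
}

pipeline_registry <- function(config) {
  h <- config$harness
  default_registry(
    enet_alphas = h$enet_alphas %||% seq(0.1, 0.9, by = 0.1),
    rsf_trees = h$rsf_trees %||% 300L,
    rsf_nodesize = h$rsf_nodesize %||% 15L,
    coxboost_steps = h$coxboost_steps %||% 100L,
    stepwise_directions = h$stepwise_directions %||% c("forward", "backward", "both"))
}

pipeline_screened_cohorts <- function(config) {
  d <- file.path(config$output_dir, "screen")
  sj <- file.path(d, "screen_summary.json")
  if (!file.exists(sj)) stop("no screen results; run pipeline_screen first")
  selected <- unlist(jsonlite::read_json(sj, simplifyVector = TRUE)$selected)
  if (length(selected) == 0L) stop("the screen selected no lncRNAs")
  data <- pipeline_load_data(config)
  cohorts <- lapply(data$cohorts, function(co) {
    co$expr <- co$expr[selected, , drop = FALSE]
    co
  })
  cohorts
}

#' Pipeline stage: benchmark
#'
#' Enumerates the configured combinations on the screened features (first
#' cohort trains, the rest validate) and writes the leaderboard.
#'
#' @inheritParams pipeline_simulate
#' @return the \code{\link{benchmark_combos}} result, invisibly.
#' @export
pipeline_benchmark <- function(config, force = FALSE) {
  cohorts <- pipeline_screened_cohorts(config)
  if (length(cohorts) < 2) stop("need at least 2 cohorts (train + validation)")
  registry <- pipeline_registry(config)
  combos <- enumerate_combinations(registry)
  if (!is.null(config$harness$combos))
    combos <- combos[combos$combo_id %in% unlist(config$harness$combos), ,
                     drop = FALSE]
  bm <- benchmark_combos(cohorts[[1L]], cohorts[-1L], registry,
                         combos = combos, k = config$harness$k %||% 10L,
                         seed = config$seed,
                         standardize = config$harness$standardize %||% "per_cohort")
  d <- stage_dir(config, "benchmark", force)
  utils::write.table(bm$leaderboard, file.path(d, "leaderboard.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(best = bm$best, config_hash = config$config_hash),
                       file.path(d, "best_combo.json"), auto_unbox = TRUE)
  manifest_write(d, config)
  invisible(bm)
}

#' Pipeline stage: fit, score and evaluate
#'
#' Builds the final signature from the chosen (or benchmark-winning)
#' combination, scores every cohort, stratifies and tests survival, computes
#' time-dependent AUC and calibration on each cohort, and serializes the
#' model.
#'
#' @inheritParams pipeline_simulate
#' @param combo_id optional "selector>predictor" (or plain predictor) id;
#'   default: the benchmark winner.
#' @return list with the signature and per-cohort evaluation tables,
#'   invisibly.
#' @export
pipeline_fit <- function(config, combo_id = NULL, force = FALSE) {
  cohorts <- pipeline_screened_cohorts(config)
  registry <- pipeline_registry(config)
  if (is.null(combo_id)) {
    bj <- file.path(config$output_dir, "benchmark", "best_combo.json")
    if (!file.exists(bj)) stop("no benchmark winner; run pipeline_benchmark or give combo_id")
    combo_id <- jsonlite::read_json(bj)$best
  }
  parts <- strsplit(combo_id, ">", fixed = TRUE)[[1L]]
  selector <- if (length(parts) == 2L) parts[1L] else NA_character_
  predictor <- parts[length(parts)]

  sig <- build_signature(cohorts[[1L]], selector, predictor, registry,
                         k = config$harness$k %||% 10L, seed = config$seed)
  d <- stage_dir(config, "signature", force)
  save_signature(sig, file.path(d, "signature.json"))

  ev <- config$evaluate
  eval_times <- unlist(ev$eval_times %||% c(12, 24, 36, 48, 60))
  restand <- isTRUE(ev$restandardize)
  evaluations <- lapply(cohorts, function(co) {
    scores <- score_cohort(sig, co, restandardize = restand)
    sd_ <- surv_data(co$time, co$event)
    utils::write.table(
      data.frame(sample_id = names(scores), score = unname(scores)),
      file.path(d, paste0(co$name, "_scores.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
    strat <- tryCatch(stratify_and_test(scores, sig$cutpoint, sd_),
                      error = function(e) NULL)
    auc <- time_dependent_auc(scores, sd_, eval_times)
    utils::write.table(auc, file.path(d, paste0(co$name, "_auc.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(strat)) {
      km_tab <- do.call(rbind, lapply(names(strat$km), function(g)
        cbind(group = g, as.data.frame(strat$km[[g]]))))
      utils::write.table(km_tab, file.path(d, paste0(co$name, "_km.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    horizon <- ev$horizon %||% stats::median(eval_times)
    cal <- tryCatch({
      ps <- predict_signature_survival(sig, co, horizon,
                                       restandardize = restand)
      calibration_curve(ps, sd_, horizon,
                        n_groups = ev$calibration_groups %||% 5L)
    }, error = function(e) NULL)
    if (!is.null(cal))
      utils::write.table(cal, file.path(d, paste0(co$name, "_calibration.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(co$clinical) && "response" %in% names(co$clinical)) {
      ra <- response_association(scores, co$clinical$response,
                                 cutpoint = sig$cutpoint)
      utils::write.table(
        data.frame(statistic = ra$statistic, p_value = ra$p_value),
        file.path(d, paste0(co$name, "_response.tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    list(cohort = co$name, scores = scores,
         cindex = concordance_index(scores, sd_),
         logrank_p = if (is.null(strat)) NA_real_ else strat$test$p_value,
         auc = auc)
  })
  summary <- data.frame(
    cohort = vapply(evaluations, `[[`, "", "cohort"),
    cindex = vapply(evaluations, `[[`, 0, "cindex"),
    logrank_p = vapply(evaluations, `[[`, 0, "logrank_p"))
  utils::write.table(summary, file.path(d, "evaluation_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest_write(d, config)
  invisible(list(signature = sig, evaluations = evaluations,
                 summary = summary))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
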