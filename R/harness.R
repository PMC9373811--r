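# Learner registry and the selector -> predictor combination harness.
#
# A learner registry entry wraps one survival algorithm: its fit function
# (which handles its own hyperparameter tuning by k-fold CV on the training
# data), which roles it can hold (selector and/or predictor), and its family
# (compositions must cross families). The harness enumerates single
# predictors plus selector-predictor compositions, benchmarks each by mean
# validation C-index, and builds the final signature from the winner.

#' Define a learner registry entry
#'
#' @param id unique identifier (variants get distinct ids, e.g.
#'   \code{enet_a0.5}).
#' @param family algorithm family (compositions must cross families).
#' @param roles subset of \code{c("selector", "predictor")}.
#' @param fit function \code{(data, seed, k)} returning a list with
#'   \code{model}, \code{selected} (character vector of covariates with
#'   signal; for pure predictors, all covariates), and \code{risk}
#'   (function mapping a covariate matrix to risk scores).
#' @return a \code{learner_spec}.
#' @export
learner_spec <- function(id, family, roles, fit) {
  if (!length(roles) || !all(roles %in% c("selector", "predictor")))
    stop("roles must be a nonempty subset of selector/predictor")
  structure(list(id = id, family = family, roles = roles, fit = fit),
            class = "learner_spec")
}

#' The default learner registry
#'
#' Registers the from-scratch learners: Cox, lasso, ridge, elastic net over
#' an alpha grid, stepwise Cox in three directions, CoxBoost, and the random
#' survival forest. Selector roles are held by the feature-selecting
#' algorithms (lasso, stepwise Cox, CoxBoost, RSF). Further algorithms
#' (e.g. partial least squares Cox, supervised principal components,
#' gradient boosting, survival SVM) can be added as additional
#' \code{\link{learner_spec}} entries; the harness is generic over any
#' registry.
#'
#' @param enet_alphas alpha grid for elastic-net variants.
#' @param rsf_trees trees per forest inside the harness.
#' @param rsf_nodesize RSF terminal node size.
#' @param coxboost_steps maximum boosting steps explored by CV.
#' @param stepwise_directions directions to register.
#' @return named list of \code{learner_spec} objects.
#' @export
default_registry <- function(enet_alphas = seq(0.1, 0.9, by = 0.1),
                             rsf_trees = 300L, rsf_nodesize = 15L,
                             coxboost_steps = 100L,
                             stepwise_directions = c("forward", "backward", "both")) {
  reg <- list()
  add <- function(spec) reg[[spec$id]] <<- spec

  risk_of <- function(model) function(x) stats::predict(model, x)

  add(learner_spec("cox", "cox", "predictor", function(data, seed, k) {
    model <- fit_cox(data)
    list(model = model, selected = colnames(data$x), risk = risk_of(model))
  }))
  add(learner_spec("lasso", "pencox_l1", c("selector", "predictor"),
    function(data, seed, k) {
      cv <- cv_penalized_cox(data, alpha = 1, k = k, seed = seed)
      list(model = cv$fit, selected = cv$fit$selected, risk = risk_of(cv$fit))
    }))
  add(learner_spec("ridge", "pencox_l2", "predictor", function(data, seed, k) {
    cv <- cv_penalized_cox(data, alpha = 0, k = k, seed = seed)
    list(model = cv$fit, selected = colnames(data$x), risk = risk_of(cv$fit))
  }))
  for (a in enet_alphas) {
    local({
      alpha <- a
      add(learner_spec(sprintf("enet_a%.1f", alpha), "enet", "predictor",
        function(data, seed, k) {
          cv <- cv_penalized_cox(data, alpha = alpha, k = k, seed = seed)
          list(model = cv$fit, selected = colnames(data$x), risk = risk_of(cv$fit))
        }))
    })
  }
  for (d in stepwise_directions) {
    local({
      dir <- d
      add(learner_spec(paste0("stepwise_", dir), "stepwise",
                       c("selector", "predictor"),
        function(data, seed, k) {
          sw <- stepwise_cox(data, direction = dir)
          risk <- if (is.null(sw$fit)) function(x) rep(0, nrow(x))
                  else risk_of(sw$fit)
          list(model = sw, selected = sw$selected, risk = risk)
        }))
    })
  }
  add(learner_spec("coxboost", "coxboost", c("selector", "predictor"),
    function(data, seed, k) {
      cv <- cv_coxboost(data, max_steps = coxboost_steps, k = k, seed = seed)
      model <- fit_coxboost(data, n_steps = max(cv$best_steps, 1L))
      list(model = model, selected = model$selected, risk = risk_of(model))
    }))
  add(learner_spec("rsf", "rsf", c("selector", "predictor"),
    function(data, seed, k) {
      model <- fit_rsf(data, n_trees = rsf_trees, nodesize = rsf_nodesize,
                       seed = seed)
      vimp <- rsf_vimp(model, data)
      sel <- names(vimp)[vimp > 0]
      list(model = model, selected = sel, risk = risk_of(model))
    }))
  reg
}

#' Enumerate learner combinations
#'
#' All single predictors (one per registered variant) plus every
#' (selector, predictor) composition in which the selector holds the
#' selector role and the predictor belongs to a different family. The list
#' order is deterministic (lexicographic by combo identifier).
#'
#' @param registry a named list of \code{\link{learner_spec}} objects.
#' @return data frame with columns \code{combo_id}, \code{selector}
#'   (NA for singles), \code{predictor}.
#' @export
enumerate_combinations <- function(registry) {
  if (!length(registry)) stop("empty registry")
  preds <- Filter(function(s) "predictor" %in% s$roles, registry)
  if (!length(preds)) stop("registry contains no predictor")
  sels <- Filter(function(s) "selector" %in% s$roles, registry)
  rows <- lapply(preds, function(p)
    data.frame(combo_id = p$id, selector = NA_character_, predictor = p$id))
  for (s in sels) for (p in preds) {
    if (p$family == s$family) next
    rows[[length(rows) + 1L]] <-
      data.frame(combo_id = paste0(s$id, ">", p$id),
                 selector = s$id, predictor = p$id)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$combo_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# covariate design for a cohort restricted to 'features'; standardization
# either per cohort (default; absorbs feature-wise batch shifts) or by
# training parameters
harness_design <- function(cohort, features, mode, train_params = NULL) {
  if (mode == "training" && !is.null(train_params))
    cohort_design(cohort, features, center = train_params$center,
                  scale = train_params$scale)
  else cohort_design(cohort, features)
}

#' Run one learner combination
#'
#' Fits the combination on the training cohort (selector, if any, on the full
#' training data; the predictor tuned by k-fold CV and refit on the selected
#' subset) and evaluates the C-index on the training cohort and each
#' validation cohort.
#'
#' @param combo one row of \code{\link{enumerate_combinations}} (or a list
#'   with \code{selector}/\code{predictor}).
#' @param train training \code{\link{surv_cohort}}.
#' @param validations list of validation \code{\link{surv_cohort}}s.
#' @param registry learner registry.
#' @param k folds for hyperparameter tuning.
#' @param seed mandatory integer seed.
#' @param standardize \code{"per_cohort"} (each cohort z-scored on its own
#'   parameters; robust to additive batch shifts) or \code{"training"}
#'   (training parameters applied everywhere).
#' @return a \code{combo_result}: combo id, per-cohort C-index, mean
#'   validation C-index, selected-feature count; \code{failed = TRUE} with a
#'   reason when the selector returns no features or a fit degenerates.
#' @export
run_combo <- function(combo, train, validations, registry, k = 10L, seed,
                      standardize = c("per_cohort", "training")) {
  standardize <- match.arg(standardize)
  if (missing(seed)) stop("'seed' is mandatory")
  combo_id <- if (is.na(combo$selector)) combo$predictor
              else paste0(combo$selector, ">", combo$predictor)
  features <- rownames(train$expr)
  fail <- function(reason)
    structure(list(combo_id = combo_id, failed = TRUE, reason = reason,
                   seed = seed), class = "combo_result")
  tr_design <- harness_design(train, features, "per_cohort")
  tr_data <- surv_data(train$time, train$event, tr_design$x)
  if (sum(tr_data$event) < k) return(fail("fewer events than folds"))

  sel_features <- features
  if (!is.na(combo$selector)) {
    sel_spec <- registry[[combo$selector]]
    sel_fit <- tryCatch(sel_spec$fit(tr_data, seed = seed, k = k),
                        error = function(e) NULL)
    if (is.null(sel_fit)) return(fail("selector error"))
    sel_features <- sel_fit$selected
    if (length(sel_features) == 0L) return(fail("selector returned 0 features"))
  }
  pred_spec <- registry[[combo$predictor]]
  sub_data <- surv_data(tr_data$time, tr_data$event,
                        tr_data$x[, sel_features, drop = FALSE])
  pred_fit <- tryCatch(pred_spec$fit(sub_data, seed = seed, k = k),
                       error = function(e) NULL)
  if (is.null(pred_fit)) return(fail("predictor error"))

  eval_c <- function(cohort) {
    des <- harness_design(cohort, sel_features, standardize,
                          train_params = list(center = tr_design$center[sel_features],
                                              scale = tr_design$scale[sel_features]))
    risk <- pred_fit$risk(des$x)
    concordance_index(risk, surv_data(cohort$time, cohort$event))
  }
  train_c <- eval_c(train)
  val_c <- vapply(validations, eval_c, 0)
  names(val_c) <- vapply(validations, `[[`, "", "name")
  structure(list(combo_id = combo_id, selector = combo$selector,
                 predictor = combo$predictor, failed = FALSE,
                 train_cindex = train_c, val_cindex = val_c,
                 mean_val_cindex = mean(val_c),
                 n_features = length(sel_features),
                 features = sel_features, seed = seed,
                 standardize = standardize),
            class = "combo_result")
}

#' Benchmark every combination and rank by mean validation C-index
#'
#' @inheritParams run_combo
#' @param combos optional subset of \code{\link{enumerate_combinations}}.
#' @return list: \code{results} (all \code{combo_result}s),
#'   \code{leaderboard} (data frame, ranked), \code{best} (combo id).
#' @export
benchmark_combos <- function(train, validations, registry, combos = NULL,
                             k = 10L, seed, standardize = "per_cohort") {
  if (is.null(combos)) combos <- enumerate_combinations(registry)
  results <- lapply(seq_len(nrow(combos)), function(i)
    run_combo(combos[i, ], train, validations, registry, k = k, seed = seed,
              standardize = standardize))
  names(results) <- combos$combo_id
  best <- select_best(results)
  ok <- !vapply(results, `[[`, TRUE, "failed")
  lb <- do.call(rbind, lapply(results[ok], function(r)
    data.frame(combo_id = r$combo_id, mean_val_cindex = r$mean_val_cindex,
               train_cindex = r$train_cindex, n_features = r$n_features,
               t(r$val_cindex), check.names = FALSE)))
  if (!is.null(lb)) {
    lb <- lb[order(-lb$mean_val_cindex, lb$n_features, lb$combo_id), ]
    rownames(lb) <- NULL
  }
  list(results = results, leaderboard = lb, best = best)
}

#' Select the best combination
#'
#' Argmax of mean validation C-index over non-failed results; ties broken by
#' fewer selected features, then lexicographic combo id. Invariant to the
#' order results are supplied.
#'
#' @param results list of \code{combo_result}s.
#' @return the winning combo id.
#' @export
select_best <- function(results) {
  ok <- Filter(function(r) !isTRUE(r$failed), results)
  if (!length(ok)) stop("all combinations failed")
  key <- data.frame(id = vapply(ok, `[[`, "", "combo_id"),
                    c = vapply(ok, `[[`, 0, "mean_val_cindex"),
                    nf = vapply(ok, function(r) as.numeric(r$n_features), 0))
  key <- key[order(-key$c, key$nf, key$id), ]
  key$id[1L]
}
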