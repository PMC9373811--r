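# The final signature: selected lncRNAs + fitted predictor + training
# standardization + stratification cutpoint, with JSON serialization.

#' Build the final prognostic signature
#'
#' Runs the selector (if any) on the full training cohort, refits the
#' predictor on the selected lncRNAs, and fixes the risk-stratification
#' cutpoint by the maximally selected log-rank statistic on the training
#' scores.
#'
#' @param train training \code{\link{surv_cohort}} (features already
#'   screened).
#' @param selector selector id in \code{registry}, or \code{NA}/\code{NULL}
#'   for a predictor-only signature.
#' @param predictor predictor id in \code{registry}.
#' @param registry learner registry (see \code{\link{default_registry}}).
#' @param k folds for hyperparameter tuning.
#' @param seed mandatory integer seed.
#' @param minprop minimum group fraction for the cutpoint search.
#' @return object of class \code{tiiclnc_signature}: \code{features},
#'   \code{model}, \code{center}/\code{scale} (training standardization),
#'   \code{cutpoint}, and provenance (\code{selector}, \code{predictor},
#'   \code{seed}).
#' @export
build_signature <- function(train, selector, predictor, registry, k = 10L,
                            seed, minprop = 0.1) {
  if (missing(seed)) stop("'seed' is mandatory")
  if (is.null(selector)) selector <- NA_character_
  combo <- list(selector = selector, predictor = predictor)
  features <- rownames(train$expr)
  des <- cohort_design(train, features)
  tr_data <- surv_data(train$time, train$event, des$x)

  sel_features <- features
  if (!is.na(selector)) {
    sel_fit <- registry[[selector]]$fit(tr_data, seed = seed, k = k)
    sel_features <- sel_fit$selected
    if (length(sel_features) == 0L) stop("selector returned 0 features")
  }
  sub <- surv_data(tr_data$time, tr_data$event,
                   tr_data$x[, sel_features, drop = FALSE])
  pred_fit <- registry[[predictor]]$fit(sub, seed = seed, k = k)
  scores <- pred_fit$risk(sub$x)
  cut <- optimal_cutpoint(scores, surv_data(train$time, train$event),
                          minprop = minprop)
  structure(list(features = sel_features, model = pred_fit$model,
                 center = des$center[sel_features],
                 scale = des$scale[sel_features],
                 cutpoint = cut$cutpoint, cut_statistic = cut$statistic,
                 selector = selector, predictor = predictor,
                 seed = seed, train_name = train$name),
            class = "tiiclnc_signature")
}

#' @export
print.tiiclnc_signature <- function(x, ...) {
  cat(sprintf("TIIClnc signature: %d lncRNA(s), %s%s predictor, cutpoint %.4g\n",
              length(x$features),
              if (is.na(x$selector)) "" else paste0(x$selector, " selector + "),
              x$predictor, x$cutpoint))
  invisible(x)
}

#' Score a cohort with a fitted signature
#'
#' Standardizes the cohort's expression of the signature lncRNAs (by default
#' with the training parameters) and feeds it to the fitted predictor.
#'
#' @param signature a \code{\link{build_signature}} result.
#' @param cohort a \code{\link{surv_cohort}} whose features cover the
#'   signature.
#' @param restandardize if \code{TRUE}, z-score the cohort on its own
#'   parameters instead of the training ones (absorbs feature-wise additive
#'   batch shifts between platforms).
#' @return numeric risk score per sample.
#' @export
score_cohort <- function(signature, cohort, restandardize = FALSE) {
  stopifnot(inherits(signature, "tiiclnc_signature"))
  des <- if (restandardize) cohort_design(cohort, signature$features)
         else cohort_design(cohort, signature$features,
                            center = signature$center, scale = signature$scale)
  risk <- stats::predict(signature$model, des$x)
  stats::setNames(risk, colnames(cohort$expr))
}

#' Optimal survival cutpoint by maximally selected log-rank statistic
#'
#' Over all candidate cutpoints (midpoints between consecutive distinct
#' scores leaving at least \code{minprop} of the samples on each side),
#' computes the standardized two-group log-rank score statistic and returns
#' the cutpoint maximizing its absolute value; exact ties resolve to the
#' lower cutpoint.
#'
#' @param scores numeric risk scores.
#' @param survival a \code{\link{surv_data}} for the same subjects.
#' @param minprop minimum fraction of samples per group.
#' @return list: \code{cutpoint}, \code{statistic} (signed S at the
#'   cutpoint).
#' @export
optimal_cutpoint <- function(scores, survival, minprop = 0.1) {
  stopifnot(inherits(survival, "surv_data"))
  n <- length(scores)
  if (n != length(survival$time)) stop("one score per subject required")
  if (length(unique(scores)) == 1L) stop("all scores equal: no cutpoint exists")
  min_side <- max(1L, ceiling(minprop * n))
  sc <- logrank_scores(survival)
  sp <- best_logrank_split(scores, sc, min_side = min_side)
  if (is.null(sp))
    stop("no candidate cutpoint leaves ", min_side, " samples on each side")
  list(cutpoint = sp$cutpoint, statistic = sp$statistic)
}

#' Stratify by a cutpoint and test group survival
#'
#' High group = score > cutpoint. Returns per-group Kaplan-Meier curves and
#' the two-sided log-rank test.
#'
#' @param scores numeric risk scores.
#' @param cutpoint stratification threshold, strictly inside the score range.
#' @param survival a \code{\link{surv_data}}.
#' @return list: \code{groups} (factor low/high), \code{km} (list of
#'   \code{km_fit} per group), \code{test} (\code{\link{logrank_test}}
#'   result).
#' @export
stratify_and_test <- function(scores, cutpoint, survival) {
  stopifnot(inherits(survival, "surv_data"))
  if (cutpoint <= min(scores) || cutpoint >= max(scores))
    stop("cutpoint must lie strictly inside the score range")
  groups <- factor(ifelse(scores > cutpoint, "high", "low"),
                   levels = c("low", "high"))
  if (any(table(groups) == 0)) stop("empty stratum")
  km <- lapply(split(seq_along(scores), groups), function(i)
    km_estimate(subset_surv(survival, i)))
  list(groups = groups, km = km, test = logrank_test(survival, groups))
}

#' Association between signature scores and treatment response
#'
#' Two-sided Wilcoxon rank-sum test of scores by binary response label, plus
#' the responder-rate contingency table across score groups at a cutpoint.
#'
#' @param scores numeric risk scores.
#' @param response binary response labels (factor or 0/1; both levels must
#'   be present).
#' @param cutpoint score threshold for the contingency table; default the
#'   median score.
#' @return list: \code{statistic} (rank-sum W), \code{p_value},
#'   \code{contingency} (2x2 table of score group x response).
#' @export
response_association <- function(scores, response,
                                 cutpoint = stats::median(scores)) {
  response <- as.factor(response)
  if (nlevels(response) != 2) stop("need exactly 2 response labels, both present")
  if (any(table(response) == 0)) stop("a response label is absent")
  wt <- stats::wilcox.test(scores ~ response, exact = FALSE)
  grp <- factor(ifelse(scores > cutpoint, "high", "low"),
                levels = c("low", "high"))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       contingency = table(score_group = grp, response = response))
}

#' Predicted survival probability at a horizon from a fitted signature
#'
#' For a random-survival-forest predictor, the forest-averaged cumulative
#' hazard gives \code{exp(-H(t|x))}. For coefficient-based predictors the
#' risk score is a log relative hazard, and the baseline cumulative hazard is
#' estimated by the Breslow estimator anchored on the cohort being evaluated:
#' \code{S_i(t) = exp(-H0(t) exp(lp_i))}.
#'
#' @param signature a \code{\link{build_signature}} result.
#' @param cohort a \code{\link{surv_cohort}}.
#' @param t horizon (single time).
#' @param restandardize as in \code{\link{score_cohort}}.
#' @return predicted survival probability per sample.
#' @export
predict_signature_survival <- function(signature, cohort, t,
                                       restandardize = FALSE) {
  stopifnot(inherits(signature, "tiiclnc_signature"))
  des <- if (restandardize) cohort_design(cohort, signature$features)
         else cohort_design(cohort, signature$features,
                            center = signature$center, scale = signature$scale)
  if (inherits(signature$model, "tiiclnc_rsf"))
    return(rsf_survival_at(signature$model, des$x, t))
  lp <- stats::predict(signature$model, des$x)
  ev_times <- sort(unique(cohort$time[cohort$event == 1]))
  ev_times <- ev_times[ev_times <= t]
  h0 <- sum(vapply(ev_times, function(s) {
    sum(cohort$time == s & cohort$event == 1) /
      sum(exp(lp[cohort$time >= s]))
  }, 0))
  exp(-h0 * exp(lp))
}

# ---- serialization ---------------------------------------------------------

model_to_list <- function(model) {
  if (inherits(model, "tiiclnc_cox"))
    list(type = "cox", beta = as.list(model$beta), covariates = model$covariates)
  else if (inherits(model, "tiiclnc_pencox"))
    list(type = "pencox", beta = as.list(model$beta), alpha = model$alpha,
         lambda = model$lambda, covariates = model$covariates)
  else if (inherits(model, "tiiclnc_coxboost"))
    list(type = "coxboost", beta = as.list(model$beta),
         penalty = model$penalty, n_steps = model$n_steps,
         covariates = model$covariates)
  else if (inherits(model, "tiiclnc_stepwise"))
    list(type = "stepwise", direction = model$direction,
         selected = model$selected,
         beta = if (is.null(model$fit)) list() else as.list(model$fit$beta),
         covariates = if (is.null(model$fit)) character(0) else model$fit$covariates)
  else if (inherits(model, "tiiclnc_rsf"))
    list(type = "rsf", n_trees = model$n_trees, mtry = model$mtry,
         nodesize = model$nodesize, seed = model$seed,
         covariates = model$covariates, grid = model$grid,
         trees = lapply(model$trees, function(tr) list(
           root = tr$root,
           nodes = lapply(tr$nodes, function(nd) list(
             var = nd$var, cut = nd$cut, left = nd$left, right = nd$right,
             chf = nd$chf)))))
  else stop("cannot serialize model of class ", class(model)[1L])
}

model_from_list <- function(lst) {
  beta <- unlist(lst$beta)
  switch(lst$type,
    cox = structure(list(beta = beta, covariates = lst$covariates,
                         hr = exp(beta)), class = "tiiclnc_cox"),
    pencox = structure(list(beta = beta, alpha = lst$alpha,
                            lambda = lst$lambda,
                            covariates = lst$covariates,
                            selected = names(beta)[beta != 0]),
                       class = "tiiclnc_pencox"),
    coxboost = structure(list(beta = beta, penalty = lst$penalty,
                              n_steps = lst$n_steps,
                              covariates = lst$covariates,
                              selected = names(beta)[beta != 0]),
                         class = "tiiclnc_coxboost"),
    stepwise = structure(list(direction = lst$direction,
                              selected = unlist(lst$selected),
                              fit = if (length(lst$beta))
                                structure(list(beta = beta,
                                               covariates = lst$covariates),
                                          class = "tiiclnc_cox") else NULL),
                         class = "tiiclnc_stepwise"),
    rsf = structure(list(n_trees = lst$n_trees, mtry = lst$mtry,
                         nodesize = lst$nodesize, seed = lst$seed,
                         covariates = unlist(lst$covariates),
                         grid = unlist(lst$grid),
                         trees = lapply(lst$trees, function(tr) list(
                           root = tr$root,
                           nodes = lapply(tr$nodes, function(nd) list(
                             var = if (is.null(nd$var)) NA_integer_ else nd$var,
                             cut = if (is.null(nd$cut)) NA_real_ else nd$cut,
                             left = nd$left, right = nd$right,
                             chf = unlist(nd$chf)))))),
                    class = "tiiclnc_rsf"),
    stop("unknown model type ", lst$type))
}

#' Save and load a fitted signature as JSON
#'
#' Full-precision JSON serialization; a save/load round trip reproduces
#' scores exactly.
#'
#' @param signature a \code{\link{build_signature}} result.
#' @param path JSON file path.
#' @export
save_signature <- function(signature, path) {
  stopifnot(inherits(signature, "tiiclnc_signature"))
  lst <- list(features = signature$features,
              model = model_to_list(signature$model),
              center = as.list(signature$center),
              scale = as.list(signature$scale),
              cutpoint = signature$cutpoint,
              cut_statistic = signature$cut_statistic,
              selector = signature$selector, predictor = signature$predictor,
              seed = signature$seed, train_name = signature$train_name)
  jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname save_signature
#' @export
load_signature <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  structure(list(features = unlist(lst$features),
                 model = model_from_list(lst$model),
                 center = unlist(lst$center), scale = unlist(lst$scale),
                 cutpoint = lst$cutpoint, cut_statistic = lst$cut_statistic,
                 selector = if (is.null(lst$selector)) NA_character_ else lst$selector,
                 predictor = lst$predictor, seed = lst$seed,
                 train_name = lst$train_name),
            class = "tiiclnc_signature")
}
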