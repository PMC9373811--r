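# Random survival forest with log-rank score splitting.
#
# Trees are grown on bootstrap samples; at every node mtry variables are
# drawn and the (variable, cutpoint) pair maximizing |S(x, c)| -- the
# standardized log-rank score statistic computed on the node's own subjects
# -- is taken, with candidate cutpoints at midpoints between consecutive
# distinct values and both children required to hold >= nodesize subjects.
# Terminal nodes carry the Nelson-Aalen cumulative hazard of their members
# on the grid of training event times; the ensemble risk score is mortality,
# the sum over that grid of the forest-averaged cumulative hazard.

node_chf <- function(time, event, grid) {
  ev <- sort(unique(time[event == 1]))
  if (length(ev) == 0L) return(numeric(length(grid)))
  d <- vapply(ev, function(s) sum(time == s & event == 1), 0)
  y <- vapply(ev, function(s) sum(time >= s), 0)
  H <- cumsum(d / y)
  c(0, H)[findInterval(grid, ev) + 1L]
}

grow_tree <- function(time, event, x, idx, mtry, nodesize, grid) {
  nodes <- list()
  new_node <- function(node) {
    nodes[[length(nodes) + 1L]] <<- node
    length(nodes)
  }
  build <- function(idx) {
    n <- length(idx)
    make_terminal <- function()
      new_node(list(var = NA_integer_, cut = NA_real_, left = NA_integer_,
                    right = NA_integer_,
                    chf = node_chf(time[idx], event[idx], grid)))
    if (n < 2L * nodesize || sum(event[idx]) == 0L) return(make_terminal())
    sc <- logrank_scores(surv_data(time[idx], event[idx]))
    if (!is.finite(sc$s2) || sc$s2 <= 0) return(make_terminal())
    vars <- sample.int(ncol(x), mtry)
    best <- NULL
    for (v in vars) {
      sp <- best_logrank_split(x[idx, v], sc, min_side = nodesize)
      if (!is.null(sp) && is.finite(sp$statistic) &&
          (is.null(best) || abs(sp$statistic) > abs(best$statistic)))
        best <- list(var = v, cut = sp$cutpoint, statistic = sp$statistic)
    }
    if (is.null(best)) return(make_terminal())
    left_idx <- idx[x[idx, best$var] <= best$cut]
    right_idx <- idx[x[idx, best$var] > best$cut]
    me <- new_node(list(var = best$var, cut = best$cut,
                        left = NA_integer_, right = NA_integer_, chf = NULL))
    l <- build(left_idx)
    r <- build(right_idx)
    nodes[[me]]$left <<- l
    nodes[[me]]$right <<- r
    me
  }
  root <- build(idx)
  list(nodes = nodes, root = root)
}

# route rows of x through a tree; returns per-subject mortality (sum of the
# terminal cumulative hazard over the training event-time grid), or the
# cumulative hazard at grid index chf_idx when given
tree_mortality <- function(tree, x, chf_idx = NULL) {
  n <- nrow(x)
  out <- numeric(n)
  route <- function(node_id, rows) {
    node <- tree$nodes[[node_id]]
    if (is.na(node$var)) {
      out[rows] <<- if (is.null(chf_idx)) sum(node$chf) else node$chf[chf_idx]
      return(invisible(NULL))
    }
    go_left <- x[rows, node$var] <= node$cut
    if (any(go_left)) route(node$left, rows[go_left])
    if (any(!go_left)) route(node$right, rows[!go_left])
  }
  if (n > 0) route(tree$root, seq_len(n))
  out
}

#' Forest-predicted survival probability at a horizon
#'
#' Forest-averaged Nelson-Aalen cumulative hazard at \code{t}, transformed to
#' survival \code{exp(-H(t))}.
#'
#' @param object a \code{\link{fit_rsf}} model.
#' @param newdata covariate matrix.
#' @param t horizon (single time).
#' @return predicted survival probability per subject.
#' @export
rsf_survival_at <- function(object, newdata, t) {
  x <- if (inherits(newdata, "surv_data")) newdata$x else as.matrix(newdata)
  if (!is.null(colnames(x)) && all(object$covariates %in% colnames(x)))
    x <- x[, object$covariates, drop = FALSE]
  idx <- findInterval(t, object$grid)
  if (idx == 0L) return(rep(1, nrow(x)))
  tot <- numeric(nrow(x))
  for (tree in object$trees) tot <- tot + tree_mortality(tree, x, chf_idx = idx)
  exp(-tot / object$n_trees)
}

#' Fit a random survival forest
#'
#' Bootstrap ensemble of survival trees split by the log-rank score statistic
#' (see \code{\link{logrank_score_split}}). The out-of-bag (OOB) error,
#' \code{1 - OOB C-index} of ensemble mortality, is tracked along the forest
#' so the error-versus-trees curve can be inspected.
#'
#' @param data a \code{\link{surv_data}} with covariates.
#' @param n_trees number of trees.
#' @param mtry variables sampled per node; default \code{ceiling(sqrt(p))}.
#' @param nodesize minimum subjects per terminal node.
#' @param seed mandatory integer seed.
#' @param oob_points approximate number of points on the OOB error curve.
#' @return object of class \code{tiiclnc_rsf} with elements \code{trees},
#'   \code{oob_mortality}, \code{oob_cindex}, \code{oob_error_curve},
#'   and the fit parameters.
#' @export
fit_rsf <- function(data, n_trees = 1000L, mtry = NULL, nodesize = 15L, seed,
                    oob_points = 10L) {
  stopifnot(inherits(data, "surv_data"))
  if (is.null(data$x)) stop("no covariates in 'data'")
  if (missing(seed)) stop("'seed' is mandatory")
  x <- data$x
  n <- nrow(x); p <- ncol(x)
  if (is.null(mtry)) mtry <- ceiling(sqrt(p))
  if (mtry > p) stop("mtry exceeds the number of covariates")
  set.seed(seed)
  grid <- sort(unique(data$time[data$event == 1]))
  trees <- vector("list", n_trees)
  inbag <- vector("list", n_trees)
  oob_sum <- numeric(n)
  oob_cnt <- integer(n)
  curve_at <- unique(pmax(1L, round(seq(1, n_trees, length.out = min(oob_points, n_trees)))))
  curve <- data.frame(n_trees = integer(0), oob_error = numeric(0))
  root_warn <- FALSE
  for (b in seq_len(n_trees)) {
    idx <- sample.int(n, n, replace = TRUE)
    tree <- grow_tree(data$time, data$event, x, idx, mtry, nodesize, grid)
    if (length(tree$nodes) == 1L && b == 1L) root_warn <- TRUE
    trees[[b]] <- tree
    inbag[[b]] <- idx
    oob <- setdiff(seq_len(n), unique(idx))
    if (length(oob)) {
      oob_sum[oob] <- oob_sum[oob] + tree_mortality(tree, x[oob, , drop = FALSE])
      oob_cnt[oob] <- oob_cnt[oob] + 1L
    }
    if (b %in% curve_at) {
      have <- oob_cnt > 0L
      err <- if (sum(have) >= 2 && sum(data$event[have]) >= 1) {
        mort <- oob_sum[have] / oob_cnt[have]
        tryCatch(1 - concordance_index(mort, subset_surv(data, have)),
                 error = function(e) NA_real_)
      } else NA_real_
      curve <- rbind(curve, data.frame(n_trees = b, oob_error = err))
    }
  }
  if (root_warn) warning("no valid split at the root; forest contains single-node trees")
  have <- oob_cnt > 0L
  oob_mort <- rep(NA_real_, n)
  oob_mort[have] <- oob_sum[have] / oob_cnt[have]
  oob_c <- tryCatch(concordance_index(oob_mort[have], subset_surv(data, have)),
                    error = function(e) NA_real_)
  structure(list(trees = trees, inbag = inbag, grid = grid,
                 n_trees = n_trees, mtry = mtry, nodesize = nodesize,
                 seed = seed, covariates = colnames(x),
                 oob_mortality = oob_mort, oob_cindex = oob_c,
                 oob_error_curve = curve, n = n),
            class = "tiiclnc_rsf")
}

#' @export
print.tiiclnc_rsf <- function(x, ...) {
  cat(sprintf("Random survival forest: %d trees, mtry %d, nodesize %d\n",
              x$n_trees, x$mtry, x$nodesize))
  cat(sprintf("  OOB C-index: %.3f\n", x$oob_cindex))
  invisible(x)
}

#' Predict ensemble mortality from a random survival forest
#'
#' @param object a \code{\link{fit_rsf}} model.
#' @param newdata covariate matrix or \code{\link{surv_data}}; columns must
#'   cover the training covariates.
#' @param ... unused.
#' @return numeric risk score (ensemble mortality) per subject.
#' @export
predict.tiiclnc_rsf <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "surv_data")) newdata$x else as.matrix(newdata)
  if (!is.null(colnames(x)) && all(object$covariates %in% colnames(x)))
    x <- x[, object$covariates, drop = FALSE]
  if (ncol(x) != length(object$covariates))
    stop("newdata does not match the training covariates")
  tot <- numeric(nrow(x))
  for (tree in object$trees) tot <- tot + tree_mortality(tree, x)
  tot / object$n_trees
}

#' @rdname predict.tiiclnc_rsf
#' @export
predict_rsf <- function(object, newdata) predict.tiiclnc_rsf(object, newdata)

#' Permutation variable importance for a random survival forest
#'
#' Drop in OOB C-index when a covariate's out-of-bag values are permuted
#' (one permutation per tree).
#'
#' @param model a \code{\link{fit_rsf}} model.
#' @param data the training \code{\link{surv_data}}.
#' @param seed integer seed for the permutations.
#' @return named numeric vector of importance values (positive = informative).
#' @export
rsf_vimp <- function(model, data, seed = model$seed + 1L) {
  x <- data$x[, model$covariates, drop = FALSE]
  n <- nrow(x)
  set.seed(seed)
  have <- !is.na(model$oob_mortality)
  base_c <- model$oob_cindex
  vimp <- stats::setNames(numeric(ncol(x)), colnames(x))
  for (j in seq_len(ncol(x))) {
    perm_sum <- numeric(n)
    perm_cnt <- integer(n)
    for (b in seq_along(model$trees)) {
      oob <- setdiff(seq_len(n), unique(model$inbag[[b]]))
      if (length(oob) < 2L) next
      xp <- x[oob, , drop = FALSE]
      xp[, j] <- xp[sample.int(length(oob)), j]
      perm_sum[oob] <- perm_sum[oob] + tree_mortality(model$trees[[b]], xp)
      perm_cnt[oob] <- perm_cnt[oob] + 1L
    }
    ok <- perm_cnt > 0L
    perm_c <- tryCatch(
      concordance_index(perm_sum[ok] / perm_cnt[ok], subset_surv(data, ok)),
      error = function(e) NA_real_)
    vimp[j] <- base_c - perm_c
  }
  vimp
}
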