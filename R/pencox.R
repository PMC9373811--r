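# Elastic-net penalized Cox regression by cyclic coordinate descent on a
# quadratic (Newton) approximation of the partial likelihood, plus greedy
# stepwise selection by AIC.

soft_threshold <- function(z, g) sign(z) * pmax(abs(z) - g, 0)

#' Elastic-net penalized Cox regression
#'
#' Maximizes \code{loglik(beta) - lambda * (alpha * ||beta||_1 +
#' (1 - alpha)/2 * ||beta||_2^2)} by repeatedly forming the Newton quadratic
#' approximation of the Efron partial likelihood and solving it with cyclic
#' coordinate descent (soft-thresholding). \code{alpha = 1} is the lasso,
#' \code{alpha = 0} ridge; \code{lambda = 0} reproduces the unpenalized
#' \code{\link{fit_cox}} solution.
#'
#' @param data a \code{\link{surv_data}} with covariates.
#' @param alpha elastic-net mixing in [0, 1].
#' @param lambda penalty strength (>= 0), on the scale of the total (not
#'   per-observation) partial likelihood.
#' @param max_outer,max_inner,tol convergence controls.
#' @return object of class \code{tiiclnc_pencox}: \code{beta},
#'   \code{selected} (nonzero coefficients), \code{converged},
#'   \code{alpha}, \code{lambda}.
#' @export
fit_penalized_cox <- function(data, alpha = 1, lambda, max_outer = 100L,
                              max_inner = 200L, tol = 1e-7) {
  stopifnot(inherits(data, "surv_data"))
  if (is.null(data$x)) stop("no covariates in 'data'")
  if (alpha < 0 || alpha > 1) stop("'alpha' must be in [0, 1]")
  if (lambda < 0) stop("'lambda' must be >= 0")
  x <- data$x
  p <- ncol(x)
  beta <- stats::setNames(numeric(p), colnames(x))
  converged <- FALSE
  for (outer in seq_len(max_outer)) {
    der <- cox_loglik_deriv(data$time, data$event, x, beta)
    A <- der$info
    g <- der$score
    b <- beta
    for (inner in seq_len(max_inner)) {
      delta <- 0
      for (j in seq_len(p)) {
        u <- g[j] - sum(A[j, ] * (b - beta)) + A[j, j] * (b[j] - beta[j]) +
          A[j, j] * beta[j]
        denom <- A[j, j] + lambda * (1 - alpha)
        newb <- if (denom <= 0) 0 else soft_threshold(u, lambda * alpha) / denom
        delta <- max(delta, abs(newb - b[j]))
        b[j] <- newb
      }
      if (delta < tol) break
    }
    step <- max(abs(b - beta))
    beta <- b
    if (step < 10 * tol) { converged <- TRUE; break }
  }
  structure(list(beta = beta, selected = names(beta)[beta != 0],
                 converged = converged, alpha = alpha, lambda = lambda,
                 covariates = colnames(x)),
            class = "tiiclnc_pencox")
}

#' @export
print.tiiclnc_pencox <- function(x, ...) {
  cat(sprintf("Penalized Cox (alpha %.2f, lambda %.4g): %d/%d nonzero%s\n",
              x$alpha, x$lambda, length(x$selected), length(x$beta),
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' @export
predict.tiiclnc_pencox <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "surv_data")) newdata$x else as.matrix(newdata)
  drop(x[, object$covariates, drop = FALSE] %*% object$beta)
}

# smallest lambda putting every coefficient at zero (given alpha)
lambda_max_cox <- function(data, alpha) {
  g0 <- cox_loglik_deriv(data$time, data$event, data$x,
                         numeric(ncol(data$x)))$score
  max(abs(g0)) / max(alpha, 1e-3)
}

#' Cross-validated elastic-net Cox
#'
#' Chooses \code{lambda} on a log-spaced path by k-fold cross-validated
#' (Verweij-van Houwelingen) partial likelihood, folds stratified by event
#' status.
#'
#' @inheritParams fit_penalized_cox
#' @param nlambda path length.
#' @param lambda_min_ratio smallest lambda as a fraction of the null lambda.
#' @param k number of folds.
#' @param seed mandatory integer seed for the fold split.
#' @return list: \code{best_lambda}, \code{fit} (refit on all data at
#'   \code{best_lambda}), \code{cv_table}.
#' @export
cv_penalized_cox <- function(data, alpha = 1, nlambda = 20L,
                             lambda_min_ratio = 0.05, k = 10L, seed) {
  if (missing(seed)) stop("'seed' is mandatory")
  lmax <- lambda_max_cox(data, alpha)
  path <- exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = nlambda))
  folds <- stratified_folds(data$event, k, seed)
  cvpl <- numeric(nlambda)
  for (f in seq_len(k)) {
    tr <- folds != f
    dtr <- subset_surv(data, tr)
    beta <- NULL
    for (i in seq_along(path)) {
      fit <- fit_penalized_cox(dtr, alpha = alpha, lambda = path[i])
      eta_all <- drop(data$x %*% fit$beta)
      eta_tr <- drop(dtr$x %*% fit$beta)
      ll_all <- cox_loglik_deriv(data$time, data$event, offset = eta_all,
                                 what = "loglik")$loglik
      ll_tr <- cox_loglik_deriv(dtr$time, dtr$event, offset = eta_tr,
                                what = "loglik")$loglik
      cvpl[i] <- cvpl[i] + (ll_all - ll_tr)
    }
  }
  best <- which.max(cvpl)
  list(best_lambda = path[best],
       fit = fit_penalized_cox(data, alpha = alpha, lambda = path[best]),
       cv_table = data.frame(lambda = path, cv_loglik = cvpl))
}

#' Stepwise Cox regression by AIC
#'
#' Greedy AIC minimization. Forward steps start from the empty model,
#' backward from the full fit, \code{"both"} allows additions and removals
#' from the empty model. Ties in AIC break deterministically by covariate
#' order. Guarded to at most 50 covariates (pre-select first beyond that).
#'
#' @param data a \code{\link{surv_data}} with covariates.
#' @param direction one of \code{"forward"}, \code{"backward"}, \code{"both"}.
#' @return list of class \code{tiiclnc_stepwise}: \code{selected}
#'   (covariate names, possibly empty), \code{fit} (a
#'   \code{\link{fit_cox}} or NULL for the empty model), \code{aic}.
#' @export
stepwise_cox <- function(data, direction = c("forward", "backward", "both")) {
  direction <- match.arg(direction)
  stopifnot(inherits(data, "surv_data"))
  if (is.null(data$x)) stop("no covariates in 'data'")
  p <- ncol(data$x)
  if (p > 50)
    stop("stepwise guard: ", p, " covariates (> 50); pre-select features first")
  vars <- colnames(data$x)
  ll0 <- cox_loglik_deriv(data$time, data$event, what = "loglik")$loglik
  aic_of <- function(sel) {
    if (length(sel) == 0L) return(list(aic = -2 * ll0, fit = NULL))
    fit <- tryCatch(fit_cox(data, covariates = sel), error = function(e) NULL)
    if (is.null(fit) || !fit$converged) return(list(aic = Inf, fit = fit))
    list(aic = cox_aic(fit), fit = fit)
  }
  current <- if (direction == "backward") vars else character(0)
  cur <- aic_of(current)
  repeat {
    moves <- list()
    if (direction %in% c("forward", "both"))
      for (v in setdiff(vars, current)) moves[[length(moves) + 1L]] <- c(current, v)
    if (direction %in% c("backward", "both"))
      for (v in current) moves[[length(moves) + 1L]] <- setdiff(current, v)
    if (length(moves) == 0L) break
    cand <- lapply(moves, aic_of)
    aics <- vapply(cand, `[[`, 0, "aic")
    best <- which.min(aics)          # first on ties: deterministic
    if (aics[best] < cur$aic - 1e-10) {
      current <- moves[[best]]
      cur <- cand[[best]]
    } else break
  }
  structure(list(selected = current, fit = cur$fit, aic = cur$aic,
                 direction = direction),
            class = "tiiclnc_stepwise")
}
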