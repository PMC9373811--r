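# Componentwise likelihood-based boosting for the Cox model.
#
# Each boosting step evaluates, for every covariate, the penalized
# one-dimensional score update at the current linear predictor offset and
# applies a one-step Newton move with ridge penalty to the single covariate
# with the largest penalized score statistic U^2 / (I + penalty). The
# resulting coefficient vector is sparse: at most one new covariate enters
# per step.

# score vector and diagonal information of the Cox partial likelihood at
# beta = 0 for every column of x, given an offset (Efron ties)
cox_score_diag <- function(time, event, x, offset) {
  n <- length(time)
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  x <- x[ord, , drop = FALSE]
  w <- exp(offset[ord])
  wx <- x * w
  wxx <- x * x * w
  p <- ncol(x)
  ev <- which(event == 1)
  if (length(ev) == 0L) return(list(U = numeric(p), I = numeric(p)))
  ev_times <- unique(time[ev])
  gid <- match(time[ev], ev_times)
  d_g <- tabulate(gid)
  first_g <- match(ev_times, time)
  S0 <- rev(cumsum(rev(w)))
  r0 <- S0[first_g]
  r1 <- tail_cumsum(wx)[first_g, , drop = FALSE]
  r2 <- tail_cumsum(wxx)[first_g, , drop = FALSE]
  U <- colSums(x[ev, , drop = FALSE])
  I <- numeric(p)
  single <- d_g == 1L
  if (any(single)) {
    phi <- r0[single]
    m <- r1[single, , drop = FALSE] / phi
    U <- U - colSums(m)
    I <- I + colSums(r2[single, , drop = FALSE] / phi) - colSums(m * m)
  }
  if (any(!single)) {
    sD0 <- drop(rowsum(w[ev], gid))
    sD1 <- rowsum(wx[ev, , drop = FALSE], gid)
    sD2 <- rowsum(wxx[ev, , drop = FALSE], gid)
    for (g in which(!single)) {
      d <- d_g[g]
      for (l in seq_len(d) - 1L) {
        phi <- r0[g] - (l / d) * sD0[g]
        m <- (r1[g, ] - (l / d) * sD1[g, ]) / phi
        U <- U - m
        I <- I + (r2[g, ] - (l / d) * sD2[g, ]) / phi - m * m
      }
    }
  }
  list(U = U, I = I)
}

#' Componentwise CoxBoost
#'
#' Likelihood-based boosting for the Cox proportional hazards model: at each
#' of \code{n_steps} steps the covariate with the largest penalized score
#' statistic receives a one-step ridge-penalized Newton update, all others
#' are left untouched. The default penalty is \code{9 * n_events}, the
#' canonical likelihood-boosting choice; the number of steps is best chosen
#' by \code{\link{cv_coxboost}}.
#'
#' @param data a \code{\link{surv_data}} with covariates.
#' @param n_steps number of boosting steps (>= 1).
#' @param penalty ridge penalty (> 0); default \code{9 * sum(event)}.
#' @return object of class \code{tiiclnc_coxboost}: sparse coefficient
#'   vector \code{beta}, \code{selected} (names of nonzero coefficients),
#'   per-step \code{update_log}, \code{penalty}, \code{n_steps}.
#' @export
fit_coxboost <- function(data, n_steps = 100L, penalty = NULL) {
  stopifnot(inherits(data, "surv_data"))
  if (is.null(data$x)) stop("no covariates in 'data'")
  if (n_steps < 1) stop("'n_steps' must be >= 1")
  if (is.null(penalty)) penalty <- 9 * sum(data$event)
  if (penalty <= 0) stop("'penalty' must be > 0")
  x <- data$x
  p <- ncol(x)
  beta <- stats::setNames(numeric(p), colnames(x))
  offset <- numeric(nrow(x))
  log_rows <- vector("list", n_steps)
  for (s in seq_len(n_steps)) {
    sc <- cox_score_diag(data$time, data$event, x, offset)
    stat <- sc$U^2 / (sc$I + penalty)
    j <- which.max(stat)                      # first index on ties
    nu <- sc$U[j] / (sc$I[j] + penalty)
    beta[j] <- beta[j] + nu
    offset <- offset + nu * x[, j]
    log_rows[[s]] <- data.frame(step = s, covariate = colnames(x)[j],
                                update = nu, score_stat = stat[j])
  }
  structure(list(beta = beta, selected = names(beta)[beta != 0],
                 update_log = do.call(rbind, log_rows),
                 penalty = penalty, n_steps = n_steps,
                 covariates = colnames(x)),
            class = "tiiclnc_coxboost")
}

#' @export
print.tiiclnc_coxboost <- function(x, ...) {
  cat(sprintf("CoxBoost: %d steps, penalty %.1f, %d covariate(s) selected\n",
              x$n_steps, x$penalty, length(x$selected)))
  invisible(x)
}

#' @export
predict.tiiclnc_coxboost <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "surv_data")) newdata$x else as.matrix(newdata)
  drop(x[, object$covariates, drop = FALSE] %*% object$beta)
}

#' Cross-validated choice of the CoxBoost step count
#'
#' K-fold cross-validation (folds stratified by event status) of the
#' Verweij-van Houwelingen cross-validated partial likelihood along the
#' boosting path.
#'
#' @param data a \code{\link{surv_data}} with covariates.
#' @param max_steps path length to explore.
#' @param penalty ridge penalty; default \code{9 * sum(event)}.
#' @param k number of folds.
#' @param seed mandatory integer seed for the fold split.
#' @return list: \code{best_steps}, \code{cv_loglik} (per step count 0..max).
#' @export
cv_coxboost <- function(data, max_steps = 100L, penalty = NULL, k = 10L, seed) {
  stopifnot(inherits(data, "surv_data"))
  if (missing(seed)) stop("'seed' is mandatory")
  if (is.null(penalty)) penalty <- 9 * sum(data$event)
  folds <- stratified_folds(data$event, k, seed)
  x <- data$x
  cvpl <- numeric(max_steps + 1L)
  for (f in seq_len(k)) {
    tr <- folds != f
    dtr <- subset_surv(data, tr)
    beta <- numeric(ncol(x))
    offs_tr <- numeric(sum(tr))
    for (s in 0:max_steps) {
      if (s > 0) {
        sc <- cox_score_diag(dtr$time, dtr$event, dtr$x, offs_tr)
        j <- which.max(sc$U^2 / (sc$I + penalty))
        nu <- sc$U[j] / (sc$I[j] + penalty)
        beta[j] <- beta[j] + nu
        offs_tr <- offs_tr + nu * dtr$x[, j]
      }
      ll_all <- cox_loglik_deriv(data$time, data$event,
                                 offset = drop(x %*% beta),
                                 what = "loglik")$loglik
      ll_tr <- cox_loglik_deriv(dtr$time, dtr$event, offset = offs_tr,
                                what = "loglik")$loglik
      cvpl[s + 1L] <- cvpl[s + 1L] + (ll_all - ll_tr)
    }
  }
  list(best_steps = which.max(cvpl) - 1L,
       cv_loglik = data.frame(steps = 0:max_steps, cv_loglik = cvpl))
}
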