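# Cox partial likelihood machinery (Efron tie handling).
#
# cox_loglik_deriv() returns the log partial likelihood, score vector and
# observed information for a linear predictor offset + X beta; fit_cox()
# runs a guarded Newton-Raphson on it. Everything downstream (univariate
# screen, stepwise, boosting, penalized fits) shares this kernel.

# tail (time-descending) cumulative sums of each column
tail_cumsum <- function(m) {
  n <- nrow(m)
  out <- apply(m[n:1, , drop = FALSE], 2L, cumsum)
  if (is.null(dim(out))) out <- matrix(out, nrow = n)
  out[n:1, , drop = FALSE]
}

# loglik/score/information at beta given covariates x (may be NULL for null
# model) and offset; Efron approximation for tied event times. Vectorized:
# risk-set sums come from tail cumulative sums (second moments in flattened
# upper-triangular layout), tied-set sums from rowsum() over event groups.
cox_loglik_deriv <- function(time, event, x = NULL, beta = NULL, offset = NULL,
                             what = c("all", "loglik")) {
  what <- match.arg(what)
  n <- length(time)
  p <- if (is.null(x)) 0L else ncol(x)
  if (is.null(offset)) offset <- numeric(n)
  eta <- offset + if (p) drop(x %*% beta) else 0
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; eta <- eta[ord]
  if (p) x <- x[ord, , drop = FALSE]
  w <- exp(eta)

  ev <- which(event == 1)
  if (length(ev) == 0L) return(list(loglik = 0, score = numeric(p),
                                    info = matrix(0, p, p)))
  ev_times <- unique(time[ev])                 # ascending (sorted input)
  gid <- match(time[ev], ev_times)             # tie group per event subject
  d_g <- tabulate(gid)
  first_g <- match(ev_times, time)             # first subject in each risk set

  S0 <- rev(cumsum(rev(w)))
  r0 <- S0[first_g]
  sD0 <- drop(rowsum(w[ev], gid))
  loglik <- sum(eta[ev])
  U <- numeric(p)
  I <- matrix(0, p, p)

  if (p) {
    wx <- x * w
    S1 <- tail_cumsum(wx)
    r1 <- S1[first_g, , drop = FALSE]
    sD1 <- rowsum(wx[ev, , drop = FALSE], gid)
    U <- colSums(x[ev, , drop = FALSE])
  }
  want_info <- p > 0 && what == "all"
  if (want_info) {
    ii <- rep(seq_len(p), times = seq_len(p))      # upper-triangular pairs
    jj <- unlist(lapply(seq_len(p), seq_len))
    flat <- x[, ii, drop = FALSE] * x[, jj, drop = FALSE] * w
    S2 <- tail_cumsum(flat)
    r2 <- S2[first_g, , drop = FALSE]
    sD2 <- rowsum(flat[ev, , drop = FALSE], gid)
    unflatten <- function(v) {
      M <- matrix(0, p, p)
      M[cbind(ii, jj)] <- v
      M[cbind(jj, ii)] <- v
      M
    }
  }
  # untied event times in one vectorized pass; Efron inner loop for ties only
  single <- d_g == 1L
  if (any(single)) {
    phi <- r0[single]
    loglik <- loglik - sum(log(phi))
    if (p) {
      m <- r1[single, , drop = FALSE] / phi
      U <- U - colSums(m)
      if (want_info)
        I <- I + unflatten(colSums(r2[single, , drop = FALSE] / phi)) -
          crossprod(m)
    }
  }
  for (g in which(!single)) {
    d <- d_g[g]
    for (l in seq_len(d) - 1L) {
      phi <- r0[g] - (l / d) * sD0[g]
      loglik <- loglik - log(phi)
      if (p) {
        m <- (r1[g, ] - (l / d) * sD1[g, ]) / phi
        U <- U - m
        if (want_info)
          I <- I + unflatten(r2[g, ] - (l / d) * sD2[g, ]) / phi - tcrossprod(m)
      }
    }
  }
  list(loglik = unname(loglik), score = unname(U), info = unname(I))
}

#' Fit a Cox proportional hazards model
#'
#' Newton-Raphson maximization of the Cox partial likelihood with Efron
#' handling of tied event times, implemented from first principles.
#' Convergence is declared when the largest score component falls below
#' \code{tol}; step-halving guards against overshooting. A fit drifting to
#' unbounded coefficients (monotone likelihood, e.g. perfect separation) is
#' flagged as non-converged.
#'
#' @param data a \code{\link{surv_data}} with covariates.
#' @param covariates optional column names/indices selecting a subset.
#' @param init optional starting coefficients.
#' @param max_iter,tol Newton-Raphson controls.
#' @return object of class \code{tiiclnc_cox}: coefficients \code{beta},
#'   standard errors \code{se}, \code{loglik}, \code{loglik_null},
#'   \code{converged}, \code{n_events}, hazard ratios and Wald statistics.
#' @export
fit_cox <- function(data, covariates = NULL, init = NULL,
                    max_iter = 50L, tol = 1e-8) {
  stopifnot(inherits(data, "surv_data"))
  if (is.null(data$x)) stop("no covariates in 'data'")
  x <- if (is.null(covariates)) data$x else data$x[, covariates, drop = FALSE]
  if (sum(data$event) < 2) stop("need at least 2 events")
  p <- ncol(x)
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0))
    stop("degenerate covariate(s) with zero variance: ",
         paste(colnames(x)[sds == 0], collapse = ", "))

  beta <- if (is.null(init)) numeric(p) else init
  ll0 <- cox_loglik_deriv(data$time, data$event, what = "loglik")$loglik
  cur <- cox_loglik_deriv(data$time, data$event, x, beta)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    if (max(abs(cur$score)) < tol) { converged <- TRUE; break }
    step <- tryCatch(solve(cur$info, cur$score), error = function(e) NULL)
    if (is.null(step)) break
    new_beta <- beta + step
    new <- cox_loglik_deriv(data$time, data$event, x, new_beta)
    halvings <- 0L
    while ((!is.finite(new$loglik) || new$loglik < cur$loglik) && halvings < 20L) {
      step <- step / 2
      new_beta <- beta + step
      new <- cox_loglik_deriv(data$time, data$event, x, new_beta)
      halvings <- halvings + 1L
    }
    beta <- new_beta
    cur <- new
    if (max(abs(beta)) > 20) break  # monotone likelihood
  }
  if (!converged && max(abs(cur$score)) < tol) converged <- TRUE
  se <- rep(NA_real_, p)
  cov <- tryCatch(solve(cur$info), error = function(e) NULL)
  if (!is.null(cov)) se <- sqrt(pmax(diag(as.matrix(cov)), 0))
  names(beta) <- names(se) <- colnames(x)
  z <- beta / se
  structure(list(beta = beta, se = se, loglik = cur$loglik, loglik_null = ll0,
                 converged = converged, iter = iter, n_events = sum(data$event),
                 hr = exp(beta), z = z,
                 p_value = 2 * stats::pnorm(-abs(z)),
                 covariates = colnames(x)),
            class = "tiiclnc_cox")
}

#' @export
print.tiiclnc_cox <- function(x, ...) {
  cat(sprintf("Cox model (%d events)%s\n", x$n_events,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  print(data.frame(beta = x$beta, HR = x$hr, se = x$se, z = x$z, p = x$p_value))
  invisible(x)
}

#' @export
predict.tiiclnc_cox <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "surv_data")) newdata$x else as.matrix(newdata)
  drop(x[, object$covariates, drop = FALSE] %*% object$beta)
}

# AIC of a fitted Cox model (2k - 2 loglik)
cox_aic <- function(fit) 2 * length(fit$beta) - 2 * fit$loglik
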