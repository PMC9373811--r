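#' Harrell's concordance index
#'
#' Fraction of usable pairs in which the shorter-lived subject carries the
#' higher risk score. A pair is usable when the shorter follow-up time ends
#' in an event and the times differ; ties in risk count 0.5. Higher risk =
#' worse outcome.
#'
#' @param risk numeric risk score per subject.
#' @param data a \code{\link{surv_data}}.
#' @return concordance in [0, 1].
#' @export
concordance_index <- function(risk, data) {
  stopifnot(inherits(data, "surv_data"))
  n <- length(data$time)
  if (length(risk) != n) stop("one risk score per subject required")
  shorter <- outer(data$time, data$time, "<") & data$event == 1  # row i usable vs col j
  n_usable <- sum(shorter)
  if (n_usable == 0) stop("no usable pairs (all times tied or no events)")
  conc <- outer(risk, risk, ">") + 0.5 * outer(risk, risk, "==")
  sum(conc[shorter]) / n_usable
}

#' Time-dependent AUC with inverse-probability-of-censoring weights
#'
#' Cumulative/dynamic AUC(t): cases are subjects with an observed event by t,
#' controls those still at risk beyond t. Cases are weighted by
#' \code{1 / G(T_i-)} where G is the Kaplan-Meier estimate of the censoring
#' survival function (the constant control weight \code{1/G(t)} cancels).
#' Ties in risk count 0.5.
#'
#' @param risk numeric risk score per subject (higher = worse).
#' @param data a \code{\link{surv_data}}.
#' @param eval_times evaluation horizons.
#' @return data frame with columns \code{time}, \code{auc} (NA when no case
#'   or no control exists at t), \code{n_cases}, \code{n_controls}.
#' @export
time_dependent_auc <- function(risk, data, eval_times) {
  stopifnot(inherits(data, "surv_data"))
  n <- length(data$time)
  if (length(risk) != n) stop("one risk score per subject required")
  # censoring distribution: events are the censorings
  g_fit <- km_estimate(surv_data(data$time, 1 - data$event))
  res <- lapply(eval_times, function(t) {
    case <- data$time <= t & data$event == 1
    ctrl <- data$time > t
    if (!any(case) || !any(ctrl))
      return(data.frame(time = t, auc = NA_real_,
                        n_cases = sum(case), n_controls = sum(ctrl)))
    g <- km_surv_at(g_fit, data$time[case], left = TRUE)
    w <- 1 / pmax(g, .Machine$double.eps)
    cmp <- outer(risk[case], risk[ctrl], ">") +
      0.5 * outer(risk[case], risk[ctrl], "==")
    auc <- sum(w * rowSums(cmp)) / (sum(w) * sum(ctrl))
    data.frame(time = t, auc = auc, n_cases = sum(case), n_controls = sum(ctrl))
  })
  do.call(rbind, res)
}

#' Calibration of predicted survival probabilities
#'
#' Bins subjects into \code{n_groups} equally sized groups by predicted
#' survival at horizon t (sort-based quantile binning) and contrasts the mean
#' prediction with the Kaplan-Meier observed survival at t per bin.
#'
#' @param pred_surv predicted survival probability at \code{t}, per subject.
#' @param data a \code{\link{surv_data}}.
#' @param t horizon.
#' @param n_groups number of bins (>= 2).
#' @return data frame: \code{group}, \code{n}, \code{mean_predicted},
#'   \code{km_observed}.
#' @export
calibration_curve <- function(pred_surv, data, t, n_groups = 5L) {
  stopifnot(inherits(data, "surv_data"))
  n <- length(pred_surv)
  if (n != length(data$time)) stop("one prediction per subject required")
  if (n_groups < 2) stop("'n_groups' must be at least 2")
  if (length(unique(pred_surv)) == 1L) {
    warning("degenerate predictions (all equal): single calibration bin")
    grp <- rep(1L, n)
  } else {
    grp <- ceiling(rank(pred_surv, ties.method = "first") * n_groups / n)
  }
  out <- lapply(sort(unique(grp)), function(g) {
    i <- grp == g
    km <- km_estimate(subset_surv(data, i))
    data.frame(group = g, n = sum(i),
               mean_predicted = mean(pred_surv[i]),
               km_observed = km_surv_at(km, t))
  })
  do.call(rbind, out)
}
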