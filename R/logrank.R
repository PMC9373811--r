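#' Log-rank (Savage) scores for censored survival data
#'
#' Computes the classical log-rank scores used for survival tree splitting.
#' Subjects are ordered by follow-up time (ties broken by original index,
#' recorded in the output); with \eqn{\Gamma_k = \#\{t : T_t \le T_k\}} the
#' score of the j-th ordered subject is
#' \deqn{a_j = \delta_j - \sum_{k=1}^{\Gamma_j} \delta_{(k)} / (n - \Gamma_k + 1).}
#' Scores are returned in original subject order. With distinct times the
#' scores sum to zero.
#'
#' @param data a \code{\link{surv_data}} (covariates ignored).
#' @return list of class \code{logrank_scores}: \code{a} (scores, original
#'   order), \code{gamma}, \code{order}, \code{a_bar} (mean), \code{s2}
#'   (sample variance, n-1 denominator).
#' @export
logrank_scores <- function(data) {
  stopifnot(inherits(data, "surv_data"))
  n <- length(data$time)
  if (n < 2) stop("need at least 2 subjects")
  ord <- order(data$time, seq_len(n))  # stable tie-break by original index
  t_o <- data$time[ord]
  d_o <- data$event[ord]
  # gamma_k = number of follow-up times <= T_(k)  (ties share a value)
  gamma <- findInterval(t_o, t_o)
  inc <- d_o / (n - gamma + 1)
  a_o <- d_o - cumsum(inc)[gamma]
  a <- numeric(n)
  a[ord] <- a_o
  structure(list(a = a, gamma = gamma, order = ord,
                 a_bar = mean(a), s2 = stats::var(a)),
            class = "logrank_scores")
}

#' Log-rank score split statistic
#'
#' Standardized difference of log-rank scores between the two sides of a
#' cutpoint: with \eqn{L = \{j : x_j \le c\}}, \eqn{n_1 = |L|},
#' \deqn{S(x, c) = \frac{\sum_{j \in L} a_j - n_1 \bar a}
#'   {\sqrt{n_1 (1 - n_1/n)\, s_a^2}}.}
#' Survival trees split on the (variable, cutpoint) pair maximizing
#' \eqn{|S(x, c)|}.
#'
#' @param x numeric covariate values, one per subject.
#' @param scores a \code{\link{logrank_scores}} object for the same subjects.
#' @param c cutpoint; subjects with \code{x <= c} form the left side.
#' @return the signed statistic, or \code{NA} if a side is empty or the
#'   scores have zero variance.
#' @export
logrank_score_split <- function(x, scores, c) {
  stopifnot(inherits(scores, "logrank_scores"))
  a <- scores$a
  n <- length(a)
  if (length(x) != n) stop("'x' must have one value per subject")
  n1 <- sum(x <= c)
  if (n1 == 0L || n1 == n) return(NA_real_)
  if (!is.finite(scores$s2) || scores$s2 <= 0) return(NA_real_)
  (sum(a[x <= c]) - n1 * scores$a_bar) /
    sqrt(n1 * (1 - n1 / n) * scores$s2)
}

# vectorized search for the cutpoint maximizing |S(x, c)|; candidates are
# midpoints between consecutive distinct x values with at least min_side
# subjects on each side. Returns NULL if no valid split exists.
best_logrank_split <- function(x, scores, min_side = 1L) {
  a <- scores$a
  n <- length(a)
  if (!is.finite(scores$s2) || scores$s2 <= 0) return(NULL)
  ord <- order(x)
  xs <- x[ord]
  cum <- cumsum(a[ord])
  n1 <- seq_len(n - 1L)
  valid <- (xs[-n] < xs[-1L]) & n1 >= min_side & (n - n1) >= min_side
  if (!any(valid)) return(NULL)
  S <- (cum[-n] - n1 * scores$a_bar) / sqrt(n1 * (1 - n1 / n) * scores$s2)
  S[!valid] <- NA
  k <- which.max(abs(S))  # first (lowest cutpoint) on exact ties
  list(cutpoint = unname((xs[k] + xs[k + 1L]) / 2), statistic = unname(S[k]))
}

#' Kaplan-Meier estimate of the survival function
#'
#' Product-limit estimator. \code{km_surv_at} evaluates the right-continuous
#' step function (optionally its left limit).
#'
#' @param data a \code{\link{surv_data}}.
#' @return data frame of class \code{km_fit}: \code{time} (distinct follow-up
#'   times), \code{n_risk}, \code{n_event}, \code{n_censor}, \code{surv}.
#' @export
km_estimate <- function(data) {
  stopifnot(inherits(data, "surv_data"))
  tt <- sort(unique(data$time))
  n_risk <- vapply(tt, function(t) sum(data$time >= t), 0)
  n_event <- vapply(tt, function(t) sum(data$time == t & data$event == 1), 0)
  n_censor <- vapply(tt, function(t) sum(data$time == t & data$event == 0), 0)
  surv <- cumprod(1 - n_event / n_risk)
  structure(data.frame(time = tt, n_risk = n_risk, n_event = n_event,
                       n_censor = n_censor, surv = surv),
            class = c("km_fit", "data.frame"))
}

#' @rdname km_estimate
#' @param fit a \code{km_fit}.
#' @param t evaluation times.
#' @param left if \code{TRUE}, return the left limit S(t-).
#' @export
km_surv_at <- function(fit, t, left = FALSE) {
  idx <- if (left) findInterval(t, fit$time, left.open = TRUE)
         else findInterval(t, fit$time)
  c(1, fit$surv)[idx + 1L]
}

#' Log-rank test for k groups
#'
#' Classical observed-minus-expected log-rank test with the hypergeometric
#' variance, chi-squared on k-1 degrees of freedom.
#'
#' @param data a \code{\link{surv_data}}.
#' @param groups group labels, one per subject (at least 2 groups, each
#'   nonempty).
#' @return list: \code{chisq}, \code{df}, \code{p_value}, per-group observed
#'   and expected event counts.
#' @export
logrank_test <- function(data, groups) {
  stopifnot(inherits(data, "surv_data"))
  groups <- as.factor(groups)
  if (length(groups) != length(data$time)) stop("one group label per subject")
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) == 0)) stop("empty group")
  k <- nlevels(groups)
  ev_times <- sort(unique(data$time[data$event == 1]))
  O <- E <- numeric(k)
  V <- matrix(0, k, k)
  for (t in ev_times) {
    at_risk <- data$time >= t
    n <- sum(at_risk)
    d <- sum(data$time == t & data$event == 1)
    ng <- vapply(levels(groups), function(g) sum(at_risk & groups == g), 0)
    dg <- vapply(levels(groups), function(g)
      sum(data$time == t & data$event == 1 & groups == g), 0)
    O <- O + dg
    E <- E + d * ng / n
    if (n > 1) {
      f <- d * (n - d) / (n - 1)
      V <- V + f * (diag(ng / n, k) - tcrossprod(ng / n))
    }
  }
  u <- (O - E)[-k]
  Vk <- V[-k, -k, drop = FALSE]
  chisq <- if (all(abs(u) < 1e-12)) 0 else {
    sol <- tryCatch(solve(Vk, u), error = function(e) NULL)
    if (is.null(sol)) 0 else drop(crossprod(u, sol))
  }
  list(chisq = chisq, df = k - 1L,
       p_value = stats::pchisq(chisq, df = k - 1L, lower.tail = FALSE),
       observed = stats::setNames(O, levels(groups)),
       expected = stats::setNames(E, levels(groups)))
}
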