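# shared helpers

# k-fold assignment stratified by a binary label; deterministic under seed
stratified_folds <- function(label, k, seed) {
  set.seed(seed)
  folds <- integer(length(label))
  for (lv in unique(label)) {
    idx <- which(label == lv)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Thin named wrapper over \code{stats::p.adjust(..., method = "BH")}, kept
#' as an explicit surface so the step-up procedure used by the differential
#' filter is a single auditable call.
#'
#' @param p raw p-values.
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

# vectorized Welch two-sample t-test for each row of two matrices
# returns data.frame(statistic, df, p_value, mean_a, mean_b)
row_welch_t <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  if (na < 2 || nb < 2) stop("each group needs at least 2 samples")
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1L, stats::var); vb <- apply(b, 1L, stats::var)
  se2 <- va / na + vb / nb
  stat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(stat), df)
  data.frame(statistic = stat, df = df, p_value = p, mean_a = ma, mean_b = mb)
}
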