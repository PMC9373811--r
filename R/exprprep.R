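#' Convert FPKM to TPM
#'
#' Per sample, \eqn{TPM_g = FPKM_g / \sum_g FPKM_g \times 10^6}, so every
#' column of the result sums to one million. Requires a linear FPKM matrix
#' with strictly positive column sums.
#'
#' @param x an \code{\link{expr_matrix}} on the \code{"linear_fpkm"} scale.
#' @return an \code{expr_matrix} on the \code{"linear_tpm"} scale.
#' @export
fpkm_to_tpm <- function(x) {
  if (expr_scale(x) != "linear_fpkm")
    stop("fpkm_to_tpm expects scale 'linear_fpkm', got '", expr_scale(x), "'")
  cs <- colSums(x)
  if (any(cs <= 0)) {
    bad <- colnames(x)[cs <= 0]
    stop("all-zero expression column(s): ", paste(bad, collapse = ", "))
  }
  expr_matrix(sweep(as_expr_values(x), 2L, cs, "/") * 1e6, scale = "linear_tpm")
}

#' Log2-transform a linear expression matrix
#'
#' \code{value' = log2(value + pseudocount)}. The default pseudocount of 1
#' maps zero expression to zero.
#'
#' @param x an \code{expr_matrix} on a linear scale.
#' @param pseudocount nonnegative offset added before taking logs.
#' @return an \code{expr_matrix} on the \code{"log2"} scale.
#' @export
log2_transform <- function(x, pseudocount = 1) {
  if (expr_scale(x) == "log2") stop("matrix is already on the log2 scale")
  if (pseudocount < 0) stop("'pseudocount' must be nonnegative")
  if (any(x < 0)) stop("negative values cannot be log-transformed")
  expr_matrix(log2(as_expr_values(x) + pseudocount), scale = "log2")
}

#' Undo a log2 transform
#' @param x a log2-scale \code{expr_matrix}.
#' @param pseudocount the offset used when transforming.
#' @param scale linear scale label for the result.
#' @return an \code{expr_matrix} on a linear scale.
#' @export
unlog2 <- function(x, pseudocount = 1, scale = "linear_tpm") {
  if (expr_scale(x) != "log2") stop("unlog2 expects a log2-scale matrix")
  expr_matrix(pmax(2^as_expr_values(x) - pseudocount, 0), scale = scale)
}

#' Quantile-normalize samples
#'
#' Forces every sample (column) onto the same empirical distribution: each
#' column's sorted values are replaced by the row-wise mean of all sorted
#' columns, preserving within-column ranks; ties receive the average of the
#' normalized values over the tied ranks. Delegates to
#' \code{limma::normalizeQuantiles}.
#'
#' @param x an \code{expr_matrix} with at least 2 samples.
#' @return a quantile-normalized \code{expr_matrix} on the same scale.
#' @export
quantile_normalize <- function(x) {
  if (ncol(x) < 2L) {
    warning("quantile normalization of a single sample is the identity")
    return(x)
  }
  out <- limma::normalizeQuantiles(as_expr_values(x), ties = TRUE)
  dimnames(out) <- dimnames(x)
  expr_matrix(out, scale = expr_scale(x))
}

#' Collapse probes to features
#'
#' Maps probe-level rows onto feature (lncRNA) identifiers. When several
#' probes map to one feature the probe with the highest mean expression is
#' kept. Rows absent from the map are dropped (with a message reporting the
#' count).
#'
#' @param x an \code{expr_matrix} whose rownames are probe ids.
#' @param probe_map data frame with columns \code{probe_id}, \code{feature_id}
#'   (many probes may share a feature).
#' @return an \code{expr_matrix} with one row per mapped feature.
#' @export
collapse_probes <- function(x, probe_map) {
  if (!is.data.frame(probe_map) || !all(c("probe_id", "feature_id") %in% names(probe_map)))
    stop("'probe_map' needs columns probe_id and feature_id")
  probe_map <- probe_map[probe_map$probe_id %in% rownames(x), , drop = FALSE]
  if (nrow(probe_map) == 0L) stop("empty probe map: no probe matches the matrix")
  if (any(!nzchar(as.character(probe_map$feature_id))))
    stop("probe map contains empty feature ids")
  n_dropped <- sum(!rownames(x) %in% probe_map$probe_id)
  if (n_dropped > 0L)
    message(n_dropped, " unmapped probe(s) dropped")
  means <- rowMeans(x)[as.character(probe_map$probe_id)]
  # stable: within a feature keep the max-mean probe, first on ties
  ord <- order(as.character(probe_map$feature_id), -means,
               seq_len(nrow(probe_map)))
  pm <- probe_map[ord, , drop = FALSE]
  keep <- pm[!duplicated(pm$feature_id), , drop = FALSE]
  out <- as_expr_values(x)[as.character(keep$probe_id), , drop = FALSE]
  rownames(out) <- as.character(keep$feature_id)
  expr_matrix(out, scale = expr_scale(x))
}

#' Restrict matrices to their common feature set
#'
#' Aligns any number of expression matrices on the ordered intersection of
#' their feature sets (order taken from the first matrix); samples untouched.
#'
#' @param ... two or more \code{expr_matrix} objects.
#' @return a list of matrices sharing an identical ordered feature set.
#' @export
intersect_features <- function(...) {
  mats <- list(...)
  if (length(mats) == 1L && is.list(mats[[1L]]) && !is.matrix(mats[[1L]]))
    mats <- mats[[1L]]
  if (length(mats) < 2L) stop("need at least 2 matrices")
  common <- rownames(mats[[1L]])
  for (m in mats[-1L]) common <- common[common %in% rownames(m)]
  if (length(common) == 0L) stop("empty feature intersection")
  lapply(mats, function(m) m[common, , drop = FALSE])
}
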