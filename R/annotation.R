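#' Immunohistochemistry H-score
#'
#' Semi-quantitative IHC score: staining intensity (0 = negative, 1 = weak,
#' 2 = moderate, 3 = strong) times stained-cell quantity category
#' (0: <10\%, 1: 10-25\%, 2: 25-50\%, 3: 50-75\%, 4: >75\%). Ranges from 0
#' to 12. Vectorized.
#'
#' @param intensity integer(s) in 0..3.
#' @param quantity integer(s) in 0..4.
#' @return integer H-score(s) in 0..12.
#' @export
h_score <- function(intensity, quantity) {
  if (!all(intensity %in% 0:3))
    stop("intensity must be one of 0, 1, 2, 3")
  if (!all(quantity %in% 0:4))
    stop("quantity must be one of 0, 1, 2, 3, 4")
  as.integer(intensity) * as.integer(quantity)
}

#' Correlation between signature scores and a marker
#'
#' Spearman rank correlation with two-sided p-value (rank-based, robust to
#' the scale differences between a model score and e.g. an IHC marker level).
#'
#' @param scores numeric signature scores.
#' @param marker paired marker values (same length, n >= 3).
#' @return list: \code{rho}, \code{p_value}, \code{n}.
#' @export
marker_correlation <- function(scores, marker) {
  if (length(scores) != length(marker)) stop("paired vectors required")
  n <- length(scores)
  if (n < 3) stop("need at least 3 pairs")
  if (stats::sd(scores) == 0 || stats::sd(marker) == 0)
    stop("correlation undefined for a constant vector")
  ct <- suppressWarnings(
    stats::cor.test(scores, marker, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = n)
}

#' Assemble an H-score table
#'
#' @param sample_id,marker identifiers per measurement.
#' @param intensity,quantity IHC scales (see \code{\link{h_score}}).
#' @return data frame sample, marker, intensity, quantity, h_score (the TSV
#'   dialect written by the pipeline).
#' @export
h_score_table <- function(sample_id, marker, intensity, quantity) {
  data.frame(sample_id = sample_id, marker = marker,
             intensity = as.integer(intensity),
             quantity = as.integer(quantity),
             h_score = h_score(intensity, quantity))
}
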