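# The four-stage candidate screen: highly expressed in immune lines ->
# uniformly expressed across immune cell types (low TSI) -> depleted in
# tumor lines -> prognostic in a bulk cohort.

#' Top-expressed candidate lncRNAs per immune cell line
#'
#' For each immune cell line (column), ranks lncRNAs by expression and marks
#' the top \code{ceiling(fraction * n_lnc)}; candidates are aggregated across
#' lines by union (default, the most inclusive reading) or intersection.
#'
#' @param immune an \code{\link{expr_matrix}} (log2) of the immune panel.
#' @param fraction fraction of lncRNAs marked per line, in (0, 1).
#' @param aggregate \code{"union"} or \code{"intersection"} across lines.
#' @return character vector of candidate lncRNA ids (in matrix row order),
#'   with attribute \code{per_line_count} (marked per line).
#' @export
top_expressed_candidates <- function(immune, fraction = 0.15,
                                     aggregate = c("union", "intersection")) {
  aggregate <- match.arg(aggregate)
  if (nrow(immune) == 0L || ncol(immune) == 0L) stop("empty expression matrix")
  if (fraction <= 0 || fraction >= 1) stop("'fraction' must be in (0, 1)")
  m <- ceiling(fraction * nrow(immune))
  marked <- apply(as_expr_values(immune), 2L, function(col) {
    sel <- logical(length(col))
    sel[order(col, decreasing = TRUE)[seq_len(m)]] <- TRUE
    sel
  })
  keep <- if (aggregate == "union") rowSums(marked) > 0 else rowSums(marked) == ncol(immune)
  out <- rownames(immune)[keep]
  attr(out, "per_line_count") <- colSums(marked)
  out
}

#' Tissue (cell-type) specificity index
#'
#' Yanai's specificity index on the per-cell-type expression profile.
#' Replicate lines are averaged within each cell type on the linear scale
#' (log2 input is un-logged first), the profile is normalized by its maximum,
#' and \deqn{TSI = \sum_{i=1}^{N} (1 - x_i) / (N - 1).} TSI is 0 for a
#' uniformly expressed lncRNA and 1 for one expressed in a single cell type.
#'
#' @param immune an \code{\link{expr_matrix}} of the immune panel (log2 or
#'   linear scale).
#' @param annotation data frame with columns \code{sample_id},
#'   \code{cell_type} covering every column of \code{immune}.
#' @param pseudocount offset removed when un-logging log2 input.
#' @return object of class \code{tsi_table}: data frame \code{table}
#'   (lnc_id, tsi; NA for all-zero profiles), matrix \code{x_profile}
#'   (max-normalized per-type profile), \code{n_types}.
#' @export
tsi <- function(immune, annotation, pseudocount = 1) {
  if (!all(c("sample_id", "cell_type") %in% names(annotation)))
    stop("'annotation' needs columns sample_id and cell_type")
  idx <- match(colnames(immune), annotation$sample_id)
  if (anyNA(idx)) stop("annotation does not cover every immune sample")
  types <- as.character(annotation$cell_type)[idx]
  if (length(unique(types)) < 2) stop("need at least 2 cell types")
  vals <- as_expr_values(immune)
  if (expr_scale(immune) == "log2") vals <- pmax(2^vals - pseudocount, 0)
  tl <- split(seq_len(ncol(vals)), types)
  profile <- vapply(tl, function(cols)
    rowMeans(vals[, cols, drop = FALSE]), numeric(nrow(vals)))
  if (nrow(immune) == 1L) profile <- matrix(profile, nrow = 1L,
                                            dimnames = list(rownames(immune), names(tl)))
  N <- ncol(profile)
  mx <- apply(profile, 1L, max)
  zero <- mx == 0
  if (any(zero))
    warning(sum(zero), " all-zero lncRNA(s): TSI undefined, reported as NA")
  xprof <- profile / ifelse(mx == 0, NA, mx)
  tsi_val <- rowSums(1 - xprof) / (N - 1)
  structure(list(table = data.frame(lnc_id = rownames(immune), tsi = tsi_val,
                                    row.names = NULL),
                 x_profile = xprof, n_types = N),
            class = "tsi_table")
}

#' @export
print.tsi_table <- function(x, ...) {
  cat(sprintf("TSI over %d cell types, %d lncRNAs (median %.3f)\n",
              x$n_types, nrow(x$table), stats::median(x$table$tsi, na.rm = TRUE)))
  invisible(x)
}

#' Select immune cell-general lncRNAs by TSI threshold
#'
#' Keeps candidates with \code{TSI < threshold} (strict); undefined TSI is
#' never retained.
#'
#' @param tsi_table a \code{\link{tsi}} result.
#' @param candidates character vector of candidate lncRNA ids.
#' @param threshold TSI cutoff in (0, 1].
#' @return character vector of general (low-TSI) ilncRNA ids.
#' @export
select_general_ilncs <- function(tsi_table, candidates, threshold = 0.2) {
  stopifnot(inherits(tsi_table, "tsi_table"))
  if (threshold <= 0 || threshold > 1) stop("'threshold' must be in (0, 1]")
  tab <- tsi_table$table
  ok <- tab$lnc_id %in% candidates & !is.na(tab$tsi) & tab$tsi < threshold
  tab$lnc_id[ok]
}

#' Immune-versus-tumor differential filter
#'
#' Welch two-sample t-test per ilncRNA on log2 expression, immune lines
#' versus tumor lines, Benjamini-Hochberg corrected; retains lncRNAs that are
#' significantly higher in immune lines (adjusted p < alpha and
#' mean(immune) > mean(tumor)).
#'
#' @param immune,tumor log2 \code{\link{expr_matrix}} objects sharing the
#'   candidate features; each must have at least 2 samples.
#' @param ilncs character vector of ilncRNA ids to test.
#' @param alpha FDR level.
#' @return list: \code{selected} (character), \code{stats} (per-ilncRNA
#'   statistic, raw/adjusted p, log2 fold change).
#' @export
differential_filter <- function(immune, tumor, ilncs, alpha = 0.05) {
  if (expr_scale(immune) != "log2" || expr_scale(tumor) != "log2")
    stop("differential filter expects log2 matrices")
  if (ncol(immune) < 2 || ncol(tumor) < 2) stop("each group needs at least 2 samples")
  missing <- setdiff(ilncs, intersect(rownames(immune), rownames(tumor)))
  if (length(missing)) stop("features absent from a matrix: ",
                            paste(utils::head(missing, 5), collapse = ", "))
  if (length(ilncs) == 0L)
    return(list(selected = character(0), stats = NULL))
  tt <- row_welch_t(as_expr_values(immune[ilncs, , drop = FALSE]),
                    as_expr_values(tumor[ilncs, , drop = FALSE]))
  stats <- data.frame(lnc_id = ilncs, statistic = tt$statistic,
                      p_value = tt$p_value, adj_p = bh_adjust(tt$p_value),
                      log2_fc = tt$mean_a - tt$mean_b, row.names = NULL)
  sel <- stats$adj_p < alpha & stats$log2_fc > 0
  list(selected = stats$lnc_id[sel], stats = stats)
}

#' Univariate Cox prognostic screen
#'
#' One single-covariate Cox fit per lncRNA on within-cohort z-scored
#' expression; retains lncRNAs with Wald p < alpha. Zero-variance lncRNAs
#' are skipped with a warning.
#'
#' @param cohort a \code{\link{surv_cohort}}.
#' @param tiiclncs character vector of lncRNA ids to screen.
#' @param alpha Wald significance level.
#' @return list: \code{selected}, \code{stats} (beta, HR, 95% CI, Wald p,
#'   direction).
#' @export
univariate_cox_screen <- function(cohort, tiiclncs, alpha = 0.05) {
  stopifnot(inherits(cohort, "surv_cohort"))
  if (length(tiiclncs) == 0L)
    return(list(selected = character(0), stats = NULL))
  if (sum(cohort$event) < 2) stop("cohort needs at least 2 events")
  base <- surv_data(cohort$time, cohort$event)
  rows <- vector("list", length(tiiclncs))
  for (i in seq_along(tiiclncs)) {
    g <- tiiclncs[i]
    v <- as.numeric(cohort$expr[g, ])
    if (stats::sd(v) == 0) {
      warning("zero-variance lncRNA skipped: ", g)
      next
    }
    z <- (v - mean(v)) / stats::sd(v)
    fit <- fit_cox(with_covariates(base, matrix(z, ncol = 1,
                                                dimnames = list(NULL, g))))
    rows[[i]] <- data.frame(lnc_id = g, beta = unname(fit$beta),
                            hr = unname(fit$hr),
                            ci_low = exp(unname(fit$beta - 1.96 * fit$se)),
                            ci_high = exp(unname(fit$beta + 1.96 * fit$se)),
                            p_value = unname(fit$p_value),
                            direction = if (fit$beta > 0) "hazardous" else "protective")
  }
  stats <- do.call(rbind, rows)
  if (is.null(stats)) return(list(selected = character(0), stats = NULL))
  list(selected = stats$lnc_id[stats$p_value < alpha], stats = stats)
}

#' Run the full four-stage screen
#'
#' Top-expressed candidates, TSI generality filter, immune-versus-tumor
#' differential filter, and univariate Cox prognostic filter, with a trace of
#' every stage (input size, output size, per-feature statistics). Stage
#' outputs are nested by construction.
#'
#' @param immune,annotation immune panel matrix and cell-type annotation.
#' @param tumor tumor cell line matrix.
#' @param cohort training \code{\link{surv_cohort}}.
#' @param fraction top-expression fraction per line.
#' @param tsi_threshold TSI generality cutoff.
#' @param diff_alpha,cox_alpha significance levels for stages 3 and 4.
#' @param aggregate candidate aggregation across lines.
#' @return object of class \code{screen_trace}: list of per-stage records and
#'   the final \code{selected} set.
#' @export
run_screen <- function(immune, annotation, tumor, cohort, fraction = 0.15,
                       tsi_threshold = 0.2, diff_alpha = 0.05,
                       cox_alpha = 0.05, aggregate = "union") {
  stages <- list()
  note <- function(name, n_in, out, stats = NULL) {
    stages[[name]] <<- list(stage = name, n_in = n_in, n_out = length(out),
                            selected = out, stats = stats)
  }
  cand <- top_expressed_candidates(immune, fraction = fraction,
                                   aggregate = aggregate)
  note("top_expressed", nrow(immune), cand)

  tsi_tab <- tsi(immune, annotation)
  ilncs <- select_general_ilncs(tsi_tab, cand, threshold = tsi_threshold)
  note("tsi_general", length(cand), ilncs,
       tsi_tab$table[tsi_tab$table$lnc_id %in% cand, ])

  diff <- differential_filter(immune, tumor, ilncs, alpha = diff_alpha)
  note("differential", length(ilncs), diff$selected, diff$stats)

  cox <- univariate_cox_screen(cohort, diff$selected, alpha = cox_alpha)
  note("univariate_cox", length(diff$selected), cox$selected, cox$stats)

  structure(list(stages = stages, selected = cox$selected,
                 params = list(fraction = fraction, tsi_threshold = tsi_threshold,
                               diff_alpha = diff_alpha, cox_alpha = cox_alpha,
                               aggregate = aggregate)),
            class = "screen_trace")
}

#' @export
print.screen_trace <- function(x, ...) {
  cat("Four-stage TIIClncRNA screen:\n")
  for (s in x$stages)
    cat(sprintf("  %-15s %5d -> %5d\n", s$stage, s$n_in, s$n_out))
  invisible(x)
}

#' Write a screen trace to disk
#'
#' One TSV per stage holding the per-feature statistics (where available)
#' plus a JSON summary of stage sizes and parameters.
#'
#' @param trace a \code{\link{run_screen}} result.
#' @param dir output directory (created if needed).
#' @export
write_screen_trace <- function(trace, dir) {
  stopifnot(inherits(trace, "screen_trace"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in trace$stages) {
    df <- if (is.null(s$stats)) data.frame(lnc_id = s$selected) else s$stats
    utils::write.table(df, file.path(dir, paste0("stage_", s$stage, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  summary <- list(stages = lapply(trace$stages, function(s)
    list(stage = s$stage, n_in = s$n_in, n_out = s$n_out)),
    params = trace$params, selected = trace$selected)
  jsonlite::write_json(summary, file.path(dir, "screen_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
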