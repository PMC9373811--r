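#' Right-censored survival data
#'
#' Bundles follow-up times, event indicators and an optional covariate matrix
#' (subjects in rows). Times must be strictly positive, events coded 0/1, and
#' no missing values are allowed anywhere.
#'
#' @param time positive numeric vector of follow-up times.
#' @param event 0/1 event indicators (1 = event observed).
#' @param x optional numeric covariate matrix, one row per subject.
#' @param time_unit free-text unit carried as metadata (e.g. "days").
#' @return an object of class \code{surv_data}.
#' @export
surv_data <- function(time, event, x = NULL, time_unit = "days") {
  time <- as.numeric(time)
  event <- as.numeric(event)
  if (length(time) != length(event)) stop("time and event lengths differ")
  if (anyNA(time) || anyNA(event)) stop("missing values in survival data")
  if (any(time <= 0)) stop("all times must be > 0")
  if (!all(event %in% c(0, 1))) stop("event indicators must be 0/1")
  if (!is.null(x)) {
    x <- as.matrix(x)
    if (!is.numeric(x)) stop("covariates must be numeric")
    if (nrow(x) != length(time)) stop("covariate rows must match subjects")
    if (anyNA(x)) stop("missing covariate values")
    if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  }
  structure(list(time = time, event = event, x = x, time_unit = time_unit),
            class = "surv_data")
}

#' @export
print.surv_data <- function(x, ...) {
  cat(sprintf("surv_data: %d subjects, %d events (%.0f%%), %d covariate(s) [%s]\n",
              length(x$time), sum(x$event), 100 * mean(x$event),
              if (is.null(x$x)) 0L else ncol(x$x), x$time_unit))
  invisible(x)
}

n_subjects <- function(d) length(d$time)

subset_surv <- function(d, i) {
  surv_data(d$time[i], d$event[i],
            if (is.null(d$x)) NULL else d$x[i, , drop = FALSE],
            time_unit = d$time_unit)
}

with_covariates <- function(d, x) surv_data(d$time, d$event, x, d$time_unit)

#' A survival cohort: expression joined to outcomes
#'
#' Pairs a log2-scale \code{\link{expr_matrix}} (features x samples) with
#' per-sample survival outcomes and optional clinical covariates.
#'
#' @param expr an \code{expr_matrix}; columns are samples.
#' @param time,event survival outcome per sample (column order of \code{expr}).
#' @param clinical optional data frame of covariates, one row per sample.
#' @param name cohort label.
#' @return an object of class \code{surv_cohort}.
#' @export
surv_cohort <- function(expr, time, event, clinical = NULL, name = "cohort") {
  stopifnot(inherits(expr, "expr_matrix"))
  if (length(time) != ncol(expr)) stop("one outcome per expression column required")
  d <- surv_data(time, event)
  if (!is.null(clinical) && nrow(clinical) != ncol(expr))
    stop("clinical rows must match samples")
  structure(list(expr = expr, time = d$time, event = d$event,
                 clinical = clinical, name = name),
            class = "surv_cohort")
}

#' @export
print.surv_cohort <- function(x, ...) {
  cat(sprintf("surv_cohort '%s': %d features x %d samples, %d events\n",
              x$name, nrow(x$expr), ncol(x$expr), sum(x$event)))
  invisible(x)
}

#' Read and write survival cohorts as TSV
#'
#' Clinical tables use the columns \code{sample_id}, \code{time}, \code{event}
#' plus any covariate columns; expression uses the matrix dialect of
#' \code{\link{read_expr_tsv}}.
#'
#' @param expr_path,clin_path file paths.
#' @param name cohort label.
#' @return a \code{\link{surv_cohort}}.
#' @export
read_cohort_tsv <- function(expr_path, clin_path, name = "cohort") {
  expr <- read_expr_tsv(expr_path)
  clin <- utils::read.delim(clin_path, sep = "\t", check.names = FALSE)
  need <- c("sample_id", "time", "event")
  if (!all(need %in% names(clin)))
    stop("clinical table must have columns ", paste(need, collapse = ", "))
  if (anyNA(clin[need])) stop("missing values in clinical table")
  idx <- match(colnames(expr), clin$sample_id)
  if (anyNA(idx))
    stop("samples without clinical rows: ",
         paste(colnames(expr)[is.na(idx)][1:3], collapse = ", "))
  clin <- clin[idx, , drop = FALSE]
  extra <- setdiff(names(clin), need)
  surv_cohort(expr, clin$time, clin$event,
              clinical = if (length(extra)) clin[extra] else NULL, name = name)
}

#' @rdname read_cohort_tsv
#' @param cohort a \code{surv_cohort} to write.
#' @export
write_cohort_tsv <- function(cohort, expr_path, clin_path) {
  write_expr_tsv(cohort$expr, expr_path)
  clin <- data.frame(sample_id = colnames(cohort$expr),
                     time = cohort$time, event = cohort$event)
  if (!is.null(cohort$clinical)) clin <- cbind(clin, cohort$clinical)
  utils::write.table(clin, clin_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

# standardized (z-scored) covariate matrix from a cohort's expression,
# restricted to 'features'; returns list(x, center, scale)
cohort_design <- function(cohort, features, center = NULL, scale = NULL) {
  missing <- setdiff(features, rownames(cohort$expr))
  if (length(missing))
    stop("cohort '", cohort$name, "' lacks feature(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  x <- t(as_expr_values(cohort$expr[features, , drop = FALSE]))
  if (is.null(center)) center <- colMeans(x)
  if (is.null(scale)) {
    scale <- apply(x, 2L, stats::sd)
    scale[scale == 0] <- 1
  }
  x <- sweep(sweep(x, 2L, center, "-"), 2L, scale, "/")
  list(x = x, center = center, scale = scale)
}
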