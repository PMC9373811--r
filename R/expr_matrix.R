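#' Expression matrix container
#'
#' A lightweight features-by-samples expression matrix carrying an explicit
#' scale flag, the currency of the whole pipeline. Linear scales
#' (\code{"linear_fpkm"}, \code{"linear_tpm"}) must be nonnegative;
#' \code{"log2"} values are unconstrained. Feature and sample identifiers must
#' be unique and nonempty; missing values are rejected outright.
#'
#' @param values numeric matrix, features in rows, samples in columns.
#' @param scale one of \code{"linear_fpkm"}, \code{"linear_tpm"}, \code{"log2"}.
#' @param feature_ids,sample_ids optional identifier vectors; default to the
#'   dimnames of \code{values}.
#' @return An object of class \code{expr_matrix}: the numeric matrix with
#'   dimnames set and a \code{scale} attribute.
#' @examples
#' m <- expr_matrix(matrix(1:6, 2, 3,
#'                         dimnames = list(c("l1", "l2"), c("s1", "s2", "s3"))),
#'                  scale = "linear_fpkm")
#' expr_scale(m)
#' @export
expr_matrix <- function(values, scale = c("log2", "linear_fpkm", "linear_tpm"),
                        feature_ids = rownames(values),
                        sample_ids = colnames(values)) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(feature_ids) || is.null(sample_ids))
    stop("feature and sample identifiers are required")
  feature_ids <- as.character(feature_ids)
  sample_ids <- as.character(sample_ids)
  if (length(feature_ids) != nrow(values) || length(sample_ids) != ncol(values))
    stop("identifier lengths do not match matrix dimensions")
  if (anyDuplicated(feature_ids))
    stop("duplicate feature ids: ",
         paste(unique(feature_ids[duplicated(feature_ids)])[1:3], collapse = ", "))
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  if (any(!nzchar(feature_ids)) || any(!nzchar(sample_ids)))
    stop("empty identifiers are not allowed")
  if (anyNA(values)) stop("missing values are not supported in expression matrices")
  if (scale != "log2" && any(values < 0))
    stop("negative values are invalid on a linear scale")
  dimnames(values) <- list(feature_ids, sample_ids)
  structure(values, scale = scale, class = c("expr_matrix", "matrix", "array"))
}

#' @rdname expr_matrix
#' @param x an \code{expr_matrix}.
#' @export
expr_scale <- function(x) {
  sc <- attr(x, "scale")
  if (is.null(sc)) stop("not an expr_matrix: no scale attribute")
  sc
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d features x %d samples [%s]\n",
              nrow(x), ncol(x), expr_scale(x)))
  n <- min(5L, nrow(x)); m <- min(5L, ncol(x))
  print(unclass(x)[seq_len(n), seq_len(m), drop = FALSE], ...)
  invisible(x)
}

# subsetting keeps class/scale and always returns a matrix
#' @export
`[.expr_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- unclass(x)[i, j, ..., drop = FALSE]
  expr_matrix(out, scale = expr_scale(x))
}

as_expr_values <- function(x) {
  attr(x, "scale") <- NULL
  class(x) <- c("matrix", "array")
  x
}

#' Read and write expression matrices as TSV
#'
#' The on-disk dialect is tab-separated text: an optional comment line
#' \code{#scale=<scale>} recording the scale, then a header row of sample ids
#' with the first column holding feature ids. \code{read_expr_tsv} rejects
#' missing or non-numeric cells.
#'
#' @param path file path.
#' @param scale scale to assume when the file carries no \code{#scale=} header.
#' @return \code{read_expr_tsv}: an \code{\link{expr_matrix}}.
#' @export
read_expr_tsv <- function(path, scale = NULL) {
  first <- readLines(path, n = 1L)
  has_header <- startsWith(first, "#scale=")
  if (has_header) scale <- sub("^#scale=", "", first)
  if (is.null(scale)) stop("no #scale= header in ", path, " and no 'scale' given")
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, colClasses = NA)
  if (ncol(df) < 2L) stop("matrix file needs a feature-id column plus samples")
  ids <- as.character(df[[1L]])
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric expression cells in ", path)
  if (anyNA(vals)) stop("missing values in ", path, " are not supported")
  rownames(vals) <- ids
  expr_matrix(vals, scale = scale)
}

#' @rdname read_expr_tsv
#' @param x an \code{expr_matrix} to write.
#' @export
write_expr_tsv <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#scale=%s", expr_scale(x)), con)
  df <- data.frame(feature_id = rownames(x), as_expr_values(x),
                   check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
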