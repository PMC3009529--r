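#' Multi-replicate expression time series
#'
#' Container for M replicate time courses measured on a common time grid and
#' gene panel: the standard input of the network-inference pipeline. Each
#' replicate is a T x n matrix (rows = time points, columns = genes).
#'
#' @param series list of M numeric T x n matrices, all with identical
#'   dimensions and column order.
#' @param times numeric length-T time grid (sampling index or minutes).
#' @param gene_names character vector of n gene labels.
#' @return An object of class `expression_series_set`.
#' @export
expression_series_set <- function(series, times, gene_names = NULL) {
  if (!is.list(series) || length(series) == 0L)
    stop("`series` must be a non-empty list of matrices")
  series <- lapply(series, function(s) {
    s <- as.matrix(s)
    storage.mode(s) <- "double"
    s
  })
  dims <- vapply(series, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all replicates must share the same T and n")
  T_ <- dims[1, 1]; n <- dims[2, 1]
  if (length(times) != T_) stop("`times` must have one entry per row")
  if (is.null(gene_names)) {
    gene_names <- colnames(series[[1]])
    if (is.null(gene_names)) gene_names <- paste0("G", seq_len(n))
  }
  if (length(gene_names) != n) stop("need one gene name per column")
  series <- lapply(series, function(s) { colnames(s) <- gene_names; s })
  structure(
    list(series = series, times = as.numeric(times), gene_names = gene_names),
    class = "expression_series_set"
  )
}

#' @export
print.expression_series_set <- function(x, ...) {
  cat(sprintf(
    "expression_series_set: %d replicate(s) x %d time points x %d genes\n",
    length(x$series), length(x$times), length(x$gene_names)))
  cat("genes:", paste(x$gene_names, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expression_series_set <- function(x) {
  c(M = length(x$series), T = length(x$times), n = length(x$gene_names))
}

#' Stack a series set into a T x n x M array
#'
#' @param data an [expression_series_set()].
#' @return numeric array with dimensions (time, gene, replicate).
#' @export
series_array <- function(data) {
  stopifnot(inherits(data, "expression_series_set"))
  T_ <- length(data$times); n <- length(data$gene_names)
  arr <- array(NA_real_, dim = c(T_, n, length(data$series)),
               dimnames = list(NULL, data$gene_names, NULL))
  for (m in seq_along(data$series)) arr[, , m] <- data$series[[m]]
  arr
}
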