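#' Inject multiplicative measurement noise
#'
#' Corrupts every expression value as `x * (1 + level * e)` with independent
#' standard-Gaussian `e`, the usual reading of "5% noisy" microarray data
#' (relative noise with standard deviation `level`). Results are clipped to a
#' small positive floor so downstream relative-error fitness stays defined.
#' `level = 0` returns the data unchanged. An additive alternative
#' (`x + level * e`) is available via `model = "additive"`.
#'
#' @param data an [expression_series_set()].
#' @param level relative noise level (e.g. 0.05 for 5%).
#' @param seed optional RNG seed.
#' @param model `"multiplicative"` (default) or `"additive"`.
#' @param floor lower clip applied after corruption.
#' @return a new [expression_series_set()].
#' @export
add_noise <- function(data, level, seed = NULL,
                      model = c("multiplicative", "additive"),
                      floor = 1e-4) {
  stopifnot(inherits(data, "expression_series_set"))
  model <- match.arg(model)
  if (level < 0) stop("noise level must be non-negative")
  if (level == 0) return(data)
  if (!is.null(seed)) set.seed(seed)
  series <- lapply(data$series, function(s) {
    e <- matrix(stats::rnorm(length(s)), nrow(s), ncol(s))
    out <- if (model == "multiplicative") s * (1 + level * e)
           else s + level * e
    pmax(out, floor)
  })
  expression_series_set(series, data$times, data$gene_names)
}

#' Normalise expression to (0, 1] per gene
#'
#' Divides each gene by its maximum over the whole replicate set, then
#' replaces exact zeros with a small positive value `zero_floor` (zeros break
#' both the relative-error fitness and power-law simulators). Idempotent
#' apart from the zero replacement.
#'
#' @param data an [expression_series_set()].
#' @param zero_floor replacement for exact zeros (default 1e-4).
#' @return a new [expression_series_set()] with all values in (0, 1].
#' @export
normalize_series <- function(data, zero_floor = 1e-4) {
  stopifnot(inherits(data, "expression_series_set"))
  arr <- series_array(data)
  gmax <- apply(arr, 2, max)
  if (any(gmax <= 0))
    stop("gene(s) with non-positive maximum cannot be normalised: ",
         paste(data$gene_names[gmax <= 0], collapse = ", "))
  series <- lapply(data$series, function(s) {
    s <- sweep(s, 2, gmax, "/")
    s[s == 0] <- zero_floor
    s
  })
  expression_series_set(series, data$times, data$gene_names)
}
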