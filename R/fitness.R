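#' Fitness configuration
#'
#' Controls how model trajectories are compared with observations. `free_run`
#' chains predictions from each replicate's first observed point; `one_step`
#' predicts every point from the observed previous one (teacher forcing).
#' `relative` scores squared relative errors ((cal-exp)/exp)^2 — the
#' convention of the S-system benchmark lineage — and therefore requires
#' strictly positive observations; `absolute` scores plain squared errors.
#'
#' @param mode `"free_run"` (default) or `"one_step"`.
#' @param normalization `"relative"` (default) or `"absolute"`.
#' @return An object of class `fitness_config`.
#' @export
fitness_config <- function(mode = c("free_run", "one_step"),
                           normalization = c("relative", "absolute")) {
  structure(list(mode = match.arg(mode),
                 normalization = match.arg(normalization)),
            class = "fitness_config")
}

#' Multi-replicate mean squared error of a parameter set
#'
#' The objective minimised during inference: squared (relative) differences
#' between model-computed and observed expression, averaged over all
#' M x n x (T-1) predicted points of all replicates. The first time point of
#' each replicate anchors the recurrence and is never scored. Zero iff the
#' model reproduces every observation exactly.
#'
#' @param params an [ltv_params()] object (or a flattened numeric theta).
#' @param data an [expression_series_set()].
#' @param cfg a [fitness_config()].
#' @return non-negative scalar.
#' @export
ltv_mse <- function(params, data, cfg = fitness_config()) {
  stopifnot(inherits(data, "expression_series_set"))
  n <- length(data$gene_names)
  theta <- if (inherits(params, "ltv_params")) flatten_params(params)
           else as.numeric(params)
  arr <- series_array(data)
  if (cfg$normalization == "relative" && any(arr <= 0))
    stop("relative normalization requires strictly positive observations; ",
         "replace zeros during preprocessing")
  .ltv_mse_batch(matrix(theta, ncol = 1), arr, n,
                 if (cfg$mode == "free_run") 0L else 1L,
                 if (cfg$normalization == "relative") 1L else 0L)[1]
}

#' Batch objective factory for the optimiser
#'
#' Returns a function mapping a D x NP matrix of flattened parameter vectors
#' to NP objective values, evaluated in compiled code. Used as the
#' `batch_objective` of [jde_run()].
#'
#' @inheritParams ltv_mse
#' @return function(matrix) -> numeric vector.
#' @export
ltv_objective <- function(data, cfg = fitness_config()) {
  stopifnot(inherits(data, "expression_series_set"))
  n <- length(data$gene_names)
  arr <- series_array(data)
  if (cfg$normalization == "relative" && any(arr <= 0))
    stop("relative normalization requires strictly positive observations")
  mode <- if (cfg$mode == "free_run") 0L else 1L
  rel <- if (cfg$normalization == "relative") 1L else 0L
  function(thetas) {
    thetas <- as.matrix(thetas)
    .ltv_mse_batch(thetas, arr, n, mode, rel)
  }
}

#' Per-gene batch objective under teacher forcing
#'
#' The one-step objective is a sum of independent per-gene terms, so the
#' parameter block of one regulated gene — its alpha/beta/phi rows plus its
#' omega, flattened as `c(alpha_i., beta_i., phi_i., omega_i)` (length
#' 3n + 1) — can be fitted on its own against the observed states. Exploited
#' by the `"per_gene"` strategy of [infer_grn()].
#'
#' @param data an [expression_series_set()].
#' @param gene 1-based index of the regulated gene; either a scalar shared by
#'   all evaluated columns or one index per column (as used by the blocked
#'   per-gene search).
#' @param normalization `"relative"` or `"absolute"`.
#' @return function(matrix) -> numeric vector of mean squared errors over the
#'   gene's M x (T-1) predictions.
#' @export
ltv_gene_objective <- function(data, gene,
                               normalization = c("relative", "absolute")) {
  stopifnot(inherits(data, "expression_series_set"))
  normalization <- match.arg(normalization)
  n <- length(data$gene_names)
  if (any(gene < 1L) || any(gene > n)) stop("gene index out of range")
  gene <- as.integer(gene)
  arr <- series_array(data)
  if (normalization == "relative" && any(arr <= 0))
    stop("relative normalization requires strictly positive observations")
  rel <- if (normalization == "relative") 1L else 0L
  function(thetas) {
    thetas <- as.matrix(thetas)
    .ltv_mse_gene_batch(thetas, arr, n, gene, rel)
  }
}
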