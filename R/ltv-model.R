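#' Linear time-variant network model parameters
#'
#' The regulatory weight of gene j on gene i at sampling index t is
#' \deqn{W_{ij}(t) = \beta_{ij} + \alpha_{ij} \sin(\omega_i t + \phi_{ij})}
#' a constant interaction strength plus one sinusoid whose slow drift lets a
#' linear-in-state model track nonlinear regulation. One angular frequency
#' \eqn{\omega_i} is shared by all inputs of a regulated gene; amplitude and
#' phase are per pair.
#'
#' @param alpha n x n sinusoid amplitude matrix (dimensionless).
#' @param beta n x n constant interaction strength matrix.
#' @param phi n x n phase matrix (radians).
#' @param omega length-n angular frequency vector (radians per sampling step),
#'   one per regulated gene (row).
#' @param gene_names optional n gene labels.
#' @return An object of class `ltv_params`.
#' @export
ltv_params <- function(alpha, beta, phi, omega, gene_names = NULL) {
  alpha <- as.matrix(alpha); beta <- as.matrix(beta); phi <- as.matrix(phi)
  n <- nrow(alpha)
  if (n < 1L) stop("need at least one gene")
  for (m in list(alpha, beta, phi))
    if (!all(dim(m) == c(n, n))) stop("alpha, beta, phi must all be n x n")
  if (length(omega) != n) stop("omega must have one entry per regulated gene")
  if (!all(is.finite(alpha), is.finite(beta), is.finite(phi),
           is.finite(omega)))
    stop("parameters must be finite")
  if (is.null(gene_names)) gene_names <- paste0("G", seq_len(n))
  if (length(gene_names) != n) stop("need one gene name per gene")
  structure(list(alpha = alpha, beta = beta, phi = phi,
                 omega = as.numeric(omega), gene_names = gene_names),
            class = "ltv_params")
}

#' @export
print.ltv_params <- function(x, ...) {
  cat(sprintf("ltv_params: %d genes (%d free parameters)\n",
              length(x$omega), 3 * length(x$omega)^2 + length(x$omega)))
  invisible(x)
}

n_genes <- function(params) length(params$omega)

#' Time-varying regulatory weight
#'
#' Evaluates \eqn{W_{ij}(t) = \beta_{ij} + \alpha_{ij}\sin(\omega_i t +
#' \phi_{ij})}, the influence of regulator gene j on target gene i at time t.
#' Positive values are induction, negative repression.
#'
#' @param params an [ltv_params()] object.
#' @param i,j target (regulated) and regulator gene indices, 1-based.
#' @param t time value (the package convention is the 0-based sampling index).
#' @return scalar weight (vectorised over `t`).
#' @export
weight_at <- function(params, i, j, t) {
  n <- n_genes(params)
  if (any(i < 1L) || any(i > n) || any(j < 1L) || any(j > n))
    stop("gene index out of range")
  params$beta[i, j] + params$alpha[i, j] * sin(params$omega[i] * t + params$phi[i, j])
}

#' Full weight matrix at one time point
#'
#' @inheritParams weight_at
#' @return n x n matrix W(t).
#' @export
weight_matrix_at <- function(params, t) {
  n <- n_genes(params)
  params$beta + params$alpha * sin(params$omega * t + params$phi)
}

#' Total regulatory input
#'
#' The summed weighted influence of all regulators on each gene:
#' \eqn{Z_i(t) = \sum_j W_{ij}(t) x_j}. Linear in the state `x`.
#'
#' @param params an [ltv_params()] object.
#' @param x length-n expression state at time t.
#' @param t time value.
#' @return length-n numeric vector Z(t).
#' @export
regulatory_input <- function(params, x, t) {
  n <- n_genes(params)
  if (length(x) != n) stop("state length must equal the number of genes")
  if (!all(is.finite(x))) stop("state must be finite")
  as.numeric(weight_matrix_at(params, t) %*% x)
}

#' Squashing function
#'
#' Bounded monotone map from total regulatory input to next-step expression:
#' the logistic sigmoid \eqn{1/(1+e^{-z})}, so predicted expression always
#' lies in (0, 1). Saturates (without overflow) for large |z|.
#'
#' @param z numeric scalar or vector.
#' @return value(s) strictly in (0, 1).
#' @export
squash <- function(z) {
  if (!all(is.finite(z))) stop("input to squash must be finite")
  stats::plogis(z)
}

#' One-step prediction of the recurrence
#'
#' \eqn{x(t+1) = squash(W(t) x(t))} elementwise.
#'
#' @param params an [ltv_params()] object.
#' @param x_t length-n state at time t.
#' @param t time value.
#' @param squash_fn squashing function; the logistic sigmoid by default.
#' @return length-n state at time t + 1.
#' @export
predict_one_step <- function(params, x_t, t, squash_fn = squash) {
  squash_fn(regulatory_input(params, x_t, t))
}

#' Simulate a trajectory of the time-variant recurrence
#'
#' In `free_run` mode each prediction is chained from the previous prediction,
#' starting at `x0`. In `one_step` (teacher-forcing) mode each prediction is
#' made from the observed previous point of `observed`, so errors do not
#' accumulate. The time variable fed to the weights is the 0-based sampling
#' index.
#'
#' @param params an [ltv_params()] object.
#' @param x0 length-n initial state (ignored in `one_step` mode, where the
#'   observed first row is the anchor).
#' @param T_ number of time points to produce (including the initial row).
#' @param mode `"free_run"` or `"one_step"`.
#' @param observed T x n matrix of observations, required for `one_step`.
#' @param squash_fn squashing function hook.
#' @return T x n matrix whose first row is the anchor state.
#' @export
simulate_trajectory <- function(params, x0, T_, mode = c("free_run", "one_step"),
                                observed = NULL, squash_fn = squash) {
  mode <- match.arg(mode)
  n <- n_genes(params)
  if (T_ < 1L) stop("T must be at least 1")
  if (mode == "one_step") {
    if (is.null(observed)) stop("one_step mode requires the observed series")
    observed <- as.matrix(observed)
    if (nrow(observed) < T_ || ncol(observed) != n)
      stop("observed series must be at least T x n")
    x0 <- observed[1L, ]
  }
  if (length(x0) != n) stop("x0 length must equal the number of genes")
  out <- matrix(NA_real_, T_, n, dimnames = list(NULL, params$gene_names))
  out[1L, ] <- x0
  if (T_ == 1L) return(out)
  for (t in seq_len(T_ - 1L)) {
    from <- if (mode == "free_run") out[t, ] else observed[t, ]
    out[t + 1L, ] <- predict_one_step(params, from, t - 1L, squash_fn)
  }
  out
}

#' Static summary weight matrix
#'
#' Reduces the time-varying weights to a single adjacency matrix by averaging
#' W(t) over the sampling grid: \eqn{\bar W_{ij} = \frac1T \sum_t W_{ij}(t)}.
#' With zero amplitudes this is exactly `beta`; over whole sinusoid periods
#' the oscillatory part averages out.
#'
#' @param params an [ltv_params()] object.
#' @param times numeric time grid over which to average (default: 0-based
#'   sampling indices `0:(T-1)` must be supplied by the caller).
#' @return n x n matrix with gene names on both dimensions.
#' @export
static_weight_matrix <- function(params, times) {
  if (length(times) < 1L) stop("time grid must be non-empty")
  W <- Reduce(`+`, lapply(times, function(t) weight_matrix_at(params, t)))
  W <- W / length(times)
  dimnames(W) <- list(params$gene_names, params$gene_names)
  W
}

#' Search bounds per parameter class
#'
#' Lower/upper box constraints for the four parameter classes of the
#' time-variant model. Defaults follow the synthetic-benchmark setup:
#' amplitudes in \[-10, 10\], constant strengths in \[-3, 3\], phases and
#' angular frequencies in \[-pi/2, pi/2\] radians.
#'
#' @param alpha,beta,phi,omega length-2 numeric `c(lower, upper)` per class.
#' @return An object of class `ltv_bounds`.
#' @export
ltv_bounds <- function(alpha = c(-10, 10), beta = c(-3, 3),
                       phi = c(-pi / 2, pi / 2), omega = c(-pi / 2, pi / 2)) {
  b <- list(alpha = alpha, beta = beta, phi = phi, omega = omega)
  for (nm in names(b)) {
    v <- b[[nm]]
    if (length(v) != 2L || !all(is.finite(v)) || v[1] >= v[2])
      stop("bounds for ", nm, " must be c(lower, upper) with lower < upper")
    b[[nm]] <- as.numeric(v)
  }
  structure(b, class = "ltv_bounds")
}

#' Expand class bounds to flat per-component vectors
#'
#' @param bounds an [ltv_bounds()] object.
#' @param n number of genes.
#' @return list with `lower` and `upper`, each of length D = 3n^2 + n, in the
#'   flattened layout `c(alpha, beta, phi, omega)`.
#' @export
expand_bounds <- function(bounds, n) {
  stopifnot(inherits(bounds, "ltv_bounds"), n >= 1L)
  nn <- n * n
  list(
    lower = c(rep(bounds$alpha[1], nn), rep(bounds$beta[1], nn),
              rep(bounds$phi[1], nn), rep(bounds$omega[1], n)),
    upper = c(rep(bounds$alpha[2], nn), rep(bounds$beta[2], nn),
              rep(bounds$phi[2], nn), rep(bounds$omega[2], n))
  )
}

#' Flatten model parameters to an optimisation vector
#'
#' Layout: `c(alpha, beta, phi, omega)` with matrices column-major, giving
#' D = 3n^2 + n components. [unflatten_params()] inverts it.
#'
#' @param params an [ltv_params()] object.
#' @return numeric vector of length D.
#' @export
flatten_params <- function(params) {
  c(as.numeric(params$alpha), as.numeric(params$beta),
    as.numeric(params$phi), params$omega)
}

#' @rdname flatten_params
#' @param theta numeric length-D vector.
#' @param n number of genes.
#' @param gene_names optional labels.
#' @export
unflatten_params <- function(theta, n, gene_names = NULL) {
  nn <- n * n
  if (length(theta) != 3 * nn + n)
    stop("theta length must be 3*n^2 + n")
  ltv_params(
    alpha = matrix(theta[seq_len(nn)], n, n),
    beta  = matrix(theta[nn + seq_len(nn)], n, n),
    phi   = matrix(theta[2 * nn + seq_len(nn)], n, n),
    omega = theta[3 * nn + seq_len(n)],
    gene_names = gene_names
  )
}
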