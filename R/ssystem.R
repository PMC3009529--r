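#' S-system parameters
#'
#' Power-law ODE system used as the ground-truth generator of synthetic
#' benchmark data:
#' \deqn{dX_i/dt = \alpha_i \prod_j X_j^{g_{ij}} - \beta_i \prod_j X_j^{h_{ij}}}
#' with production/degradation rate constants `rate_alpha`, `rate_beta` and
#' kinetic-order matrices `g`, `h`.
#'
#' @param rate_alpha,rate_beta length-n non-negative rate constants.
#' @param g,h n x n kinetic-order matrices.
#' @param gene_names optional labels.
#' @return An object of class `ssystem_params`.
#' @export
ssystem_params <- function(rate_alpha, rate_beta, g, h, gene_names = NULL) {
  g <- as.matrix(g); h <- as.matrix(h)
  n <- length(rate_alpha)
  if (length(rate_beta) != n || !all(dim(g) == n) || !all(dim(h) == n))
    stop("inconsistent S-system dimensions")
  if (any(rate_alpha < 0) || any(rate_beta < 0))
    stop("rate constants must be non-negative")
  if (is.null(gene_names)) gene_names <- paste0("G", seq_len(n))
  structure(list(rate_alpha = as.numeric(rate_alpha),
                 rate_beta = as.numeric(rate_beta),
                 g = g, h = h, gene_names = gene_names),
            class = "ssystem_params")
}

#' The five-gene S-system benchmark network
#'
#' The standard five-gene power-law cascade used throughout the GRN-inference
#' literature as a nonlinear test system. Twelve regulatory influences:
#' every gene degrades itself (h_ii = 2), plus 3->1, 5->1 (repression),
#' 1->2, 2->3 (mixed), 3->4, 5->4 (repression) and 4->5.
#'
#' @return An [ssystem_params()] object.
#' @export
ssystem_benchmark5 <- function() {
  g <- matrix(0, 5, 5)
  h <- matrix(0, 5, 5)
  g[1, 3] <- 1;  g[1, 5] <- -1
  g[2, 1] <- 2
  g[3, 2] <- -1
  g[4, 3] <- 2;  g[4, 5] <- -1
  g[5, 4] <- 2
  diag(h) <- 2
  h[3, 2] <- -1
  ssystem_params(rate_alpha = c(5, 10, 10, 8, 10),
                 rate_beta = rep(10, 5), g = g, h = h)
}

#' S-system right-hand side
#'
#' @param p an [ssystem_params()] object.
#' @param x length-n strictly positive state.
#' @return length-n derivative vector.
#' @export
ssystem_derivatives <- function(p, x) {
  if (length(x) != length(p$rate_alpha)) stop("state length mismatch")
  if (any(x <= 0))
    stop("S-system state must stay strictly positive (power laws with ",
         "negative kinetic orders are undefined at 0)")
  lx <- log(x)
  as.numeric(p$rate_alpha * exp(p$g %*% lx) - p$rate_beta * exp(p$h %*% lx))
}

#' ODE integration configuration
#'
#' @param t_end end of the integration window (start is 0).
#' @param n_points number of uniformly spaced samples in \[0, t_end\].
#' @param step internal fixed step of the 4th-order Runge-Kutta integrator.
#' @param x0_range length-2 range from which random initial values are drawn.
#' @param replicates number of replicate series M.
#' @param seed RNG seed for the initial values.
#' @return An object of class `ode_run_config`.
#' @export
ode_run_config <- function(t_end = 0.5, n_points = 11L, step = 0.0025,
                           x0_range = c(0.05, 1.0), replicates = 10L,
                           seed = NULL) {
  if (n_points < 2L) stop("need at least two sampling points")
  if (step <= 0) stop("step must be positive")
  structure(list(t_end = t_end, n_points = as.integer(n_points), step = step,
                 x0_range = as.numeric(x0_range),
                 replicates = as.integer(replicates), seed = seed),
            class = "ode_run_config")
}

#' Integrate an ODE with fixed-step RK4 on a uniform sampling grid
#'
#' Classic 4th-order Runge-Kutta via [deSolve::ode()] with internal step
#' `cfg$step`, returned at `cfg$n_points` uniform times in \[0, t_end\].
#'
#' @param deriv_fn function(x) -> derivative vector (autonomous systems).
#' @param x0 initial state.
#' @param cfg an [ode_run_config()].
#' @return list with `times` (length-T grid) and `states` (T x n matrix).
#' @export
integrate_ode <- function(deriv_fn, x0, cfg = ode_run_config()) {
  times <- seq(0, cfg$t_end, length.out = cfg$n_points)
  list(times = times,
       states = integrate_at(deriv_fn, x0, times, cfg$step))
}

# RK4 at explicit output times (first entry is t0). Internal.
integrate_at <- function(deriv_fn, x0, times, step) {
  rhs <- function(t, x, parms) list(deriv_fn(x))
  out <- deSolve::ode(y = as.numeric(x0), times = times, func = rhs,
                      parms = NULL, method = "rk4", hini = step)
  states <- unname(as.matrix(out[, -1, drop = FALSE]))
  if (nrow(states) < length(times) || any(!is.finite(states)))
    stop("integration diverged: non-finite state in the sampled window")
  states
}

#' Generate a multi-replicate S-system benchmark dataset
#'
#' Integrates the power-law system from `replicates` random initial states
#' drawn uniformly from `x0_range`, samples `n_points` uniform times, then
#' normalises each gene to (0, 1] against its maximum over the whole set
#' (the observation scale the squashing model emits). Initial draws that
#' fail to integrate are redrawn up to `max_retries` times.
#'
#' @param p an [ssystem_params()] object (default: the five-gene benchmark).
#' @param cfg an [ode_run_config()].
#' @param normalize normalise the set to (0, 1] per gene (default TRUE).
#' @param max_retries redraw budget for failed integrations.
#' @return An [expression_series_set()].
#' @export
generate_ssystem_dataset <- function(p = ssystem_benchmark5(),
                                     cfg = ode_run_config(),
                                     normalize = TRUE, max_retries = 20L) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- length(p$rate_alpha)
  deriv <- function(x) {
    if (any(x <= 0)) stop("state left the positive orthant")
    ssystem_derivatives(p, x)
  }
  series <- vector("list", cfg$replicates)
  times <- NULL
  for (m in seq_len(cfg$replicates)) {
    for (try in seq_len(max_retries + 1L)) {
      x0 <- stats::runif(n, cfg$x0_range[1], cfg$x0_range[2])
      res <- tryCatch(integrate_ode(deriv, x0, cfg), error = function(e) NULL)
      if (!is.null(res) && all(res$states > 0)) break
      res <- NULL
    }
    if (is.null(res))
      stop("could not integrate replicate ", m, " after ", max_retries,
           " retries")
    series[[m]] <- res$states
    times <- res$times
  }
  out <- expression_series_set(series, times, p$gene_names)
  if (normalize) out <- normalize_series(out)
  out
}
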