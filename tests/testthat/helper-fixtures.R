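# Shared fixtures: small random model instances and an independent,
# loop-based implementation of the objective used as oracle.

random_ltv_params <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ltv_params(alpha = matrix(runif(n * n, -2, 2), n),
             beta = matrix(runif(n * n, -2, 2), n),
             phi = matrix(runif(n * n, -pi / 2, pi / 2), n),
             omega = runif(n, -pi / 2, pi / 2))
}

random_series_set <- function(params, M = 2, T_ = 7, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(params$omega)
  series <- lapply(seq_len(M), function(m)
    simulate_trajectory(params, runif(n, 0.1, 0.9), T_, mode = "free_run"))
  expression_series_set(series, seq_len(T_) - 1)
}

# Independent oracle for the multi-replicate MSE: plain nested loops over
# replicates, time and genes, no shared code with the package kernel.
mse_oracle <- function(params, data, mode = "free_run",
                       normalization = "relative") {
  arr <- series_array(data)
  T_ <- dim(arr)[1]; n <- dim(arr)[2]; M <- dim(arr)[3]
  total <- 0
  for (m in seq_len(M)) {
    x <- arr[1, , m]
    for (t in seq_len(T_ - 1)) {
      if (mode == "one_step") x <- arr[t, , m]
      z <- numeric(n)
      for (i in seq_len(n)) {
        for (j in seq_len(n)) {
          w <- params$beta[i, j] +
            params$alpha[i, j] * sin(params$omega[i] * (t - 1) + params$phi[i, j])
          z[i] <- z[i] + w * x[j]
        }
      }
      pred <- 1 / (1 + exp(-z))
      for (i in seq_len(n)) {
        e <- pred[i] - arr[t + 1, i, m]
        if (normalization == "relative") e <- e / arr[t + 1, i, m]
        total <- total + e^2
      }
      if (mode == "free_run") x <- pred
    }
  }
  as.numeric(total / (M * n * (T_ - 1)))
}
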