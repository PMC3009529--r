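# Synthetic data generators: S-system power law, RK4 integration, the cAMP
# oscillator, noise injection and normalisation.

test_that("S-system derivatives follow the power-law form", {
  # exponent-free case: dX_i/dt = alpha_i - beta_i
  p <- ssystem_params(c(3, 1), c(1, 4), matrix(0, 2, 2), matrix(0, 2, 2))
  expect_equal(ssystem_derivatives(p, c(0.7, 0.2)), c(2, -3))

  # benchmark gene 2 balances exactly when X1 = X2:
  # 10*X1^2 - 10*X2^2 = 0
  bench <- ssystem_benchmark5()
  for (c_ in c(0.3, 1, 1.7)) {
    x <- c(c_, c_, 0.5, 0.8, 1.1)
    expect_equal(ssystem_derivatives(bench, x)[2], 0)
  }

  # independent log-domain evaluation as oracle
  set.seed(60)
  g <- matrix(rnorm(9, sd = 0.5), 3); h <- matrix(rnorm(9, sd = 0.5), 3)
  p <- ssystem_params(runif(3, 1, 5), runif(3, 1, 5), g, h)
  x <- runif(3, 0.2, 2)
  oracle <- sapply(1:3, function(i)
    p$rate_alpha[i] * exp(sum(g[i, ] * log(x))) -
      p$rate_beta[i] * exp(sum(h[i, ] * log(x))))
  expect_equal(ssystem_derivatives(p, x), oracle)

  expect_error(ssystem_derivatives(bench, c(0, 1, 1, 1, 1)), "positive")
})

test_that("RK4 integration matches closed forms and converges at 4th order", {
  cfg <- ode_run_config(t_end = 1, n_points = 5, step = 0.01)
  const <- integrate_ode(function(x) 0 * x, c(2, 3), cfg)
  expect_equal(const$states, cbind(rep(2, 5), rep(3, 5)))

  # exponential decay: e^-t within 1e-6 at a moderate step
  dec <- integrate_ode(function(x) -x, 1,
                       ode_run_config(t_end = 1, n_points = 11, step = 1e-3))
  expect_equal(dec$states[, 1], exp(-dec$times), tolerance = 1e-6)

  # halving the step shrinks the error ~16x (order 4)
  err <- sapply(c(0.2, 0.1), function(st) {
    out <- integrate_ode(function(x) -x, 1,
                         ode_run_config(t_end = 2, n_points = 3, step = st))
    abs(out$states[3, 1] - exp(-2))
  })
  expect_gt(err[1] / err[2], 8)
})

test_that("benchmark dataset has the advertised shape and scale", {
  d <- generate_ssystem_dataset(cfg = ode_run_config(replicates = 10,
                                                     n_points = 11,
                                                     seed = 1))
  expect_length(d$series, 10)
  expect_equal(dim(d$series[[1]]), c(11, 5))
  # 10 x 11 = 110 samples per gene
  expect_equal(sum(sapply(d$series, nrow)), 110)
  arr <- series_array(d)
  expect_true(all(arr > 0 & arr <= 1))

  tiny <- generate_ssystem_dataset(cfg = ode_run_config(replicates = 1,
                                                        n_points = 2,
                                                        seed = 2))
  expect_length(tiny$series, 1)
  expect_equal(nrow(tiny$series[[1]]), 2)

  d2 <- generate_ssystem_dataset(cfg = ode_run_config(replicates = 3,
                                                      n_points = 11,
                                                      seed = 33))
  d3 <- generate_ssystem_dataset(cfg = ode_run_config(replicates = 3,
                                                      n_points = 11,
                                                      seed = 33))
  expect_identical(d2$series, d3$series)
})

test_that("cAMP oscillator derivatives implement the stated wiring", {
  k <- laub_loomis_rates()
  # zero state with the constant production term removed gives zero flux
  k0 <- k; k0["k7"] <- 0
  expect_equal(laub_loomis_derivatives(rep(0, 7), k0), rep(0, 7))
  expect_error(laub_loomis_derivatives(rep(1, 6)), "7 components")

  # finite-difference Jacobian signs at a positive state match the wiring
  s0 <- c(1.2, 0.8, 0.9, 1.1, 0.7, 0.3, 1.5)
  J <- matrix(0, 7, 7)
  eps <- 1e-6
  for (j in 1:7) {
    sp <- s0; sp[j] <- sp[j] + eps
    sm <- s0; sm[j] <- sm[j] - eps
    J[, j] <- (laub_loomis_derivatives(sp, k) -
                 laub_loomis_derivatives(sm, k)) / (2 * eps)
  }
  comp <- camp_components()
  dimnames(J) <- list(comp, comp)
  expect_lt(J["ACA", "PKA"], 0)    # PKA -| ACA
  expect_gt(J["ACA", "CAR1"], 0)   # CAR1 -> ACA
  expect_gt(J["PKA", "cAMPi"], 0)
  expect_gt(J["ERK2", "CAR1"], 0)
  expect_lt(J["ERK2", "PKA"], 0)
  expect_lt(J["RegA", "ERK2"], 0)
  expect_gt(J["cAMPi", "ACA"], 0)
  expect_lt(J["cAMPi", "RegA"], 0)
  expect_gt(J["cAMPe", "ACA"], 0)
  expect_gt(J["CAR1", "cAMPe"], 0)
  # every component decays through its own level
  expect_true(all(diag(J) < 0))
})

test_that("cAMP trajectories oscillate with the default constants", {
  tr <- integrate_ode(function(x) laub_loomis_derivatives(x),
                      rep(1, 7),
                      ode_run_config(t_end = 30, n_points = 601, step = 0.01))
  ci <- tr$states[tr$times > 10, 5]  # internal cAMP past the transient
  maxima <- sum(diff(sign(diff(ci))) == -2)
  expect_gte(maxima, 2)
  expect_gt(max(ci) - min(ci), 0.1)  # non-decaying amplitude
})

test_that("cAMP dataset: 5 x 10 = 50 normalised samples per component", {
  d <- generate_camp_dataset(cfg = ode_run_config(t_end = 7.2, n_points = 10,
                                                  step = 0.01,
                                                  x0_range = c(0.2, 1.2),
                                                  replicates = 5, seed = 4))
  expect_length(d$series, 5)
  expect_equal(dim(d$series[[1]]), c(10, 7))
  expect_equal(sum(sapply(d$series, nrow)), 50)
  arr <- series_array(d)
  expect_true(all(arr > 0 & arr <= 1))
  expect_equal(unname(apply(arr, 2, max)), rep(1, 7))
})

test_that("noise injection is calibrated, floored and seeded", {
  p <- random_ltv_params(3, seed = 61)
  d <- random_series_set(p, M = 5, T_ = 20, seed = 62)
  expect_identical(add_noise(d, 0), d)
  expect_error(add_noise(d, -0.1), "non-negative")

  noisy <- add_noise(d, 0.05, seed = 9)
  rel <- (series_array(noisy) - series_array(d)) / series_array(d)
  expect_lt(abs(sd(rel) - 0.05), 0.01)
  expect_true(all(series_array(noisy) >= 1e-4))

  n1 <- add_noise(d, 0.1, seed = 3)
  n2 <- add_noise(d, 0.1, seed = 3)
  expect_identical(n1$series, n2$series)
})

test_that("normalisation maps to (0,1], replaces zeros, and is idempotent", {
  d <- expression_series_set(list(cbind(c(0, 2, 4), c(1, 2, 5))), 0:2,
                             c("a", "b"))
  nm <- normalize_series(d)
  expect_equal(nm$series[[1]][, 1], c(1e-4, 0.5, 1.0))
  expect_equal(nm$series[[1]][, 2], c(0.2, 0.4, 1.0))
  expect_identical(normalize_series(nm)$series, nm$series)

  bad <- expression_series_set(list(cbind(c(0, 0), c(1, 2))), 0:1)
  expect_error(normalize_series(bad), "normalis")
})
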