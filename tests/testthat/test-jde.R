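# Self-adaptive differential evolution: operator semantics, adaptation
# statistics, and end-to-end optimisation behaviour.

test_that("control-parameter adaptation follows the jDE rules", {
  cfg <- jde_config(NP = 4)
  # no-adapt branch: rand2 and rand4 at/above tau keep (F, CR)
  r <- matrix(c(0.7, 0.5, 0.3, 0.9), 1)
  out <- jde_adapt_control(0.5, 0.9, cfg, rand = r)
  expect_equal(out$F, 0.5)
  expect_equal(out$CR, 0.9)

  # adapt branch endpoints: F_new = F_low + rand1 * F_upp
  r <- matrix(c(0, 0.05, 0.42, 0.05), 1)
  out <- jde_adapt_control(0.5, 0.9, cfg, rand = r)
  expect_equal(out$F, 0.1)
  expect_equal(out$CR, 0.42)
  r <- matrix(c(1, 0.05, 0.42, 0.5), 1)
  out <- jde_adapt_control(0.5, 0.9, cfg, rand = r)
  expect_equal(out$F, 1.0)
  expect_equal(out$CR, 0.9)
})

test_that("adaptation frequency matches tau within binomial bounds", {
  set.seed(40)
  n <- 1e5
  cfg <- jde_config(NP = 4)
  out <- jde_adapt_control(rep(0.5, n), rep(0.9, n), cfg)
  p_F <- mean(out$F != 0.5)
  p_CR <- mean(out$CR != 0.9)
  tol <- 3 * sqrt(0.1 * 0.9 / n)
  expect_lt(abs(p_F - 0.1), tol + 1e-6)   # tiny allowance: resampled F can
  expect_lt(abs(p_CR - 0.1), tol + 1e-2)  # collide with the old value; CR
                                          # draws hit [0,1] uniformly
  expect_true(all(out$F >= 0.1 & out$F <= 1.0))
  expect_true(all(out$CR >= 0 & out$CR <= 1))
})

test_that("DE/rand/1 mutation is the documented vector arithmetic", {
  set.seed(41)
  theta <- matrix(rnorm(5 * 6), 5, 6)
  # equal member *vectors* (distinct indices) collapse the difference term
  theta[, 5] <- theta[, 3]
  expect_equal(jde_mutate(theta, 1, 0.7, idx = c(2, 3, 5)),
               theta[, 2])
  expect_equal(jde_mutate(theta, 1, 0, idx = c(4, 2, 5)), theta[, 4])
  expect_equal(jde_mutate(theta, 2, 0.6, idx = c(1, 3, 5)),
               theta[, 1] + 0.6 * (theta[, 3] - theta[, 5]))
  expect_error(jde_mutate(theta, 2, 0.5, idx = c(2, 3, 5)), "distinct")
  expect_error(jde_mutate(theta[, 1:3, drop = FALSE], 1, 0.5),
               "at least 4")
  # sampled indices are always distinct and skip the target
  for (k in 1:50) {
    v <- jde_mutate(theta, 3, 0)
    expect_true(any(apply(theta[, -3], 2, function(col)
      isTRUE(all.equal(col, v)))))
  }
})

test_that("binomial crossover honours CR and the forced index", {
  set.seed(42)
  target <- rnorm(8); donor <- rnorm(8)
  expect_equal(jde_crossover(target, donor, CR = 1), donor)
  tr <- jde_crossover(target, donor, CR = 0, jrand = 5)
  expect_equal(tr[-5], target[-5])
  expect_equal(tr[5], donor[5])
  expect_error(jde_crossover(target, donor[-1], 0.5), "equal length")

  # component-source counts follow Binomial(D-1, CR) for the free positions
  D <- 20; CR <- 0.3; nrep <- 4000
  counts <- replicate(nrep, {
    tr <- jde_crossover(rep(0, D), rep(1, D), CR)
    sum(tr)
  })
  # mean = 1 + (D-1)*CR, sd = sqrt((D-1)*CR*(1-CR))
  expect_equal(mean(counts), 1 + (D - 1) * CR,
               tolerance = 4 * sqrt((D - 1) * CR * (1 - CR) / nrep) /
                 (1 + (D - 1) * CR))
})

test_that("bound repair clamps and is idempotent", {
  lo <- c(-1, 0, 2); hi <- c(1, 5, 3)
  expect_equal(repair_bounds(c(0, 1, 2.5), lo, hi), c(0, 1, 2.5))
  expect_equal(repair_bounds(c(-4, 9, 1), lo, hi), c(-1, 5, 2))
  x <- c(-100, 100, 100)
  expect_equal(repair_bounds(repair_bounds(x, lo, hi), lo, hi),
               repair_bounds(x, lo, hi))
})

test_that("selection is greedy with ties to the trial", {
  tgt <- list(theta = 1, F = 0.5, CR = 0.9, fitness = 2)
  tri <- list(theta = 2, F = 0.6, CR = 0.8, fitness = 1)
  expect_equal(jde_select(tgt, tri)$theta, 2)
  tri$fitness <- 2
  expect_equal(jde_select(tgt, tri)$theta, 2)
  tri$fitness <- 3
  expect_equal(jde_select(tgt, tri)$theta, 1)
  tri$fitness <- NA
  expect_error(jde_select(tgt, tri), "evaluated")
})

test_that("initial population covers the box uniformly", {
  cfg <- jde_config(NP = 1000, seed = NULL)
  set.seed(43)
  pop <- jde_init_population(c(-2, 0), c(2, 1), cfg)
  expect_equal(dim(pop$theta), c(2, 1000))
  expect_true(all(pop$F == 0.5) && all(pop$CR == 0.9))
  expect_lt(min(pop$theta[1, ]), -1.95)
  expect_gt(max(pop$theta[1, ]), 1.95)
  expect_lt(min(pop$theta[2, ]), 0.02)
  expect_gt(max(pop$theta[2, ]), 0.98)

  # degenerate bounds collapse every individual onto the point
  pop0 <- jde_init_population(c(1, 1), c(1, 1), jde_config(NP = 10))
  expect_true(all(pop0$theta == 1))
  expect_error(jde_config(NP = 3), "at least 4")
})

test_that("jde_run solves the sphere and keeps its invariants", {
  cfg <- jde_config(NP = 50, max_generations = 200, seed = 99)
  res <- jde_run(function(th) sum(th^2), rep(-5, 10), rep(5, 10), cfg)
  expect_lt(res$best$fitness, 1e-3)
  # monotone non-increasing best fitness (greedy selection)
  expect_true(all(diff(res$history$best_fitness) <= 1e-15))
  # control parameters stay in range throughout
  expect_true(all(res$population$F >= 0.1 & res$population$F <= 1))
  expect_true(all(res$population$CR >= 0 & res$population$CR <= 1))
  # population size constant
  expect_equal(ncol(res$population$theta), 50)
})

test_that("jde_run is deterministic given a seed", {
  cfg <- jde_config(NP = 20, max_generations = 50, seed = 7)
  f <- function(th) sum((th - 1)^2)
  r1 <- jde_run(f, rep(-3, 5), rep(3, 5), cfg)
  r2 <- jde_run(f, rep(-3, 5), rep(3, 5), cfg)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$best, r2$best)
})

test_that("zero generations returns the best of the initial population", {
  cfg <- jde_config(NP = 30, max_generations = 0, seed = 11)
  f <- function(th) sum(th^2)
  res <- jde_run(f, rep(-2, 4), rep(2, 4), cfg)
  expect_equal(res$best$fitness, min(res$population$fitness))
  expect_equal(nrow(res$history), 0)
})

test_that("tau = 0 reduces jDE to classic DE with frozen controls", {
  cfg <- jde_config(NP = 20, max_generations = 30, tau1 = 0, tau2 = 0,
                    seed = 13)
  res <- jde_run(function(th) sum(th^2), rep(-2, 3), rep(2, 3), cfg)
  expect_true(all(res$population$F == 0.5))
  expect_true(all(res$population$CR == 0.9))
})

test_that("the fused per-gene engine is deterministic and converges", {
  p <- random_ltv_params(3, seed = 50)
  d <- random_series_set(p, M = 3, T_ = 8, seed = 51)
  cfg <- jde_config(NP = 50, max_generations = 400)
  f1 <- infer_grn(d, runs = 1, jde = cfg, seed = 5)
  f2 <- infer_grn(d, runs = 1, jde = cfg, seed = 5)
  expect_identical(f1$runs[[1]]$W, f2$runs[[1]]$W)
  # data generated by the model itself: near-exact one-step fit is reachable
  expect_lt(f1$runs[[1]]$best_fitness, 5e-3)
  # monotone best-fitness trace
  expect_true(all(diff(f1$runs[[1]]$history$best_fitness) <= 1e-15))
})
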