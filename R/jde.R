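#' Configuration of the self-adaptive differential evolution optimiser
#'
#' jDE: classic DE/rand/1/bin in which every individual carries its own
#' amplification factor F and crossover rate CR, stochastically resampled
#' with probabilities `tau1` and `tau2` before its mutation each generation,
#' so control settings that produce good offspring propagate with them.
#'
#' @param NP population size (at least 4; mutation draws 3 distinct
#'   non-target members).
#' @param max_generations number of generations to run.
#' @param tau1,tau2 adaptation probabilities for F and CR.
#' @param F_low,F_upp resampled F is `F_low + rand * F_upp`, i.e. in
#'   \[0.1, 1.0\] with the defaults.
#' @param F_init,CR_init control values assigned to every initial individual.
#' @param seed integer seed for the run's single RNG stream (`NULL` = leave
#'   the RNG state alone).
#' @return An object of class `jde_config`.
#' @export
jde_config <- function(NP = 200L, max_generations = 10000L,
                       tau1 = 0.1, tau2 = 0.1,
                       F_low = 0.1, F_upp = 0.9,
                       F_init = 0.5, CR_init = 0.9, seed = NULL) {
  if (NP < 4L) stop("NP must be at least 4")
  for (p in c(tau1, tau2))
    if (p < 0 || p > 1) stop("tau1 and tau2 must be probabilities")
  structure(list(NP = as.integer(NP),
                 max_generations = as.integer(max_generations),
                 tau1 = tau1, tau2 = tau2, F_low = F_low, F_upp = F_upp,
                 F_init = F_init, CR_init = CR_init, seed = seed),
            class = "jde_config")
}

#' Initialise a jDE population
#'
#' Every component of every parameter vector is drawn uniformly within its
#' box bounds; every individual starts with F = `F_init`, CR = `CR_init`.
#'
#' @param lower,upper length-D numeric bound vectors.
#' @param cfg a [jde_config()].
#' @param objective optional function(theta) -> scalar used to evaluate the
#'   initial fitnesses; left `NA` if omitted.
#' @return list with `theta` (D x NP matrix), `F`, `CR`, `fitness` (length-NP).
#' @export
jde_init_population <- function(lower, upper, cfg = jde_config(),
                                objective = NULL) {
  D <- length(lower)
  if (length(upper) != D) stop("lower and upper must have equal length")
  if (any(lower > upper)) stop("lower bound exceeds upper bound")
  theta <- matrix(stats::runif(D * cfg$NP, lower, upper), nrow = D)
  fit <- rep(NA_real_, cfg$NP)
  if (!is.null(objective)) fit <- apply(theta, 2, objective)
  list(theta = theta,
       F = rep(cfg$F_init, cfg$NP),
       CR = rep(cfg$CR_init, cfg$NP),
       fitness = fit)
}

#' Self-adaptation of the control parameters
#'
#' With probability `tau1` an individual's F is resampled uniformly in
#' \[F_low, F_low + F_upp\]; with probability `tau2` its CR is resampled
#' uniformly in \[0, 1\]; otherwise both are inherited unchanged. The new
#' values are decided *before* mutation, so they steer the operators that
#' build this generation's trial vector.
#'
#' @param F,CR current control values (vectorised over individuals).
#' @param cfg a [jde_config()].
#' @param rand optional length(F) x 4 matrix of uniforms (rand1..rand4 per
#'   individual) for deterministic testing; drawn from the RNG if omitted.
#' @return list with updated `F` and `CR` vectors.
#' @export
jde_adapt_control <- function(F, CR, cfg = jde_config(), rand = NULL) {
  k <- length(F)
  if (length(CR) != k) stop("F and CR must have equal length")
  if (is.null(rand)) rand <- matrix(stats::runif(4 * k), nrow = k)
  F_new <- ifelse(rand[, 2] < cfg$tau1, cfg$F_low + rand[, 1] * cfg$F_upp, F)
  CR_new <- ifelse(rand[, 4] < cfg$tau2, rand[, 3], CR)
  list(F = F_new, CR = CR_new)
}

#' DE/rand/1 mutation
#'
#' Donor vector `V = X_r1 + F * (X_r2 - X_r3)` built from three distinct
#' population members, none of which is the target.
#'
#' @param theta D x NP population matrix.
#' @param target_idx index of the target individual.
#' @param F amplification factor for this individual.
#' @param idx optional integer triple (r1, r2, r3) for deterministic testing;
#'   sampled uniformly without replacement from the non-target members if
#'   omitted.
#' @return length-D donor vector.
#' @export
jde_mutate <- function(theta, target_idx, F, idx = NULL) {
  NP <- ncol(theta)
  if (NP < 4L) stop("mutation needs at least 4 individuals")
  if (is.null(idx)) {
    idx <- sample.int(NP - 1L, 3L)
    idx[idx >= target_idx] <- idx[idx >= target_idx] + 1L
  }
  if (length(unique(idx)) != 3L || target_idx %in% idx)
    stop("r1, r2, r3 must be distinct and differ from the target")
  theta[, idx[1]] + F * (theta[, idx[2]] - theta[, idx[3]])
}

#' Binomial crossover
#'
#' Each trial component comes from the donor with probability CR, from the
#' target otherwise; one uniformly chosen index `j_rand` always comes from
#' the donor, so the trial differs from the target whenever the donor does.
#'
#' @param target,donor length-D vectors.
#' @param CR crossover rate in \[0, 1\].
#' @param jrand optional forced index; sampled if omitted.
#' @param rand optional length-D uniforms for deterministic testing.
#' @return length-D trial vector.
#' @export
jde_crossover <- function(target, donor, CR, jrand = NULL, rand = NULL) {
  D <- length(target)
  if (length(donor) != D) stop("target and donor must have equal length")
  if (is.null(jrand)) jrand <- sample.int(D, 1L)
  if (is.null(rand)) rand <- stats::runif(D)
  take <- rand < CR
  take[jrand] <- TRUE
  ifelse(take, donor, target)
}

#' Clamp a parameter vector to its box bounds
#'
#' Components that leave the search region are set to the violated boundary
#' value. Idempotent.
#'
#' @param theta numeric vector (or D x NP matrix).
#' @param lower,upper bound vectors recycled along columns.
#' @return clamped object of the same shape.
#' @export
repair_bounds <- function(theta, lower, upper) {
  pmin(pmax(theta, lower), upper)
}

#' Greedy one-to-one selection
#'
#' Keeps whichever of target and trial has the smaller objective value; ties
#' go to the trial (the standard DE convention, which lets the population
#' drift across plateaus). Each individual is a list with `theta`, `F`, `CR`
#' and `fitness`; the survivor keeps its own control parameters.
#'
#' @param target,trial individual lists with evaluated `fitness`.
#' @return the surviving individual.
#' @export
jde_select <- function(target, trial) {
  if (is.na(target$fitness) || is.na(trial$fitness))
    stop("both individuals must have evaluated fitness")
  if (trial$fitness <= target$fitness) trial else target
}

#' Run the jDE optimisation loop
#'
#' Full self-adaptive DE: per generation and per individual, adapt (F, CR),
#' mutate (DE/rand/1), binomial crossover, boundary repair, evaluate, greedy
#' select. All randomness flows from one RNG stream seeded by
#' `config$seed`, with a fixed draw order per generation (adaptation
#' uniforms, mutation indices, crossover uniforms, forced crossover index),
#' so runs are exactly reproducible.
#'
#' @param objective function(theta) -> scalar to minimise.
#' @param lower,upper length-D box bounds.
#' @param config a [jde_config()].
#' @param batch_objective optional function(D x k matrix) -> length-k vector
#'   evaluated instead of `objective` for whole populations (used for the
#'   compiled model objective).
#' @return list of class `jde_result`: `best` (theta, F, CR, fitness),
#'   `history` (per-generation best/mean fitness and mean control values),
#'   final `population`, and the `config`.
#' @export
jde_run <- function(objective, lower, upper, config = jde_config(),
                    batch_objective = NULL) {
  evalfun <- if (!is.null(batch_objective)) batch_objective
             else function(m) apply(m, 2, objective)
  eng <- jde_engine(lower, upper, config, evalfun, blocks = 1L)
  pop <- eng$pop
  b <- which.min(pop$fitness)
  structure(list(
    best = list(theta = pop$theta[, b], F = pop$F[b], CR = pop$CR[b],
                fitness = pop$fitness[b]),
    history = data.frame(generation = seq_len(nrow(eng$best_hist)),
                         best_fitness = eng$best_hist[, 1],
                         mean_fitness = eng$mean_hist[, 1],
                         mean_F = eng$mean_F, mean_CR = eng$mean_CR),
    population = pop, config = config
  ), class = "jde_result")
}

# Vectorised jDE engine evolving `blocks` independent populations of NP
# individuals side by side (columns 1..NP are block 1, and so on). Blocks
# never exchange individuals: mutation indices are drawn within a block.
# Running b subproblems in one matrix keeps the per-generation R overhead
# independent of b; all randomness comes from the current RNG stream (seeded
# from config$seed) in a fixed order per generation: adaptation uniforms,
# mutation indices, crossover uniforms, forced crossover indices.
jde_engine <- function(lower, upper, config, evalfun, blocks = 1L) {
  if (!is.null(config$seed)) set.seed(config$seed)
  D <- length(lower)
  NP <- config$NP
  ncols <- NP * blocks
  block_of <- rep(seq_len(blocks), each = NP)

  theta <- matrix(stats::runif(D * ncols, lower, upper), nrow = D)
  Fv <- rep(config$F_init, ncols)
  CRv <- rep(config$CR_init, ncols)
  fit <- as.numeric(evalfun(theta))

  gens <- config$max_generations
  best_hist <- matrix(NA_real_, gens, blocks)
  mean_hist <- matrix(NA_real_, gens, blocks)
  mean_F <- mean_CR <- rep(NA_real_, gens)
  offset <- (seq_len(blocks) - 1L) * NP

  for (g in seq_len(gens)) {
    ctl <- jde_adapt_control(Fv, CRv, config)

    ridx <- draw_mutation_indices(NP, blocks)
    donors <- theta[, ridx[1L, ], drop = FALSE] +
      rep(ctl$F, each = D) * (theta[, ridx[2L, ], drop = FALSE] -
                              theta[, ridx[3L, ], drop = FALSE])

    cross <- matrix(stats::runif(D * ncols), nrow = D) <
      rep(ctl$CR, each = D)
    jrand <- sample.int(D, ncols, replace = TRUE)
    cross[cbind(jrand, seq_len(ncols))] <- TRUE
    trial <- donors
    keep <- !cross
    trial[keep] <- theta[keep]
    trial <- repair_bounds(trial, lower, upper)

    trial_fit <- as.numeric(evalfun(trial))
    win <- trial_fit <= fit
    theta[, win] <- trial[, win]
    fit[win] <- trial_fit[win]
    Fv[win] <- ctl$F[win]
    CRv[win] <- ctl$CR[win]

    fb <- vapply(seq_len(blocks), function(b)
      min(fit[offset[b] + seq_len(NP)]), numeric(1))
    mb <- vapply(seq_len(blocks), function(b)
      mean(fit[offset[b] + seq_len(NP)]), numeric(1))
    best_hist[g, ] <- fb
    mean_hist[g, ] <- mb
    mean_F[g] <- mean(Fv)
    mean_CR[g] <- mean(CRv)
  }

  list(pop = list(theta = theta, F = Fv, CR = CRv, fitness = fit),
       block_of = block_of, best_hist = best_hist, mean_hist = mean_hist,
       mean_F = mean_F, mean_CR = mean_CR)
}

# 3 distinct indices per target, none equal to the target, all within the
# target's own block: vectorised rejection sampling.
draw_mutation_indices <- function(NP, blocks) {
  ncols <- NP * blocks
  tgt <- rep(seq_len(NP), blocks)
  r <- matrix(sample.int(NP, 3L * ncols, replace = TRUE), nrow = 3L)
  repeat {
    bad <- r[1L, ] == tgt | r[2L, ] == tgt | r[3L, ] == tgt |
      r[1L, ] == r[2L, ] | r[1L, ] == r[3L, ] | r[2L, ] == r[3L, ]
    if (!any(bad)) break
    r[, bad] <- sample.int(NP, 3L * sum(bad), replace = TRUE)
  }
  r + matrix(rep((seq_len(blocks) - 1L) * NP, each = NP),
             nrow = 3L, ncol = ncols, byrow = TRUE)
}

#' @export
print.jde_result <- function(x, ...) {
  cat(sprintf("jde_result: best fitness %.6g after %d generations (NP = %d)\n",
              x$best$fitness, x$config$max_generations, x$config$NP))
  invisible(x)
}
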