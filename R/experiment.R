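#' Run a named benchmark experiment end to end
#'
#' Chains data generation, repeated jDE inference, per-run scoring and
#' Z-score consensus for one of the built-in benchmark conditions:
#'
#' * `"noise-free"` — five-gene S-system, 10 replicates x 11 points;
#' * `"noise5"` / `"noise10"` — the same data with 5% / 10% multiplicative
#'   Gaussian noise;
#' * `"camp"` — Laub-Loomis cAMP oscillator, 5 replicates x 10 points,
#'   amplitude bounds narrowed to \[-5, 5\].
#'
#' All randomness (initial values, noise, optimiser) derives from `seed`.
#'
#' @param name experiment name.
#' @param runs independent optimisation runs.
#' @param generations jDE generations per run.
#' @param NP jDE population size.
#' @param seed base seed.
#' @param magnitude_threshold edge pruning threshold.
#' @param Z_th consensus Z threshold.
#' @return list with `data`, `gold`, `fit` (a [infer_grn()] result) and
#'   `scores` (a [score_inference()] result).
#' @export
run_experiment <- function(name = c("noise-free", "noise5", "noise10", "camp"),
                           runs = 3L, generations = 1500L, NP = 200L,
                           seed = 1L, magnitude_threshold = 0.5, Z_th = 1.0) {
  name <- match.arg(name)
  seed <- as.integer(seed)
  if (name == "camp") {
    cfg <- ode_run_config(t_end = 7.2, n_points = 10L, step = 0.01,
                          x0_range = c(0.2, 1.2), replicates = 5L,
                          seed = seed)
    data <- generate_camp_dataset(cfg = cfg)
    gold <- camp_gold_standard()
    bounds <- ltv_bounds(alpha = c(-5, 5))
  } else {
    cfg <- ode_run_config(replicates = 10L, n_points = 11L, seed = seed)
    data <- generate_ssystem_dataset(cfg = cfg)
    gold <- gold_from_ssystem(ssystem_benchmark5())
    bounds <- ltv_bounds()
    level <- switch(name, "noise5" = 0.05, "noise10" = 0.10, 0)
    if (level > 0) data <- add_noise(data, level, seed = seed + 1L)
  }
  fit <- infer_grn(data, bounds = bounds, runs = runs,
                   jde = jde_config(NP = NP, max_generations = generations),
                   seed = seed + 100L)
  scores <- score_inference(fit, gold, magnitude_threshold, Z_th)
  list(name = name, data = data, gold = gold, fit = fit, scores = scores)
}
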