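#' Rate constants of the cAMP oscillator
#'
#' The 14 rate constants of the Laub-Loomis seven-component model of
#' spontaneous cAMP oscillations during *Dictyostelium discoideum*
#' aggregation (units: min^-1 for first-order terms, uM^-1 min^-1 for
#' second-order terms, uM min^-1 for the constant RegA production k7).
#' With these values the system settles onto a stable limit cycle with a
#' period of roughly 7 minutes.
#'
#' @return named numeric vector k1..k14.
#' @export
laub_loomis_rates <- function() {
  c(k1 = 2.0, k2 = 0.9, k3 = 2.5, k4 = 1.5, k5 = 0.6, k6 = 0.8, k7 = 1.0,
    k8 = 1.3, k9 = 0.3, k10 = 0.8, k11 = 0.7, k12 = 4.9, k13 = 23.0,
    k14 = 4.5)
}

#' Component names of the cAMP oscillator, in model order.
#' @return character vector of length 7.
#' @export
camp_components <- function() {
  c("ACA", "PKA", "ERK2", "RegA", "cAMPi", "cAMPe", "CAR1")
}

#' Right-hand side of the cAMP oscillation network
#'
#' Seven coupled ODEs: extracellular cAMP (cAMPe) bound to the receptor CAR1
#' activates the adenylyl cyclase ACA and the MAP kinase ERK2; internal cAMP
#' (cAMPi, produced by ACA and hydrolysed by RegA) activates PKA, which
#' inhibits both ACA and ERK2; ERK2 inhibits RegA; ACA secretes cAMPe, which
#' binds CAR1 — closing the oscillatory loop. Each component also decays.
#'
#' @param state length-7 non-negative vector in [camp_components()] order.
#' @param k length-14 rate constants (default [laub_loomis_rates()]).
#' @return length-7 derivative vector.
#' @export
laub_loomis_derivatives <- function(state, k = laub_loomis_rates()) {
  if (length(state) != 7L) stop("state must have 7 components")
  if (length(k) != 14L) stop("need 14 rate constants")
  ACA <- state[1]; PKA <- state[2]; ERK2 <- state[3]; RegA <- state[4]
  cAMPi <- state[5]; cAMPe <- state[6]; CAR1 <- state[7]
  k <- unname(k)
  c(k[1] * CAR1 - k[2] * ACA * PKA,
    k[3] * cAMPi - k[4] * PKA,
    k[5] * CAR1 - k[6] * PKA * ERK2,
    k[7] - k[8] * ERK2 * RegA,
    k[9] * ACA - k[10] * RegA * cAMPi,
    k[11] * ACA - k[12] * cAMPe,
    k[13] * cAMPe - k[14] * CAR1)
}

#' Generate replicate time courses from the cAMP oscillator
#'
#' Each replicate starts from random initial concentrations, is integrated
#' past a transient window so it reaches the limit cycle, and is then sampled
#' at `cfg$n_points` uniform instants spanning `cfg$t_end` minutes (about one
#' oscillation period with the defaults). The set is normalised per component
#' to (0, 1]. Defaults emulate the in-silico benchmark: 5 replicates x 10
#' instants x 7 components, i.e. 50 samples per component.
#'
#' @param k rate constants, see [laub_loomis_rates()].
#' @param cfg an [ode_run_config()]; `t_end` is the width of the sampled
#'   window (minutes), `x0_range` the initial-concentration range (uM).
#' @param transient minutes discarded before sampling starts.
#' @return An [expression_series_set()].
#' @export
generate_camp_dataset <- function(k = laub_loomis_rates(),
                                  cfg = ode_run_config(t_end = 7.2,
                                                       n_points = 10L,
                                                       step = 0.01,
                                                       x0_range = c(0.2, 1.2),
                                                       replicates = 5L),
                                  transient = 15) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  deriv <- function(x) laub_loomis_derivatives(x, k)
  want <- seq(transient, transient + cfg$t_end, length.out = cfg$n_points)
  grid <- if (transient > 0) c(0, want) else want
  series <- vector("list", cfg$replicates)
  for (m in seq_len(cfg$replicates)) {
    x0 <- stats::runif(7L, cfg$x0_range[1], cfg$x0_range[2])
    states <- integrate_at(deriv, x0, grid, cfg$step)
    if (transient > 0) states <- states[-1L, , drop = FALSE]
    series[[m]] <- states
  }
  times <- seq(0, cfg$t_end, length.out = cfg$n_points)
  normalize_series(expression_series_set(series, times, camp_components()))
}

#' Gold-standard wiring of the cAMP oscillator
#'
#' The 17 regulatory influences of the oscillator as a signed edge list:
#' 10 cross-component links (CAR1->ACA, PKA-|ACA, cAMPi->PKA, CAR1->ERK2,
#' PKA-|ERK2, ERK2-|RegA, ACA->cAMPi, RegA-|cAMPi, ACA->cAMPe, cAMPe->CAR1)
#' plus one self-decay per component.
#'
#' @return A `gold_standard` object, see [gold_standard()].
#' @export
camp_gold_standard <- function() {
  genes <- camp_components()
  edges <- rbind(
    data.frame(regulator = c("CAR1", "PKA", "cAMPi", "CAR1", "PKA", "ERK2",
                             "ACA", "RegA", "ACA", "cAMPe"),
               target = c("ACA", "ACA", "PKA", "ERK2", "ERK2", "RegA",
                          "cAMPi", "cAMPi", "cAMPe", "CAR1"),
               sign = c(1, -1, 1, 1, -1, -1, 1, -1, 1, 1)),
    data.frame(regulator = genes, target = genes, sign = -1)
  )
  gold_standard(edges, gene_names = genes)
}
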