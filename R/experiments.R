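#' Polarity retention through division in a three-cell chain
#'
#' A minimal in-silico experiment for the bond-memory mechanism: three cells
#' in a row receive fixed, graded Ds supply rates, so the middle cell's
#' Dachs points toward its low-Ds neighbor. The middle cell is then divided
#' along the chain axis, creating a bond-free daughter-daughter interface.
#' Because both daughters keep expressing at the same rates and bonds
#' replenish within a few dissociation times, both daughters should recover
#' the pre-division Dachs direction once their new interfaces pass the
#' grace period.
#'
#' @param seed RNG seed.
#' @param ds_rates Ds supply rates (proteins/min) for the three cells, low
#'   to high along the chain.
#' @param n_equil Equilibration steps before the division.
#' @param recovery_window Steps allowed for recovery; defaults to
#'   `3 / k_dissoc` minutes, a few bond-replenishment time constants.
#' @param grace_period Interface maturity requirement in steps.
#' @return A list: `recovered` (both daughters realigned within the
#'   window), `steps_to_recover`, `pre_direction_x` (middle cell's Dachs x
#'   component before division, negative = toward the low-Ds end).
#' @export
chain_division_experiment <- function(seed = 1L, ds_rates = c(2, 20, 60),
                                      n_equil = 150L,
                                      recovery_window = NULL,
                                      grace_period = 30L) {
  stopifnot(length(ds_rates) == 3)
  scen <- build_scenario(scenario_config(
    "wildtype",
    overrides = list(
      morphogen = list(mode = "none"),
      fj = list(mode = "uniform", uniform_level = 1),
      growth = list(G0 = 1e-6, r_div = 10, r_max = 10),
      adjacency = list(grace_period = as.integer(grace_period))
    )))
  scen$polarity_start <- 0L
  if (is.null(recovery_window)) {
    recovery_window <- ceiling(3 / scen$kinetics$k_dissoc)
  }

  set.seed(as.integer(seed))
  spacing <- 3.4
  disc <- .new_wing_disc(x = spacing * (0:2), y = rep(0, 3), r = rep(1.7, 3))
  disc <- attach_scenario(disc, scen)
  disc$ds_rate_override <- ds_rates
  disc <- rebuild_graph(disc)
  disc$established[] <- -grace_period  # the chain pre-exists the experiment

  for (k in seq_len(n_equil)) disc <- sim_step(disc)
  pre_dx <- disc$dachs_dx[2]
  pre_mag <- disc$dachs_mag[2]

  disc <- divide_cell(disc, 2L, orientation_mode = "axis", angle = 0)
  d1 <- 2L; d2 <- 4L
  steps_to_recover <- NA_integer_
  for (k in seq_len(recovery_window)) {
    disc <- sim_step(disc)
    ok <- function(i) {
      !is.na(disc$dachs_dx[i]) && disc$dachs_mag[i] > 0.05 &&
        disc$dachs_dx[i] * pre_dx > 0.7
    }
    if (ok(d1) && ok(d2)) {
      steps_to_recover <- k
      break
    }
  }
  list(recovered = !is.na(steps_to_recover),
       steps_to_recover = steps_to_recover,
       pre_direction_x = pre_dx, pre_magnitude = pre_mag)
}
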