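#' Genotypes known to the simulator
#'
#' @return Character vector of genotype names.
#' @export
genotype_names <- function() {
  c("wildtype", "ft_null", "ds_null", "ft_ds_null", "fj_null",
    "uniform_fj", "uniform_ds", "uniform_fj_ds",
    "ft_no_icd", "ft_no_ecd", "no_morphogen", "uniform_morphogen")
}

#' Scenario configuration
#'
#' Names a genotype, the Ds front mode, an optional clone, and parameter
#' overrides. [build_scenario()] maps this deterministically onto module
#' parameters.
#'
#' @param genotype One of [genotype_names()].
#' @param front_mode `"moving"` or `"stationary"` Ds front.
#' @param clone Optional [clone_spec()].
#' @param overrides Named list of parameter overrides; allowed names are
#'   `morphogen`, `fj`, `ds`, `kinetics`, `growth`, `mech`, `adjacency`
#'   (each a list of arguments passed to the respective constructor).
#' @return A list of class `fatds_scenario_config`.
#' @export
scenario_config <- function(genotype = "wildtype",
                            front_mode = c("moving", "stationary"),
                            clone = NULL, overrides = list()) {
  front_mode <- match.arg(front_mode)
  if (!genotype %in% genotype_names()) {
    abort(sprintf("Unknown genotype '%s'. See genotype_names().", genotype))
  }
  bad <- setdiff(names(overrides),
                 c("morphogen", "fj", "ds", "kinetics", "growth", "mech",
                   "adjacency"))
  if (length(bad)) {
    abort(sprintf("Unknown override group(s): %s.", paste(bad, collapse = ", ")))
  }
  structure(list(genotype = genotype, front_mode = front_mode, clone = clone,
                 overrides = overrides),
            class = "fatds_scenario_config")
}

#' Concentric clone specification
#'
#' Clones are circular and concentric with the disc: at `induction_step`,
#' every cell within `radius_fraction` of the disc radius is labeled and
#' receives the kind-specific override, heritable by its daughters.
#'
#' @param kind `"ds_overexpress"` (clone cells express 200 Ds/min),
#'   `"fj_overexpress"` (uniform Fj at roughly 10x the wild-type central
#'   level), or `"morphogen_elevated"` (uniformly high morphogen inside).
#' @param induction_step Step at which the clone is induced.
#' @param radius_fraction Clone radius as a fraction of the disc radius.
#' @param override_level Optional explicit level/rate; kind-specific default
#'   when `NULL`.
#' @return A list of class `fatds_clone_spec`.
#' @export
clone_spec <- function(kind = c("ds_overexpress", "fj_overexpress",
                                "morphogen_elevated"),
                       induction_step = 100L, radius_fraction = 0.4,
                       override_level = NULL) {
  kind <- match.arg(kind)
  stopifnot(radius_fraction > 0, radius_fraction <= 1, induction_step >= 0)
  structure(list(kind = kind, induction_step = as.integer(induction_step),
                 radius_fraction = radius_fraction,
                 override_level = override_level),
            class = "fatds_clone_spec")
}

#' Run schedule
#'
#' @param n_steps Number of simulation steps (2880 one-minute steps spans
#'   the roughly 48-hour third instar).
#' @param dt Minutes per step.
#' @param seed Base RNG seed; replicate seeds are derived deterministically.
#' @param record_start First step at which polarity is computed and
#'   snapshots recorded (default 100).
#' @param record_every Snapshot cadence in steps (default 10).
#' @param n_replicates Number of replicate runs.
#' @param n_cells Starting population (default 1000).
#' @param target_radius Initial disc radius, um (default 40).
#' @return A list of class `fatds_run_config`.
#' @export
run_config <- function(n_steps = 2880L, dt = 1, seed = 1L,
                       record_start = 100L, record_every = 10L,
                       n_replicates = 1L, n_cells = 1000L,
                       target_radius = 40) {
  stopifnot(n_steps >= 1, dt > 0, record_every >= 1, n_replicates >= 1)
  structure(list(n_steps = as.integer(n_steps), dt = dt,
                 seed = as.integer(seed),
                 record_start = as.integer(record_start),
                 record_every = as.integer(record_every),
                 n_replicates = as.integer(n_replicates),
                 n_cells = as.integer(n_cells),
                 target_radius = target_radius),
            class = "fatds_run_config")
}

.apply_overrides <- function(ctor, defaults, override) {
  do.call(ctor, utils::modifyList(defaults, override %||% list()))
}

#' Assemble module parameters for a scenario
#'
#' Deterministically maps a genotype and front mode onto the morphogen
#' field, Fj profile, Ds rule, kinetic, growth, mechanics and adjacency
#' parameters, plus behavior flags (`ft_null`, `ds_null`, `ft_no_icd`,
#' `ft_no_ecd`). Discs lacking Ft or Ds never form bonds and are treated as
#' maximally asymmetric; `fj_null` discs never phosphorylate.
#'
#' @param config A [scenario_config()].
#' @return A list of class `fatds_scenario` with the per-module parameters.
#' @export
build_scenario <- function(config = scenario_config()) {
  stopifnot(inherits(config, "fatds_scenario_config"))
  ov <- config$overrides
  g <- config$genotype

  morph_args <- list()
  fj_args <- list()
  ds_args <- list(front_mode = config$front_mode)
  kin_args <- list()
  flags <- list(ft_null = FALSE, ds_null = FALSE, ft_no_icd = FALSE,
                ft_no_ecd = FALSE)

  if (g %in% c("ft_null", "ft_ds_null")) {
    flags$ft_null <- TRUE
    kin_args$ft_rate <- 0
  }
  if (g %in% c("ds_null", "ft_ds_null")) {
    flags$ds_null <- TRUE
    ds_args$rate_high <- 0
    ds_args$rate_low <- 0
  }
  if (g == "fj_null") fj_args$mode <- "absent"
  if (g %in% c("uniform_fj", "uniform_fj_ds")) fj_args$mode <- "uniform"
  if (g %in% c("uniform_ds", "uniform_fj_ds")) {
    ds_args$uniform_rate <- ds_expression_rule()$rate_high
  }
  if (g == "ft_no_icd") flags$ft_no_icd <- TRUE
  if (g == "ft_no_ecd") flags$ft_no_ecd <- TRUE
  if (g == "no_morphogen") morph_args$mode <- "none"
  if (g == "uniform_morphogen") morph_args$mode <- "uniform"

  scen <- list(
    config = config,
    flags = flags,
    morphogen = .apply_overrides(morphogen_field, morph_args, ov$morphogen),
    fj = .apply_overrides(fj_profile, fj_args, ov$fj),
    ds_rule = .apply_overrides(ds_expression_rule, ds_args, ov$ds),
    kinetics = .apply_overrides(kinetic_params, kin_args, ov$kinetics),
    growth = .apply_overrides(growth_params, list(), ov$growth),
    mech = .apply_overrides(mech_params, list(), ov$mech),
    adjacency = utils::modifyList(list(cutoff_factor = 1.5,
                                       grace_period = 30L),
                                  ov$adjacency %||% list()),
    polarity_start = 100L
  )
  structure(scen, class = "fatds_scenario")
}

#' Induce a concentric clone
#'
#' Labels every cell within `radius_fraction * R` of the disc centroid as
#' clone tissue and activates the clone's override for field evaluation.
#' Labels are heritable: daughters of clone cells are clone cells.
#'
#' @param disc A `wing_disc`.
#' @param clone A [clone_spec()].
#' @param step Induction step (must match `clone$induction_step` when run
#'   through the scheduler).
#' @return The disc with `clone` labels and the override active.
#' @export
apply_clone <- function(disc, clone, step = disc$step) {
  stopifnot(inherits(disc, "wing_disc"), inherits(clone, "fatds_clone_spec"))
  R <- disc_radius(disc)
  rr <- .radial_distance(disc$x, disc$y)
  disc$clone <- rr <= clone$radius_fraction * R
  disc$clone_active <- clone
  disc
}

# Clone override levels, resolved lazily against the wild-type profiles.
.clone_level <- function(clone, scen, R) {
  if (!is.null(clone$override_level)) return(clone$override_level)
  switch(clone$kind,
    ds_overexpress = 200,
    fj_overexpress = 10 * fj_level_at(0, 0, R, fj_profile()),
    morphogen_elevated = scen$morphogen$C0 * exp(1))
}
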