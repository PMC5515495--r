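# Per-step orchestration. The step order is a fixed contract:
#  (1) field evaluation, (2) expression + phosphorylation, (3) bond
#  dissolution, (4) free degradation, (5) dephosphorylation, (6) partition +
#  bond formation, (7) polarity over mature neighbors (from the polarity
#  start time), (8) adaptation, (9) growth, (10) division, (11) mechanics,
#  (12) adjacency rebuild + prune.

#' Attach a scenario to a disc and initialize signaling state
#'
#' Sets module parameters from the scenario and seeds the protein pools at
#' their expression/degradation steady state: Ds (and its phosphorylated
#' share) follows the local expression rate at time zero, Ft is uniform
#' across the disc.
#'
#' @param disc A `wing_disc` (e.g., from [init_disc()]).
#' @param scenario A [build_scenario()] result.
#' @return The disc, ready for [sim_step()].
#' @export
attach_scenario <- function(disc, scenario = build_scenario()) {
  stopifnot(inherits(disc, "wing_disc"), inherits(scenario, "fatds_scenario"))
  disc$scenario <- scenario
  disc$params$mech <- scenario$mech
  disc$params$adjacency <- scenario$adjacency
  n <- .n_cells(disc)
  R <- disc_radius(disc)
  rr <- .radial_distance(disc$x, disc$y)
  kin <- scenario$kinetics

  fj <- fj_level_at(rr, 0, R, scenario$fj)
  p_phos <- fj / (fj + kin$phos_K)

  ds_mean <- if (isTRUE(scenario$flags$ds_null)) rep(0, n) else {
    ds_rate_at(rr, 0, R, scenario$morphogen, scenario$ds_rule) /
      max(kin$k_deg_ds, 1e-6)
  }
  ft_mean <- if (isTRUE(scenario$flags$ft_null)) rep(0, n) else {
    rep(kin$ft_rate / max(kin$k_deg_ft, 1e-6), n)
  }
  ds0 <- rpois(n, ds_mean)
  ft0 <- rpois(n, ft_mean)
  ds_p0 <- rbinom(n, ds0, p_phos)
  ft_p0 <- rbinom(n, ft0, p_phos)
  disc$ds_u <- as.numeric(ds0 - ds_p0); disc$ds_p <- as.numeric(ds_p0)
  disc$ft_u <- as.numeric(ft0 - ft_p0); disc$ft_p <- as.numeric(ft_p0)
  disc
}

# Stage 1: evaluate morphogen, Fj, and the Ds expression rate per cell,
# honoring genotype modes and an active clone override.
.evaluate_fields <- function(disc) {
  scen <- disc$scenario
  t <- disc$step * disc$dt
  R <- disc_radius(disc)
  rr <- .radial_distance(disc$x, disc$y)
  M <- morphogen_at(rr, t, R, scen$morphogen)
  fj <- fj_level_at(rr, t, R, scen$fj)
  ds <- if (isTRUE(scen$flags$ds_null)) rep(0, length(rr)) else {
    ds_rate_at(rr, t, R, scen$morphogen, scen$ds_rule)
  }
  # Fixed per-cell supply (clone-free micro-experiments, e.g., the chain).
  if (!is.null(disc$ds_rate_override)) ds <- disc$ds_rate_override
  cl <- disc$clone_active
  if (!is.null(cl) && any(disc$clone)) {
    lvl <- .clone_level(cl, scen, R)
    idx <- disc$clone
    if (cl$kind == "ds_overexpress") ds[idx] <- lvl
    if (cl$kind == "fj_overexpress") fj[idx] <- lvl
    if (cl$kind == "morphogen_elevated") M[idx] <- lvl
  }
  list(M = M, fj = fj, ds_rate = ds, R = R, r = rr)
}

# Stage 6: partition free pools evenly over interfaces and form bonds at
# every interface in both orientations, vectorized over all half-edges.
.bind_all_interfaces <- function(disc) {
  e <- disc$edges
  E <- nrow(e)
  n <- .n_cells(disc)
  if (E == 0L || isTRUE(disc$scenario$flags$ft_no_ecd)) return(disc)
  owner <- c(e[, 1], e[, 2])
  deg <- .group_count(owner, n)

  # Even integer split of each pool across the owner's half-edges, with the
  # remainder going to uniformly random interfaces.
  ord <- order(owner, runif(length(owner)))
  o_sorted <- owner[ord]
  pos <- sequence(rle(o_sorted)$lengths)
  split_pool <- function(pool) {
    pool <- as.integer(round(pool))
    base <- pool %/% pmax(deg, 1L)
    rem <- pool %% pmax(deg, 1L)
    alloc <- base[owner]
    gets <- pos <= rem[o_sorted]
    alloc[ord[gets]] <- alloc[ord[gets]] + 1L
    alloc
  }
  a_fu <- split_pool(disc$ft_u); a_fp <- split_pool(disc$ft_p)
  a_du <- split_pool(disc$ds_u); a_dp <- split_pool(disc$ds_p)

  h1 <- seq_len(E); h2 <- E + h1   # half-edge of e[,1] / e[,2]
  w <- disc$scenario$kinetics$w
  form_dir <- function(fu, fp, du, dp) {
    FT <- fu + fp; DS <- du + dp
    K <- pmin(FT, DS)
    fp_in <- rhyper(E, fp, fu, K)
    dp_in <- rhyper(E, dp, du, K)
    pp_att <- rhyper(E, dp_in, K - dp_in, fp_in)
    att <- cbind(uu = K - fp_in - (dp_in - pp_att),
                 up = dp_in - pp_att,
                 pu = fp_in - pp_att,
                 pp = pp_att)
    new <- matrix(rbinom(length(att), as.integer(att),
                         rep(w[colnames(att)], each = E)),
                  E, 4, dimnames = list(NULL, colnames(att)))
    new
  }
  # Direction a -> b: Ft allocated by a, Ds allocated by b.
  new_ij <- form_dir(a_fu[h1], a_fp[h1], a_du[h2], a_dp[h2])
  new_ji <- form_dir(a_fu[h2], a_fp[h2], a_du[h1], a_dp[h1])
  disc$bonds_ij <- disc$bonds_ij + new_ij
  disc$bonds_ji <- disc$bonds_ji + new_ji

  a <- e[, 1]; b <- e[, 2]
  disc$ft_u <- disc$ft_u - .group_sum(c(new_ij[, "uu"] + new_ij[, "up"],
                                        new_ji[, "uu"] + new_ji[, "up"]),
                                      c(a, b), n)
  disc$ft_p <- disc$ft_p - .group_sum(c(new_ij[, "pu"] + new_ij[, "pp"],
                                        new_ji[, "pu"] + new_ji[, "pp"]),
                                      c(a, b), n)
  disc$ds_u <- disc$ds_u - .group_sum(c(new_ij[, "uu"] + new_ij[, "pu"],
                                        new_ji[, "uu"] + new_ji[, "pu"]),
                                      c(b, a), n)
  disc$ds_p <- disc$ds_p - .group_sum(c(new_ij[, "up"] + new_ij[, "pp"],
                                        new_ji[, "up"] + new_ji[, "pp"]),
                                      c(b, a), n)
  disc
}

# Bound protein owned by each cell (Ft it contributed, Ds it contributed).
.bound_totals <- function(disc) {
  n <- .n_cells(disc)
  if (nrow(disc$edges) == 0L) return(list(ft = numeric(n), ds = numeric(n)))
  a <- disc$edges[, 1]; b <- disc$edges[, 2]
  t_ij <- rowSums(disc$bonds_ij); t_ji <- rowSums(disc$bonds_ji)
  list(ft = .group_sum(c(t_ij, t_ji), c(a, b), n),
       ds = .group_sum(c(t_ji, t_ij), c(a, b), n))
}

#' Advance a disc by one simulation step
#'
#' Applies the full per-step contract (fields, expression, bond kinetics,
#' polarity, adaptation, growth, division, mechanics, adjacency rebuild) and
#' increments the step counter. Per-step production/degradation diagnostics
#' are stored in `disc$diag`.
#'
#' @param disc A `wing_disc` with an attached scenario.
#' @return The advanced disc.
#' @export
sim_step <- function(disc) {
  stopifnot(inherits(disc, "wing_disc"))
  scen <- disc$scenario
  if (is.null(scen)) abort("Attach a scenario first (see attach_scenario()).")
  kin <- scen$kinetics
  gp <- scen$growth
  dt <- disc$dt
  n0 <- .n_cells(disc)

  # (1) fields
  f <- .evaluate_fields(disc)

  # (2) expression + phosphorylation of new protein
  pools <- list(ft_u = disc$ft_u, ft_p = disc$ft_p,
                ds_u = disc$ds_u, ds_p = disc$ds_p)
  fj_eff <- if (scen$fj$mode == "absent") rep(0, n0) else f$fj
  pools <- express_proteins(pools, fj_eff, f$ds_rate, kin, dt)
  produced_ft <- attr(pools, "produced_ft")
  produced_ds <- attr(pools, "produced_ds")

  # (3) bond dissolution (both orientations), released protein back to owners
  if (nrow(disc$edges) > 0L) {
    a <- disc$edges[, 1]; b <- disc$edges[, 2]
    n <- n0
    dis_ij <- dissolve_bonds(disc$bonds_ij, kin$k_dissoc, dt)
    dis_ji <- dissolve_bonds(disc$bonds_ji, kin$k_dissoc, dt)
    disc$bonds_ij <- dis_ij$bonds
    disc$bonds_ji <- dis_ji$bonds
    rel_ij <- dis_ij$released; rel_ji <- dis_ji$released
    pools$ft_u <- pools$ft_u +
      .group_sum(c(rel_ij[, "uu"] + rel_ij[, "up"],
                   rel_ji[, "uu"] + rel_ji[, "up"]), c(a, b), n)
    pools$ft_p <- pools$ft_p +
      .group_sum(c(rel_ij[, "pu"] + rel_ij[, "pp"],
                   rel_ji[, "pu"] + rel_ji[, "pp"]), c(a, b), n)
    pools$ds_u <- pools$ds_u +
      .group_sum(c(rel_ij[, "uu"] + rel_ij[, "pu"],
                   rel_ji[, "uu"] + rel_ji[, "pu"]), c(b, a), n)
    pools$ds_p <- pools$ds_p +
      .group_sum(c(rel_ij[, "up"] + rel_ij[, "pp"],
                   rel_ji[, "up"] + rel_ji[, "pp"]), c(b, a), n)
  }

  # (4) free degradation, (5) dephosphorylation
  pools <- degrade_free(pools, kin$k_deg_ft, kin$k_deg_ds, dt)
  degraded_ft <- attr(pools, "degraded_ft")
  degraded_ds <- attr(pools, "degraded_ds")
  pools <- dephosphorylate(pools, kin$k_dephos, dt)
  disc$ft_u <- pools$ft_u; disc$ft_p <- pools$ft_p
  disc$ds_u <- pools$ds_u; disc$ds_p <- pools$ds_p

  # (6) partition + bond formation
  disc <- .bind_all_interfaces(disc)

  # (7) polarity over mature neighbors, from the polarity start time on
  t_min <- disc$step * dt
  if (t_min >= scen$polarity_start) {
    pol <- .asymmetries_all(disc, disc$step, scen$adjacency$grace_period,
                            count_bonds = !isTRUE(scen$flags$ft_no_icd))
    disc$x_ft <- pol$x_ft
    disc$x_ds <- pol$x_ds
    has_dir <- !is.na(pol$min_ft_partner) & pol$n_mature > 0L
    dx <- disc$x[pol$min_ft_partner[has_dir]] - disc$x[has_dir]
    dy <- disc$y[pol$min_ft_partner[has_dir]] - disc$y[has_dir]
    nv <- pmax(sqrt(dx^2 + dy^2), 1e-12)
    disc$dachs_dx[] <- NA_real_; disc$dachs_dy[] <- NA_real_
    disc$dachs_dx[has_dir] <- dx / nv
    disc$dachs_dy[has_dir] <- dy / nv
    disc$dachs_mag <- ifelse(pol$n_mature > 0L, pol$x_ft, 0)
  }

  # (8) adaptation (integral feedback; shapes growth only)
  raw_m <- f$M / (f$M + gp$K_M)
  am <- adapt(raw_m, disc$y_m, gp$tau_adapt, dt)
  aft <- adapt(disc$x_ft, disc$y_ft, gp$tau_adapt, dt)
  ads <- adapt(disc$x_ds, disc$y_ds, gp$tau_adapt, dt)
  disc$y_m <- am$y; disc$y_ft <- aft$y; disc$y_ds <- ads$y
  disc$x_m_ad <- am$x; disc$x_ft_ad <- aft$x; disc$x_ds_ad <- ads$x

  # (9) growth
  free_load <- disc$ds_u + disc$ds_p
  if (!isTRUE(scen$flags$ft_no_icd)) free_load <- free_load + disc$ft_u + disc$ft_p
  U <- gp$u_scale * free_load
  ratio <- growth_ratio(disc$x_m_ad, disc$x_ft_ad, disc$x_ds_ad, U, gp, dt)
  disc$r <- pmin(disc$r * ratio, gp$r_max)

  # (10) division
  p_div <- division_probability(disc$r, gp, dt)
  dividers <- which(runif(n0) < p_div)
  for (cid in dividers) disc <- divide_cell(disc, cid)

  # (11) mechanics, (12) adjacency rebuild
  disc <- integrate_motion(disc)
  disc$step <- disc$step + 1L
  disc <- rebuild_graph(disc)

  disc$diag <- list(produced_ft = produced_ft, produced_ds = produced_ds,
                    degraded_ft = degraded_ft, degraded_ds = degraded_ds,
                    divided = dividers, n_before = n0)
  disc
}

.init_run_state <- function(config, scenario) {
  disc <- init_disc(config$n_cells, config$target_radius, seed = config$seed,
                    params = scenario$mech)
  disc$dt <- config$dt
  attach_scenario(disc, scenario)
}

.run_loop <- function(disc, config) {
  if (!is.null(disc$rng_state)) {
    assign(".Random.seed", disc$rng_state, envir = globalenv())
    disc$rng_state <- NULL
  }
  scen <- disc$scenario
  snapshots <- list()
  summaries <- list()
  record <- function(d) {
    key <- as.character(d$step)
    snapshots[[key]] <<- tidy(d)
    summaries[[key]] <<- glance(d)
  }
  clone <- scen$config$clone
  if (!is.null(clone) && clone$induction_step >= config$n_steps) {
    abort("Clone induction scheduled after the end of the run.")
  }
  while (disc$step < config$n_steps) {
    if (!is.null(clone) && disc$step == clone$induction_step) {
      disc <- apply_clone(disc, clone)
    }
    disc <- sim_step(disc)
    s <- disc$step
    if (s >= config$record_start &&
        (s - config$record_start) %% config$record_every == 0L) {
      record(disc)
    }
  }
  if (!as.character(disc$step) %in% names(snapshots)) record(disc)
  structure(list(config = config, scenario = scen, seed = config$seed,
                 snapshots = snapshots,
                 summary = dplyr::bind_rows(summaries),
                 final = disc),
            class = "disc_run")
}

#' Run a scenario
#'
#' Builds the initial disc, runs `n_steps` of the per-step contract, and
#' records per-cell snapshots from `record_start` on at the configured
#' cadence (plus the final state). With `n_replicates > 1`, replicate seeds
#' are derived deterministically from the base seed and a list of runs
#' (class `disc_run_set`) is returned.
#'
#' @param config A [run_config()].
#' @param scenario A [build_scenario()] result (or a [scenario_config()],
#'   which is built automatically).
#' @return A `disc_run` (or `disc_run_set`): snapshots, a summary tibble,
#'   and the final `wing_disc`.
#' @export
run_scenario <- function(config = run_config(), scenario = build_scenario()) {
  if (inherits(scenario, "fatds_scenario_config")) {
    scenario <- build_scenario(scenario)
  }
  stopifnot(inherits(config, "fatds_run_config"),
            inherits(scenario, "fatds_scenario"))
  if (config$n_replicates > 1L) {
    runs <- lapply(seq_len(config$n_replicates), function(i) {
      cfg_i <- config
      cfg_i$seed <- as.integer(config$seed + 7919L * (i - 1L))
      cfg_i$n_replicates <- 1L
      run_scenario(cfg_i, scenario)
    })
    return(structure(runs, class = "disc_run_set"))
  }
  disc <- .init_run_state(config, scenario)
  .run_loop(disc, config)
}

#' Resume a run from a saved disc state
#'
#' Continues stepping a disc (e.g., read back by [read_snapshot()]) up to
#' `config$n_steps`, restoring the saved RNG state so the continuation is
#' identical to an uninterrupted run.
#'
#' @param disc A `wing_disc` with attached scenario (and optionally a saved
#'   RNG state).
#' @param config A [run_config()]; only steps beyond `disc$step` are run.
#' @return A `disc_run` covering the continued portion.
#' @export
resume_run <- function(disc, config) {
  stopifnot(inherits(disc, "wing_disc"))
  if (disc$step >= config$n_steps) {
    abort("Disc is already at or beyond the requested number of steps.")
  }
  .run_loop(disc, config)
}

#' @export
print.disc_run <- function(x, ...) {
  cat(sprintf("<disc_run> %s | %d steps | %d snapshots | final cells: %d\n",
              x$scenario$config$genotype, x$config$n_steps,
              length(x$snapshots), .n_cells(x$final)))
  invisible(x)
}

#' @export
print.disc_run_set <- function(x, ...) {
  cat(sprintf("<disc_run_set> %d replicates of %s\n", length(x),
              x[[1]]$scenario$config$genotype))
  invisible(x)
}
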