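#' Adjusted minimum fraction of a bond-count distribution
#'
#' The evenness statistic behind Dachs polarization and the growth boost:
#' the smallest per-neighbor bond count divided by the total, multiplied by
#' the number of neighbors. 1 means perfectly even bonds; 0 means at least
#' one neighbor shares no bonds. An empty list or an all-zero total also
#' returns 0, so a cell with no bonds at all is regarded as maximally
#' asymmetric (this convention drives the overgrowth of ft-/ds- mutants).
#'
#' @param counts Non-negative per-neighbor bond counts.
#' @return A number in `[0, 1]`.
#' @examples
#' adjusted_min_fraction(c(1, 2, 2, 2, 2, 3))  # 6/12 = 0.5
#' adjusted_min_fraction(c(2, 2, 2, 2, 2, 2))  # 1
#' adjusted_min_fraction(c(0, 2, 2, 2, 3, 3))  # 0
#' @export
adjusted_min_fraction <- function(counts) {
  if (length(counts) == 0L) return(0)
  if (any(counts < 0)) abort("Bond counts must be non-negative.")
  total <- sum(counts)
  if (total == 0) return(0)
  length(counts) * min(counts) / total
}

# Vectorized asymmetry over all cells: per-half-edge bound counts grouped by
# owner, restricted to mature interfaces. Returns x = 1 - adjusted minimum
# fraction with the conventions: no mature neighbors -> x = 0 (and no Dachs);
# mature neighbors but zero bonds -> x = 1.
.asymmetries_all <- function(disc, step = disc$step, grace = NULL,
                             count_bonds = TRUE) {
  if (is.null(grace)) grace <- disc$params$adjacency$grace_period
  n <- .n_cells(disc)
  e <- disc$edges
  mature <- (step - disc$established) >= grace
  rows <- which(mature)
  out <- list(x_ft = numeric(n), x_ds = numeric(n),
              n_mature = integer(n),
              min_ft_partner = rep(NA_integer_, n))
  if (length(rows) == 0L) return(out)
  a <- e[rows, 1]; b <- e[rows, 2]
  t_ij <- rowSums(disc$bonds_ij[rows, , drop = FALSE])  # Ft from a, Ds from b
  t_ji <- rowSums(disc$bonds_ji[rows, , drop = FALSE])  # Ft from b, Ds from a
  if (!count_bonds) { t_ij <- t_ij * 0; t_ji <- t_ji * 0 }
  owner <- c(a, b)
  partner <- c(b, a)
  bound_ft <- c(t_ij, t_ji)
  bound_ds <- c(t_ji, t_ij)
  k <- .group_count(owner, n)
  tot_ft <- .group_sum(bound_ft, owner, n)
  tot_ds <- .group_sum(bound_ds, owner, n)
  min_ft <- .group_min(bound_ft, owner, n)
  min_ds <- .group_min(bound_ds, owner, n)

  has <- k > 0L
  amf_ft <- numeric(n); amf_ds <- numeric(n)
  pos_ft <- has & tot_ft > 0
  pos_ds <- has & tot_ds > 0
  amf_ft[pos_ft] <- k[pos_ft] * min_ft[pos_ft] / tot_ft[pos_ft]
  amf_ds[pos_ds] <- k[pos_ds] * min_ds[pos_ds] / tot_ds[pos_ds]
  x_ft <- numeric(n); x_ds <- numeric(n)
  x_ft[has] <- 1 - amf_ft[has]
  x_ds[has] <- 1 - amf_ds[has]
  out$x_ft <- x_ft
  out$x_ds <- x_ds
  out$n_mature <- k

  # Partner with the least bound Ft, random tie-break (seeded RNG).
  pri <- runif(length(owner))
  ord <- order(owner, bound_ft, pri)
  first <- !duplicated(owner[ord])
  out$min_ft_partner[owner[ord][first]] <- partner[ord][first]
  out
}

#' Bond asymmetries of every cell
#'
#' Asymmetry is one minus the adjusted minimum fraction of the per-neighbor
#' bound-Ft (and bound-Ds) counts, computed over *mature* neighbors only
#' (interfaces older than the grace period). A cell with mature neighbors but
#' no bonds scores 1; a cell with no mature neighbors scores 0 and carries no
#' Dachs.
#'
#' @param disc A `wing_disc`.
#' @param step,grace_period Override the assessment step or grace period.
#' @return A tibble `id`, `x_ft`, `x_ds`, `n_mature`.
#' @export
bond_asymmetries <- function(disc, step = NULL, grace_period = NULL) {
  stopifnot(inherits(disc, "wing_disc"))
  if (is.null(step)) step <- disc$step
  no_icd <- isTRUE(disc$scenario$flags$ft_no_icd)
  res <- .asymmetries_all(disc, step, grace_period, count_bonds = !no_icd)
  tibble::tibble(id = disc$id, x_ft = res$x_ft, x_ds = res$x_ds,
                 n_mature = res$n_mature)
}

#' Dachs polarization vector of a single cell
#'
#' Dachs localizes to the side of the cell with the least bound Ft: the
#' direction is the unit vector from the cell center toward the mature
#' neighbor sharing the fewest bound Ft (ties broken by a seeded random
#' draw), and the magnitude is the cell's bound-Ft asymmetry. With no mature
#' neighbors the cell is unpolarized (magnitude 0, direction undefined).
#'
#' @param center Cell center, length-2 numeric.
#' @param neighbor_positions Matrix of mature-neighbor positions (rows).
#' @param bound_ft Bound-Ft counts shared with each neighbor.
#' @return List with `direction` (unit 2-vector or `NULL`) and `magnitude`.
#' @export
dachs_vector <- function(center, neighbor_positions, bound_ft) {
  k <- length(bound_ft)
  if (k == 0L) return(list(direction = NULL, magnitude = 0))
  neighbor_positions <- matrix(neighbor_positions, ncol = 2)
  mag <- 1 - adjusted_min_fraction(bound_ft)
  candidates <- which(bound_ft == min(bound_ft))
  pick <- if (length(candidates) > 1L) sample(candidates, 1L) else candidates
  v <- neighbor_positions[pick, ] - center
  nv <- sqrt(sum(v^2))
  list(direction = if (nv > 0) v / nv else c(NA_real_, NA_real_),
       magnitude = mag)
}

#' Integral-feedback adaptation of a growth signal
#'
#' A first-order internal integrator tracks the running level of the raw
#' signal (`y <- y + (raw - y) * dt / tau`); the adapted signal is the
#' positive part of the excess, `max(0, raw - y)`. A constant input is fully
#' adapted away with time constant `tau`; a sudden step passes through
#' immediately. Adaptation shapes only the growth rate, never the bond
#' asymmetries themselves.
#'
#' @param raw Raw signal in `[0, 1]` (vectorized).
#' @param y Integrator state (same length).
#' @param tau_adapt Adaptation time constant, minutes.
#' @param dt Minutes per step.
#' @return List with `x` (adapted signal) and `y` (updated integrator).
#' @export
adapt <- function(raw, y, tau_adapt, dt = 1) {
  if (tau_adapt <= 0) abort("`tau_adapt` must be positive.")
  y <- y + (raw - y) * dt / tau_adapt
  list(x = pmax(0, raw - y), y = y)
}

#' Growth and division parameters
#'
#' Defaults are calibrated so that an average wild-type cell divides roughly
#' every 8 hours under the default signaling parameters: base growth `G0`
#' scaled up by morphogen and bond-asymmetry gains (each `C * x < 1`) and
#' penalized by the free-protein load `U`.
#'
#' @param G0 Base radial growth rate per minute.
#' @param C_M,C_Ft,C_Ds Dimensionless gains on adapted morphogen and
#'   asymmetry signals.
#' @param K_M Morphogen normalization for `x_M = M / (M + K_M)` (a.u.).
#' @param u_scale Free-protein penalty per molecule: `U = u_scale * (free Ft
#'   + free Ds)`.
#' @param tau_adapt Adaptation time constant, minutes.
#' @param r_div Division-threshold radius, um.
#' @param div_steepness Logistic width of the division threshold, um; small
#'   values make division nearly deterministic in size yet asynchronous in
#'   time.
#' @param r_birth Newborn radius, um (`r_div / sqrt(2)` conserves area).
#' @param r_max Hard cap on cell radius, um.
#' @return A list of class `fatds_growth`.
#' @export
growth_params <- function(G0 = 6.5e-4, C_M = 0.9, C_Ft = 0.9, C_Ds = 0.9,
                          K_M = 1, u_scale = 5e-4, tau_adapt = 300,
                          r_div = 1.9, div_steepness = 0.05,
                          r_birth = 1.34, r_max = 2.2) {
  stopifnot(G0 > 0, tau_adapt > 0, r_div > 0, div_steepness > 0)
  structure(list(G0 = G0, C_M = C_M, C_Ft = C_Ft, C_Ds = C_Ds, K_M = K_M,
                 u_scale = u_scale, tau_adapt = tau_adapt, r_div = r_div,
                 div_steepness = div_steepness, r_birth = r_birth,
                 r_max = r_max),
            class = "fatds_growth")
}

#' Per-step radius growth ratio
#'
#' `r_n / r_{n-1} = 1 + G0 (1 + C_Ft x_ft)(1 + C_Ds x_ds)(1 + C_M x_m) /
#' (1 + U)`. Always at least 1: cells cannot shrink. With all signals and
#' penalties zero the radius grows at the small base rate `G0`.
#'
#' @param x_m,x_ft,x_ds Adapted signals in `[0, 1]` (vectorized).
#' @param U Free-protein penalty, `>= 0`.
#' @param params [growth_params()].
#' @param dt Minutes per step (the base rate is per minute).
#' @return Growth ratio `>= 1`.
#' @export
growth_ratio <- function(x_m, x_ft, x_ds, U, params = growth_params(),
                         dt = 1) {
  if (any(U < 0)) abort("`U` must be non-negative.")
  1 + params$G0 * dt *
    (1 + params$C_Ft * x_ft) * (1 + params$C_Ds * x_ds) *
    (1 + params$C_M * x_m) / (1 + U)
}

#' Probability that a cell divides this step
#'
#' Rises sharply (logistically) as the radius approaches the division
#' threshold; rescaled exactly for non-unit time steps.
#'
#' @param radius Cell radius, um (vectorized).
#' @param params [growth_params()].
#' @param dt Minutes per step.
#' @return Probability in `[0, 1]`.
#' @export
division_probability <- function(radius, params = growth_params(), dt = 1) {
  if (any(radius <= 0)) abort("`radius` must be positive.")
  p1 <- plogis((radius - params$r_div) / params$div_steepness)
  1 - (1 - p1)^dt
}

#' Divide a cell
#'
#' Replaces the mother with two daughters of radius `mother / sqrt(2)` (area
#' conserved), placed symmetrically about the mother's center along the
#' division axis. Free pools split binomially per phosphorylation state;
#' each former interface's bonds go to whichever daughter keeps that
#' neighbor (split binomially when shared); the new daughter-daughter
#' interface starts bond-free with `established_step` set to now. Total
#' protein and total bonds are conserved exactly.
#'
#' @param disc A `wing_disc`.
#' @param cell_id Index of the dividing cell.
#' @param orientation_mode `"random"` (uniform axis; the orientation of
#'   divisions has little effect on outcomes), `"radial"`, `"tangential"`,
#'   or `"axis"` (use `angle`).
#' @param angle Division axis in radians for `orientation_mode = "axis"`.
#' @return The disc with one more cell.
#' @export
divide_cell <- function(disc, cell_id,
                        orientation_mode = c("random", "radial", "tangential",
                                             "axis"),
                        angle = 0) {
  stopifnot(inherits(disc, "wing_disc"))
  orientation_mode <- match.arg(orientation_mode)
  if (!cell_id %in% disc$id) abort(sprintf("Unknown cell id %s.", cell_id))
  center <- .disc_centroid(disc$x, disc$y)
  theta <- switch(orientation_mode,
    random = runif(1, 0, 2 * pi),
    radial = atan2(disc$y[cell_id] - center[2], disc$x[cell_id] - center[1]),
    tangential = atan2(disc$y[cell_id] - center[2],
                       disc$x[cell_id] - center[1]) + pi / 2,
    axis = angle)
  r_m <- disc$r[cell_id]
  off <- 0.5 * r_m
  ux <- cos(theta); uy <- sin(theta)
  x0 <- disc$x[cell_id]; y0 <- disc$y[cell_id]

  new_id <- .n_cells(disc) + 1L
  # Mother becomes the "minus" daughter; the new cell takes the "plus" side.
  disc$x[cell_id] <- x0 - off * ux
  disc$y[cell_id] <- y0 - off * uy
  disc$r[cell_id] <- r_m / sqrt(2)
  disc$x[new_id] <- x0 + off * ux
  disc$y[new_id] <- y0 + off * uy
  disc$r[new_id] <- r_m / sqrt(2)
  disc$id[new_id] <- new_id
  disc$birth_step[new_id] <- disc$step
  disc$mother_id[new_id] <- cell_id
  disc$clone[new_id] <- disc$clone[cell_id]

  for (p in c("ft_u", "ft_p", "ds_u", "ds_p")) {
    total <- as.integer(disc[[p]][cell_id])
    to_new <- rbinom(1, total, 0.5)
    disc[[p]][cell_id] <- total - to_new
    disc[[p]][new_id] <- to_new
  }
  for (p in c("y_m", "y_ft", "y_ds", "x_ft", "x_ds",
              "x_m_ad", "x_ft_ad", "x_ds_ad", "dachs_mag")) {
    disc[[p]][new_id] <- disc[[p]][cell_id]
  }
  disc$dachs_dx[new_id] <- disc$dachs_dx[cell_id]
  disc$dachs_dy[new_id] <- disc$dachs_dy[cell_id]
  if (!is.null(disc$ds_rate_override)) {
    disc$ds_rate_override[new_id] <- disc$ds_rate_override[cell_id]
  }

  update_after_division(disc, cell_id, new_id)
}
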