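# The wing_disc state object: parallel vectors for speed, tibbles on the
# surface (see tidy.wing_disc / glance.wing_disc).

.new_wing_disc <- function(x, y, r, step = 0L, dt = 1) {
  n <- length(x)
  zeros <- numeric(n)
  disc <- list(
    id = seq_len(n),
    x = x, y = y, r = r,
    birth_step = rep(0L, n),
    mother_id = rep(NA_integer_, n),
    clone = rep(FALSE, n),
    ft_u = zeros, ft_p = zeros, ds_u = zeros, ds_p = zeros,
    y_m = zeros, y_ft = zeros, y_ds = zeros,
    x_ft = zeros, x_ds = zeros,
    x_m_ad = zeros, x_ft_ad = zeros, x_ds_ad = zeros,
    dachs_dx = rep(NA_real_, n), dachs_dy = rep(NA_real_, n),
    dachs_mag = zeros,
    step = as.integer(step), dt = dt,
    edges = matrix(integer(0), 0, 2),
    established = integer(0),
    bonds_ij = matrix(0, 0, 4, dimnames = list(NULL, c("uu", "up", "pu", "pp"))),
    bonds_ji = matrix(0, 0, 4, dimnames = list(NULL, c("uu", "up", "pu", "pp"))),
    params = list(mech = mech_params(),
                  adjacency = list(cutoff_factor = 1.5, grace_period = 30L)),
    scenario = NULL,
    diag = NULL
  )
  structure(disc, class = "wing_disc")
}

.n_cells <- function(disc) length(disc$x)

#' @export
print.wing_disc <- function(x, ...) {
  cat(sprintf("<wing_disc> %d cells | step %d (dt = %g min) | R = %.1f um\n",
              .n_cells(x), x$step, x$dt, disc_radius(x)))
  if (!is.null(x$scenario)) {
    cat(sprintf("  genotype: %s | front: %s\n",
                x$scenario$config$genotype, x$scenario$config$front_mode))
  }
  cat(sprintf("  %d neighbor edges | %d Ft-Ds bonds\n",
              nrow(x$edges), round(sum(x$bonds_ij) + sum(x$bonds_ji))))
  invisible(x)
}

#' Tidy a wing disc into a per-cell tibble
#'
#' One row per cell: geometry, lineage, protein pools, adaptation integrators,
#' and the latest polarity readouts. `radial_r` is the distance from the disc
#' centroid.
#'
#' @param x A `wing_disc`.
#' @param ... Unused.
#' @return A tibble with one row per cell.
#' @export
tidy.wing_disc <- function(x, ...) {
  d <- x
  center <- .disc_centroid(d$x, d$y)
  tibble::tibble(
    id = d$id,
    mother_id = d$mother_id,
    x = d$x, y = d$y, radius = d$r,
    radial_r = .radial_distance(d$x, d$y, center),
    birth_step = d$birth_step,
    region = ifelse(d$clone, "clone", "bulk"),
    ft_u = d$ft_u, ft_p = d$ft_p, ds_u = d$ds_u, ds_p = d$ds_p,
    y_m = d$y_m, y_ft = d$y_ft, y_ds = d$y_ds,
    x_ft = d$x_ft, x_ds = d$x_ds,
    x_m_ad = d$x_m_ad, x_ft_ad = d$x_ft_ad, x_ds_ad = d$x_ds_ad,
    dachs_dx = d$dachs_dx, dachs_dy = d$dachs_dy, dachs_mag = d$dachs_mag
  )
}

#' One-row summary of a wing disc
#'
#' @param x A `wing_disc`.
#' @param ... Unused.
#' @return A one-row tibble: step, cell count, disc radius, Ds front radius
#'   (NA when the scenario has no front), mean bond asymmetry and mean Dachs
#'   magnitude.
#' @export
glance.wing_disc <- function(x, ...) {
  front <- NA_real_
  if (!is.null(x$scenario)) {
    front <- tryCatch(
      front_radius(x$step * x$dt, disc_radius(x),
                   x$scenario$morphogen, x$scenario$ds_rule),
      error = function(e) NA_real_)
  }
  tibble::tibble(
    step = x$step,
    n_cells = .n_cells(x),
    disc_radius_um = disc_radius(x),
    front_radius_um = front,
    mean_x_ft = mean(x$x_ft),
    mean_dachs_mag = mean(x$dachs_mag)
  )
}

#' Graph of cell neighbors as a tibble
#'
#' @param disc A `wing_disc`.
#' @return Tibble with columns `cell_a`, `cell_b`, `established_step`.
#' @export
neighbor_graph <- function(disc) {
  stopifnot(inherits(disc, "wing_disc"))
  tibble::tibble(cell_a = disc$edges[, 1], cell_b = disc$edges[, 2],
                 established_step = disc$established)
}

#' Per-interface Ft-Ds bond table
#'
#' Each row is one ordered interface: `cell_i` contributes the Ft, `cell_j`
#' the Ds. Counts are split by phosphorylation type (`n_uu`, `n_up`, `n_pu`,
#' `n_pp`; Ft state first, `u` unphosphorylated, `p` phosphorylated).
#'
#' @param disc A `wing_disc`.
#' @return A tibble with one row per ordered cell pair with any history.
#' @export
bond_table <- function(disc) {
  stopifnot(inherits(disc, "wing_disc"))
  e <- disc$edges
  tibble::tibble(
    cell_i = c(e[, 1], e[, 2]),
    cell_j = c(e[, 2], e[, 1]),
    n_uu = c(disc$bonds_ij[, "uu"], disc$bonds_ji[, "uu"]),
    n_up = c(disc$bonds_ij[, "up"], disc$bonds_ji[, "up"]),
    n_pu = c(disc$bonds_ij[, "pu"], disc$bonds_ji[, "pu"]),
    n_pp = c(disc$bonds_ij[, "pp"], disc$bonds_ji[, "pp"])
  )
}
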