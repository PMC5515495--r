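#' Mechanical interaction parameters
#'
#' Parameters of the pairwise center-to-center force law and of the overdamped
#' position update. Cells repel linearly when their centers are closer than the
#' sum of their radii and attract weakly, with an exponentially decaying tail,
#' when a gap opens between them; the force is zero at contact and at infinity.
#'
#' @param k_rep Repulsion stiffness (acceleration units per unit relative
#'   overlap). Linear in the overlap fraction.
#' @param k_att Attraction amplitude for separated cells.
#' @param lambda Range of the attractive tail, as a fraction of the contact
#'   distance.
#' @param mobility Overdamped mobility: displacement per step is
#'   `mobility * net acceleration * dt`. The default relaxes two
#'   half-overlapping cells to contact within roughly ten one-minute steps.
#' @param cap_factor Per-step displacement cap, as a fraction of the mean cell
#'   radius; guards stability when the time step is lengthened.
#' @return A list of class `fatds_mech_params`.
#' @export
mech_params <- function(k_rep = 1, k_att = 0.4, lambda = 0.5,
                        mobility = 0.4, cap_factor = 0.25) {
  stopifnot(k_rep > 0, k_att >= 0, lambda > 0, mobility > 0, cap_factor > 0)
  structure(list(k_rep = k_rep, k_att = k_att, lambda = lambda,
                 mobility = mobility, cap_factor = cap_factor),
            class = "fatds_mech_params")
}

#' Signed pairwise acceleration between two cells
#'
#' Positive values are repulsive (centers overlap, `d < d_eq`), negative values
#' attractive (`d > d_eq`); the acceleration is zero at contact (`d = d_eq`)
#' and decays to zero at large separation.
#'
#' @param d Center-to-center distance (um). Vectorized.
#' @param d_eq Contact distance, the sum of the two cell radii (um).
#' @param params A [mech_params()] list.
#' @return Signed acceleration, same length as `d`.
#' @examples
#' pairwise_acceleration(2, 2, mech_params())   # touching: zero
#' pairwise_acceleration(1, 2, mech_params())   # overlap: positive
#' pairwise_acceleration(3, 2, mech_params())   # gap: negative
#' @export
pairwise_acceleration <- function(d, d_eq, params = mech_params()) {
  if (any(d_eq <= 0)) abort("`d_eq` must be positive.")
  if (any(d < 0)) abort("`d` must be non-negative.")
  s <- d / d_eq
  out <- numeric(length(s))
  inside <- s < 1
  out[inside] <- params$k_rep * (1 - s[inside])
  g <- s[!inside] - 1
  out[!inside] <- -params$k_att * g * exp(-g / params$lambda)
  out
}

#' Overdamped position update from pairwise forces
#'
#' Displaces every cell by `mobility * net acceleration * dt` along the sum of
#' its pairwise interactions with its graph neighbors, with the per-step
#' displacement capped at `cap_factor` times the mean cell radius. First-order
#' (velocity-free) dynamics: the bulk forces only enforce packing.
#'
#' @param disc A `wing_disc` object.
#' @param graph Optional edge matrix (two integer columns of cell indices);
#'   defaults to the disc's current neighbor graph.
#' @param dt Minutes per step; defaults to the disc's `dt`.
#' @return The disc with updated positions.
#' @export
integrate_motion <- function(disc, graph = NULL, dt = NULL) {
  stopifnot(inherits(disc, "wing_disc"))
  if (is.null(graph)) graph <- disc$edges
  if (is.null(dt)) dt <- disc$dt
  n <- length(disc$x)
  if (n < 2L || nrow(graph) == 0L) return(disc)
  i <- graph[, 1]; j <- graph[, 2]
  dx <- disc$x[j] - disc$x[i]
  dy <- disc$y[j] - disc$y[i]
  d <- sqrt(dx^2 + dy^2)
  d_eq <- disc$r[i] + disc$r[j]
  a <- pairwise_acceleration(d, d_eq, disc$params$mech)
  # Repulsion (a > 0) pushes i away from j; unit vector i -> j is (dx, dy)/d.
  ok <- d > 1e-12
  ux <- ifelse(ok, dx / d, 0)
  uy <- ifelse(ok, dy / d, 0)
  fx <- .group_sum(c(-a * ux, a * ux), c(i, j), n)
  fy <- .group_sum(c(-a * uy, a * uy), c(i, j), n)
  mech <- disc$params$mech
  sx <- mech$mobility * fx * dt
  sy <- mech$mobility * fy * dt
  cap <- mech$cap_factor * mean(disc$r)
  norm <- sqrt(sx^2 + sy^2)
  scale <- ifelse(norm > cap, cap / norm, 1)
  disc$x <- disc$x + sx * scale
  disc$y <- disc$y + sy * scale
  disc
}

#' Disc radius estimate
#'
#' The disc radius `R` is the 99th percentile, over cells, of the distance from
#' the disc centroid to the cell center plus the cell radius. Deterministic,
#' rotation-invariant, and homogeneous of degree one under rescaling.
#'
#' @param disc A `wing_disc`, or a data frame with columns `x`, `y`, `radius`.
#' @return Radius in um.
#' @export
disc_radius <- function(disc) {
  if (inherits(disc, "wing_disc")) {
    x <- disc$x; y <- disc$y; r <- disc$r
  } else {
    stopifnot(all(c("x", "y", "radius") %in% names(disc)))
    x <- disc$x; y <- disc$y; r <- disc$radius
  }
  if (length(x) == 0L) abort("Cannot compute the radius of an empty disc.")
  rd <- .radial_distance(x, y)
  unname(quantile(rd + r, 0.99, names = FALSE, type = 7))
}

# Poisson-disc-like rejection sampling of n points in a circle of radius rad:
# candidates are accepted only if at least `dmin` from all accepted points;
# dmin shrinks geometrically whenever placement stalls.
.sample_packed_positions <- function(n, rad) {
  px <- numeric(n); py <- numeric(n)
  dmin <- 1.7 * rad / sqrt(n)
  placed <- 0L
  stall <- 0L
  while (placed < n) {
    theta <- runif(1, 0, 2 * pi)
    rr <- rad * sqrt(runif(1))
    cx <- rr * cos(theta); cy <- rr * sin(theta)
    if (placed == 0L ||
        min((px[seq_len(placed)] - cx)^2 + (py[seq_len(placed)] - cy)^2) >= dmin^2) {
      placed <- placed + 1L
      px[placed] <- cx; py[placed] <- cy
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall > 500L) {
        dmin <- dmin * 0.95
        stall <- 0L
      }
    }
  }
  cbind(px, py)
}

#' Construct a mechanically relaxed initial disc
#'
#' Places `n_cells` cells by Poisson-disc-like rejection sampling inside a
#' circle, draws radii so that typical cell diameters are 3-4 um, and runs
#' relaxation-only mechanics (with periodic neighbor-graph rebuilds) until the
#' packing settles. Because adjacent cells attract, the relaxed disc is denser
#' in the center than at the periphery, and its overall radius is close to
#' `target_radius`.
#'
#' @param n_cells Number of cells (>= 3 for a meaningful triangulation).
#' @param target_radius Intended disc radius in um (default 40).
#' @param seed RNG seed; identical seeds give identical discs.
#' @param relax_steps Relaxation-only mechanics steps (default 200).
#' @param r_range Range from which initial cell radii are drawn uniformly
#'   (um); defaults to the newborn-to-division-threshold range.
#' @param params Mechanics parameters ([mech_params()]).
#' @return A `wing_disc` object (geometry, neighbor graph, empty protein
#'   pools; signaling state is attached when a scenario is built on top).
#' @export
init_disc <- function(n_cells, target_radius = 40, seed = 1L,
                      relax_steps = 200L, r_range = c(1.3, 1.8),
                      params = mech_params()) {
  if (!is.numeric(n_cells) || n_cells < 1) {
    abort("`n_cells` must be a positive count.")
  }
  if (target_radius <= 0) abort("`target_radius` must be positive.")
  n_cells <- as.integer(n_cells)
  set.seed(as.integer(seed))
  # Placement radius is pre-shrunk: relaxation lets the packing breathe
  # outward, so the relaxed disc lands near the target radius.
  pos <- .sample_packed_positions(n_cells, 0.86 * target_radius)
  r <- runif(n_cells, r_range[1], r_range[2])
  disc <- .new_wing_disc(x = pos[, 1], y = pos[, 2], r = r)
  disc$params$mech <- params
  if (n_cells >= 2L) {
    for (k in seq_len(relax_steps)) {
      if (k %% 10L == 1L) disc <- rebuild_graph(disc)
      disc <- integrate_motion(disc)
    }
    disc <- rebuild_graph(disc)
  }
  disc
}
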