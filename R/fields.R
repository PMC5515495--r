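#' Morphogen field description
#'
#' A radially symmetric, exponentially amplifying morphogen (an abstract
#' superposition of Dpp and Wg). In the wild-type mode the concentration at
#' radial position `r` and time `t` is `C0 * exp(t / t0 - A * r / R)`: it
#' decays with radius with a decay length that scales with the disc radius
#' `R`, while its amplitude grows e-fold every `t0` minutes.
#'
#' @param C0 Initial concentration at the disc center (a.u.).
#' @param A Unitless decay constant relating the profile's decay length to
#'   the disc radius.
#' @param t0 Amplification e-folding time in minutes (default 1200).
#' @param mode `"wildtype"` (graded, amplifying), `"uniform"` (flat at
#'   `uniform_level`), or `"none"` (zero everywhere).
#' @param uniform_level Level used in `"uniform"` mode; defaults to `C0 * e`,
#'   a high, fixed concentration.
#' @return A list of class `fatds_morphogen`.
#' @export
morphogen_field <- function(C0 = 1, A = 2.5, t0 = 1200,
                            mode = c("wildtype", "uniform", "none"),
                            uniform_level = C0 * exp(1)) {
  mode <- match.arg(mode)
  stopifnot(C0 > 0, A > 0, t0 > 0)
  structure(list(C0 = C0, A = A, t0 = t0, mode = mode,
                 uniform_level = uniform_level),
            class = "fatds_morphogen")
}

#' Morphogen concentration at a radial position
#'
#' @param r Radial distance from the disc center (um). Vectorized.
#' @param t Time in minutes.
#' @param R Current disc radius (um), must be positive.
#' @param field A [morphogen_field()].
#' @return Concentration in a.u.
#' @examples
#' f <- morphogen_field()
#' morphogen_at(0, 0, 40, f)          # C0
#' morphogen_at(0, 1200, 40, f)       # C0 * e after one e-folding time
#' @export
morphogen_at <- function(r, t, R, field = morphogen_field()) {
  if (any(R <= 0)) abort("`R` must be positive.")
  if (any(r < 0) || any(t < 0)) abort("`r` and `t` must be non-negative.")
  switch(field$mode,
    wildtype = field$C0 * exp(t / field$t0 - field$A * r / R),
    uniform = rep_len(field$uniform_level, length(r)),
    none = rep_len(0, length(r))
  )
}

#' Four-jointed concentration profile
#'
#' Fj decreases linearly with radial distance: `fj_min + slope * (R - r)`.
#' As the disc grows the central (maximum) level rises but the slope is
#' constant, so the Fj difference between two cells at fixed separation does
#' not change with time. Fj acts catalytically (it sets phosphorylation
#' probabilities) and is treated as a concentration field rather than an
#' expressed pool.
#'
#' @param slope Concentration drop per um (default 2.5e-2, the wild-type
#'   value).
#' @param fj_min Level at the disc edge (default 0.1, the wild-type value).
#' @param mode `"graded"`, `"uniform"`, or `"absent"`.
#' @param uniform_level Level in `"uniform"` mode (default 10, roughly 10x
#'   the wild-type central level).
#' @return A list of class `fatds_fj`.
#' @export
fj_profile <- function(slope = 2.5e-2, fj_min = 0.1,
                       mode = c("graded", "uniform", "absent"),
                       uniform_level = 10) {
  mode <- match.arg(mode)
  stopifnot(slope >= 0, fj_min >= 0, uniform_level >= 0)
  structure(list(slope = slope, fj_min = fj_min, mode = mode,
                 uniform_level = uniform_level),
            class = "fatds_fj")
}

#' Fj level at a radial position
#'
#' @inheritParams morphogen_at
#' @param profile A [fj_profile()].
#' @return Fj level in a.u.
#' @export
fj_level_at <- function(r, t, R, profile = fj_profile()) {
  if (any(R <= 0)) abort("`R` must be positive.")
  switch(profile$mode,
    graded = profile$fj_min + profile$slope * pmax(0, R - r),
    uniform = rep_len(profile$uniform_level, length(r)),
    absent = rep_len(0, length(r))
  )
}

#' Ds expression rule
#'
#' The Ds expression rate is a repressive Hill function of the local morphogen
#' concentration: high (`rate_high`, about 20 proteins per minute) where
#' morphogen is low (the disc periphery), low (`rate_low`) where morphogen is
#' high (the center), with a steep sigmoidal transition region -- the Ds front.
#' The absolute threshold concentration `m_star` is calibrated so that the
#' front starts at radius `front_r0` (8 um) in a disc of radius `front_R0`
#' (40 um) at time zero. In `"stationary"` front mode the inflection is pinned
#' at a fixed relative radius instead of tracking the morphogen.
#'
#' @param rate_high Peripheral (low-morphogen) expression rate, proteins/min.
#' @param rate_low Central (high-morphogen) plateau rate, proteins/min.
#' @param hill_n Hill coefficient; large values give a transition region a
#'   few cells wide.
#' @param front_mode `"moving"` (morphogen-tracked) or `"stationary"`.
#' @param stationary_rel_radius Fixed relative front position (fraction of
#'   the disc radius) used in stationary mode.
#' @param front_r0,front_R0 Calibration anchor for the threshold: the front
#'   radius (um) at time zero in a disc of radius `front_R0`.
#' @param m_star Absolute morphogen threshold; computed from the anchor when
#'   `NULL`.
#' @param uniform_rate When non-`NULL`, Ds is expressed uniformly at this
#'   rate (overexpression genotypes).
#' @return A list of class `fatds_ds_rule`.
#' @export
ds_expression_rule <- function(rate_high = 20, rate_low = 2, hill_n = 8,
                               front_mode = c("moving", "stationary"),
                               stationary_rel_radius = 0.85,
                               front_r0 = 8, front_R0 = 40, m_star = NULL,
                               uniform_rate = NULL) {
  front_mode <- match.arg(front_mode)
  stopifnot(rate_high >= rate_low, rate_low >= 0, hill_n >= 1,
            stationary_rel_radius > 0, stationary_rel_radius <= 1)
  structure(list(rate_high = rate_high, rate_low = rate_low, hill_n = hill_n,
                 front_mode = front_mode,
                 stationary_rel_radius = stationary_rel_radius,
                 front_r0 = front_r0, front_R0 = front_R0, m_star = m_star,
                 uniform_rate = uniform_rate),
            class = "fatds_ds_rule")
}

.ds_m_star <- function(field, rule) {
  rule$m_star %||% (field$C0 * exp(-field$A * rule$front_r0 / rule$front_R0))
}

#' Ds expression rate for cells at a radial position
#'
#' @inheritParams morphogen_at
#' @param field A [morphogen_field()].
#' @param rule A [ds_expression_rule()].
#' @return Expression rate in proteins per minute.
#' @export
ds_rate_at <- function(r, t, R, field = morphogen_field(),
                       rule = ds_expression_rule()) {
  if (any(R <= 0)) abort("`R` must be positive.")
  if (!is.null(rule$uniform_rate)) return(rep_len(rule$uniform_rate, length(r)))
  n <- rule$hill_n
  if (rule$front_mode == "stationary") {
    ratio <- (r / R) / rule$stationary_rel_radius
    h <- ratio^n / (1 + ratio^n)
  } else {
    m <- morphogen_at(r, t, R, field)
    ms <- .ds_m_star(field, rule)
    h <- ms^n / (ms^n + m^n)
  }
  rule$rate_low + (rule$rate_high - rule$rate_low) * h
}

#' Radius of the Ds expression front
#'
#' For a moving front this inverts the morphogen profile at the Ds threshold:
#' `r* = (R / A) * (t / t0 + log(C0 / m_star))`, clipped to `[0, R]`; it moves
#' strictly outward in time at fixed `R`. For a stationary front it is the
#' pinned relative radius times `R`. Uniform or absent morphogen has no front.
#'
#' @inheritParams ds_rate_at
#' @param t Time in minutes.
#' @param R Disc radius in um.
#' @return Front radius in um, or an error when the field has no front.
#' @export
front_radius <- function(t, R, field = morphogen_field(),
                         rule = ds_expression_rule()) {
  if (any(R <= 0)) abort("`R` must be positive.")
  if (rule$front_mode == "stationary") return(rule$stationary_rel_radius * R)
  if (field$mode != "wildtype") {
    abort("No Ds front: morphogen field is not graded (uniform or absent mode).")
  }
  ms <- .ds_m_star(field, rule)
  r_star <- (R / field$A) * (t / field$t0 + log(field$C0 / ms))
  pmin(pmax(r_star, 0), R)
}
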