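#' Radial profile of a per-cell quantity
#'
#' Bins cells into equal-width radial bins from the disc centroid to the
#' disc radius and reports the per-bin mean and standard deviation. Bins
#' with no cells are reported as missing (`NA`), never as zero.
#'
#' @param snapshot A per-cell tibble (e.g., from `tidy()` on a `wing_disc`
#'   or a recorded snapshot) with columns `x`, `y`, `radius`, and the
#'   quantity of interest.
#' @param quantity Name of a numeric column to profile (e.g., `"x_ft"`,
#'   `"dachs_mag"`, `"ds_u"`).
#' @param n_bins Number of radial bins (default 20).
#' @param R Outer radius; defaults to the snapshot's disc radius.
#' @return A tibble `bin`, `r_mid`, `mean`, `sd`, `n`.
#' @export
radial_profile <- function(snapshot, quantity, n_bins = 20, R = NULL) {
  stopifnot(is.data.frame(snapshot))
  num_cols <- names(snapshot)[vapply(snapshot, is.numeric, logical(1))]
  if (!quantity %in% num_cols) {
    abort(sprintf("Unknown quantity '%s'. Numeric columns: %s.",
                  quantity, paste(num_cols, collapse = ", ")))
  }
  if (is.null(R)) R <- disc_radius(snapshot)
  rr <- .radial_distance(snapshot$x, snapshot$y)
  breaks <- seq(0, R, length.out = n_bins + 1)
  bin <- pmin(pmax(findInterval(rr, breaks, rightmost.closed = TRUE), 1L),
              n_bins)
  v <- snapshot[[quantity]]
  out <- tibble::tibble(bin = seq_len(n_bins),
                        r_mid = (breaks[-1] + breaks[-(n_bins + 1)]) / 2)
  agg <- tibble::tibble(bin = bin, v = v) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(mean = mean(.data$v), sd = stats::sd(.data$v),
                     n = dplyr::n(), .groups = "drop")
  out <- dplyr::left_join(out, agg, by = "bin")
  out$n[is.na(out$n)] <- 0L
  out
}

#' Average radial profiles across replicate runs
#'
#' @param profiles A list of tibbles from [radial_profile()] with identical
#'   binning.
#' @return A tibble with the per-bin mean of the replicate means (equal
#'   weights) and the between-replicate sd.
#' @export
aggregate_profiles <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  dplyr::bind_rows(profiles, .id = "replicate") |>
    dplyr::group_by(.data$bin, .data$r_mid) |>
    dplyr::summarise(n_replicates = sum(!is.na(.data$mean)),
                     sd = stats::sd(.data$mean, na.rm = TRUE),
                     mean = mean(.data$mean, na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::select("bin", "r_mid", "mean", "sd", "n_replicates")
}

#' Spatially smoothed Dachs polarization map
#'
#' For each point of a square grid inside the disc, averages the Dachs
#' vectors (direction times magnitude, so antialigned cells cancel) and the
#' scalar magnitudes of all cells within `smoothing_radius`. Grid points
#' with no cells nearby are omitted.
#'
#' @param snapshot Per-cell tibble with `x`, `y`, `dachs_dx`, `dachs_dy`,
#'   `dachs_mag`.
#' @param smoothing_radius Neighborhood radius in um (default 5).
#' @param grid_spacing Grid pitch in um (default 4).
#' @return A tibble of class `fatds_polmap`: `gx`, `gy`, `vx`, `vy`
#'   (vector-mean components), `mean_mag` (scalar mean), `n_cells`.
#' @export
polarization_map <- function(snapshot, smoothing_radius = 5,
                             grid_spacing = 4) {
  stopifnot(smoothing_radius > 0, grid_spacing > 0)
  center <- .disc_centroid(snapshot$x, snapshot$y)
  R <- disc_radius(snapshot)
  gx <- seq(center[1] - R, center[1] + R, by = grid_spacing)
  gy <- seq(center[2] - R, center[2] + R, by = grid_spacing)
  grid <- expand.grid(gx = gx, gy = gy)
  grid <- grid[(grid$gx - center[1])^2 + (grid$gy - center[2])^2 <= R^2, ]
  vx <- ifelse(is.na(snapshot$dachs_dx), 0, snapshot$dachs_dx * snapshot$dachs_mag)
  vy <- ifelse(is.na(snapshot$dachs_dy), 0, snapshot$dachs_dy * snapshot$dachs_mag)
  res <- purrr::pmap_dfr(grid, function(gx, gy) {
    near <- (snapshot$x - gx)^2 + (snapshot$y - gy)^2 <= smoothing_radius^2
    if (!any(near)) return(NULL)
    tibble::tibble(gx = gx, gy = gy,
                   vx = mean(vx[near]), vy = mean(vy[near]),
                   mean_mag = mean(snapshot$dachs_mag[near]),
                   n_cells = sum(near))
  })
  class(res) <- c("fatds_polmap", class(res))
  res
}

#' Mean distal alignment of Dachs polarization
#'
#' The mean cosine of the angle between each cell's Dachs direction and the
#' inward (distal, center-facing) radial direction: +1 when every cell
#' points at the disc center, 0 for isotropic directions, -1 for uniformly
#' outward (proximal) polarization. Cells with zero Dachs magnitude (or no
#' direction) are excluded.
#'
#' @param snapshot Per-cell tibble with `x`, `y`, `dachs_dx`, `dachs_dy`,
#'   `dachs_mag`.
#' @param subset Optional logical vector selecting the region of interest
#'   (e.g., cells inside the front).
#' @return Mean cosine in `[-1, 1]`, or `NA` if the region is empty.
#' @export
distal_alignment <- function(snapshot, subset = NULL) {
  keep <- snapshot$dachs_mag > 0 & !is.na(snapshot$dachs_dx)
  if (!is.null(subset)) keep <- keep & subset
  if (!any(keep)) return(NA_real_)
  center <- .disc_centroid(snapshot$x, snapshot$y)
  ix <- center[1] - snapshot$x[keep]
  iy <- center[2] - snapshot$y[keep]
  nv <- pmax(sqrt(ix^2 + iy^2), 1e-12)
  mean(snapshot$dachs_dx[keep] * ix / nv + snapshot$dachs_dy[keep] * iy / nv)
}

#' Final disc sizes relative to wild-type
#'
#' Summarizes final cell counts per genotype (replicate mean and sd) and
#' their ratio to the wild-type mean. All runs must share the same length.
#'
#' @param records Named list of `disc_run` or `disc_run_set` objects; one
#'   element must be named `"wildtype"`.
#' @return Tibble `genotype`, `mean_cells`, `sd_cells`, `ratio_to_wildtype`.
#' @export
disc_size_comparison <- function(records) {
  stopifnot(is.list(records), "wildtype" %in% names(records))
  counts <- lapply(records, function(rec) {
    runs <- if (inherits(rec, "disc_run_set")) rec else list(rec)
    steps <- vapply(runs, function(r) r$config$n_steps, numeric(1))
    list(n = vapply(runs, function(r) .n_cells(r$final), numeric(1)),
         steps = steps[1])
  })
  steps <- vapply(counts, `[[`, numeric(1), "steps")
  if (length(unique(steps)) != 1L) {
    abort("All records must share the same run length.")
  }
  wt <- mean(counts[["wildtype"]]$n)
  tibble::tibble(
    genotype = names(counts),
    mean_cells = unname(vapply(counts, function(cc) mean(cc$n), numeric(1))),
    sd_cells = unname(vapply(counts, function(cc) stats::sd(cc$n), numeric(1))),
    ratio_to_wildtype = .data$mean_cells / wt
  )
}

#' Radial decomposition of the growth rate
#'
#' Splits the per-cell growth multiplier into its morphogen factor
#' `(1 + C_M x_M)` and its bond-asymmetry factor `(1 + C_Ft x_Ft)(1 + C_Ds
#' x_Ds)`, averaged in radial bins. In a wild-type disc the two patterns are
#' complementary: morphogen dominates the center, asymmetry peaks in the
#' wake of the Ds front.
#'
#' @param snapshot Per-cell tibble with adapted signals `x_m_ad`, `x_ft_ad`,
#'   `x_ds_ad`.
#' @param params [growth_params()] used for the gains.
#' @param n_bins Number of radial bins.
#' @return Tibble `bin`, `r_mid`, `morphogen_factor`, `asymmetry_factor`,
#'   `total_factor`, `n`.
#' @export
growth_decomposition <- function(snapshot, params = growth_params(),
                                 n_bins = 20) {
  m_fac <- 1 + params$C_M * snapshot$x_m_ad
  a_fac <- (1 + params$C_Ft * snapshot$x_ft_ad) *
           (1 + params$C_Ds * snapshot$x_ds_ad)
  tmp <- snapshot
  tmp$m_fac <- m_fac
  tmp$a_fac <- a_fac
  tmp$t_fac <- m_fac * a_fac
  pm <- radial_profile(tmp, "m_fac", n_bins)
  pa <- radial_profile(tmp, "a_fac", n_bins)
  pt <- radial_profile(tmp, "t_fac", n_bins)
  tibble::tibble(bin = pm$bin, r_mid = pm$r_mid,
                 morphogen_factor = pm$mean, asymmetry_factor = pa$mean,
                 total_factor = pt$mean, n = pm$n)
}
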