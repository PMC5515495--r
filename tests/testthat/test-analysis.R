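test_that("radial profiles bin correctly, report empty bins as missing, and name valid quantities", {
  set.seed(51)
  th <- runif(200, 0, 2 * pi); rr <- sqrt(runif(200)) * 10
  snap <- tibble::tibble(x = rr * cos(th), y = rr * sin(th),
                         radius = 0.5, flat = 1, lin = rr)
  p <- radial_profile(snap, "flat", n_bins = 10, R = 10)
  filled <- !is.na(p$mean)
  expect_true(all(p$mean[filled] == 1))
  expect_true(all(p$sd[filled] == 0))
  # a radially symmetric linear field is recovered at the bin centers
  pl <- radial_profile(snap, "lin", n_bins = 10, R = 10)
  ok <- !is.na(pl$mean) & pl$n > 5
  expect_true(all(abs(pl$mean[ok] - pl$r_mid[ok]) < 1))
  # an annulus leaves inner bins missing, not zero
  ring <- dplyr::filter(snap, sqrt(x^2 + y^2) > 6)
  pr <- radial_profile(ring, "flat", n_bins = 10, R = 10)
  expect_true(is.na(pr$mean[2]))
  expect_equal(pr$n[2], 0L)
  expect_error(radial_profile(snap, "nope"), "flat")
})

test_that("replicate profiles aggregate with equal weights", {
  p1 <- tibble::tibble(bin = 1:3, r_mid = c(1, 3, 5), mean = c(1, 2, 3),
                       sd = 0, n = 10L)
  p2 <- tibble::tibble(bin = 1:3, r_mid = c(1, 3, 5), mean = c(3, 4, 5),
                       sd = 0, n = 99L)
  agg <- aggregate_profiles(list(p1, p2))
  expect_equal(agg$mean, c(2, 3, 4))   # unweighted by cell count
  expect_equal(agg$n_replicates, rep(2L, 3))
})

test_that("polarization maps vector-average nearby cells", {
  set.seed(52)
  th <- runif(600, 0, 2 * pi); rr <- sqrt(runif(600)) * 12
  snap <- tibble::tibble(x = rr * cos(th), y = rr * sin(th), radius = 0.5,
                         dachs_dx = -1, dachs_dy = 0, dachs_mag = 0.8)
  pm <- polarization_map(snap, smoothing_radius = 4, grid_spacing = 4)
  expect_true(all(abs(pm$vx + 0.8) < 1e-9))
  expect_true(all(abs(pm$vy) < 1e-9))
  expect_true(all(abs(pm$mean_mag - 0.8) < 1e-9))
  # random directions: vector means cancel while scalar means do not
  phi <- runif(600, 0, 2 * pi)
  rnd <- dplyr::mutate(snap, dachs_dx = cos(phi), dachs_dy = sin(phi))
  pr <- polarization_map(rnd, smoothing_radius = 6, grid_spacing = 6)
  big <- pr$n_cells > 30
  expect_true(mean(sqrt(pr$vx[big]^2 + pr$vy[big]^2)) < 0.25)
  expect_true(all(pr$mean_mag > 0.5))
  # triangle inequality at every grid point
  expect_true(all(sqrt(pr$vx^2 + pr$vy^2) <= pr$mean_mag + 1e-9))
  # grid points with no cells nearby are omitted
  donut <- dplyr::filter(snap, sqrt(x^2 + y^2) > 8)
  pd <- polarization_map(donut, smoothing_radius = 2, grid_spacing = 2)
  expect_false(any(sqrt(pd$gx^2 + pd$gy^2) < 4))
})

test_that("distal alignment is +1 inward, -1 outward, near 0 for isotropic Dachs", {
  set.seed(53)
  th <- runif(800, 0, 2 * pi); rr <- sqrt(runif(800)) * 10 + 0.5
  x <- rr * cos(th); y <- rr * sin(th)
  inward <- tibble::tibble(x = x, y = y, radius = 0.5,
                           dachs_dx = -cos(th), dachs_dy = -sin(th),
                           dachs_mag = 0.5)
  # directions point at the true origin; the sample centroid is near but not
  # exactly there, so alignment is 1 up to the finite-sample offset
  expect_equal(distal_alignment(inward), 1, tolerance = 1e-3)
  outward <- dplyr::mutate(inward, dachs_dx = cos(th), dachs_dy = sin(th))
  expect_equal(distal_alignment(outward), -1, tolerance = 1e-3)
  phi <- runif(800, 0, 2 * pi)
  iso <- dplyr::mutate(inward, dachs_dx = cos(phi), dachs_dy = sin(phi))
  expect_lt(abs(distal_alignment(iso)), 3 / sqrt(2 * 800))  # MC bound
  # rotation invariance
  rot <- function(d, a) dplyr::mutate(d,
    x2 = cos(a) * x - sin(a) * y, y2 = sin(a) * x + cos(a) * y,
    dx2 = cos(a) * dachs_dx - sin(a) * dachs_dy,
    dy2 = sin(a) * dachs_dx + cos(a) * dachs_dy,
    x = x2, y = y2, dachs_dx = dx2, dachs_dy = dy2)
  expect_equal(distal_alignment(rot(iso, 1.1)), distal_alignment(iso),
               tolerance = 1e-9)
  # zero-magnitude cells are excluded; empty regions are missing
  off <- dplyr::mutate(inward, dachs_mag = 0)
  expect_true(is.na(distal_alignment(off)))
  expect_true(is.na(distal_alignment(inward, rep(FALSE, 800))))
})

test_that("growth decomposition multiplies back to the total factor", {
  disc <- make_test_disc(n = 40, R = 8, seed = 55)
  disc$scenario$polarity_start <- 0L
  for (k in 1:40) disc <- sim_step(disc)
  snap <- tidy(disc)
  gd <- growth_decomposition(snap, disc$scenario$growth, n_bins = 6)
  ok <- !is.na(gd$total_factor)
  prod_check <- radial_profile(
    dplyr::mutate(snap, pf = (1 + 0.9 * x_m_ad) * (1 + 0.9 * x_ft_ad) *
                    (1 + 0.9 * x_ds_ad)), "pf", n_bins = 6)
  expect_equal(gd$total_factor[ok], prod_check$mean[ok], tolerance = 1e-9)
  expect_true(all(gd$morphogen_factor[ok] >= 1))
  expect_true(all(gd$asymmetry_factor[ok] >= 1))
})

test_that("disc size comparison reports ratios to wild-type and checks run lengths", {
  cfg <- run_config(n_steps = 110, n_cells = 20, target_radius = 5, seed = 4)
  wt <- run_scenario(cfg, build_scenario(scenario_config("wildtype")))
  cmp <- disc_size_comparison(list(wildtype = wt, again = wt))
  expect_equal(cmp$ratio_to_wildtype, c(1, 1))
  cfg2 <- run_config(n_steps = 120, n_cells = 20, target_radius = 5, seed = 4)
  other <- run_scenario(cfg2, build_scenario(scenario_config("wildtype")))
  expect_error(disc_size_comparison(list(wildtype = wt, other = other)),
               "length")
})

test_that("snapshots round-trip losslessly and fail loudly on damage", {
  disc <- make_test_disc(n = 30, R = 7, seed = 61)
  for (k in 1:20) disc <- sim_step(disc)
  path <- tempfile("snapdir")
  write_snapshot(disc, path)
  back <- read_snapshot(path, disc$scenario)
  for (f in c("x", "y", "r", "ft_u", "ft_p", "ds_u", "ds_p", "y_m", "y_ft",
              "y_ds", "established", "x_ft", "dachs_mag")) {
    expect_equal(back[[f]], disc[[f]], info = f)
  }
  expect_equal(back$edges, disc$edges)
  expect_equal(unname(back$bonds_ij), unname(disc$bonds_ij))
  expect_equal(back$step, disc$step)
  # missing bond table: explicit schema error, not a silent empty state
  file.remove(file.path(path, "bonds.csv"))
  expect_error(read_snapshot(path, disc$scenario), "bonds.csv")
  # schema version mismatch
  path2 <- tempfile("snapdir2")
  write_snapshot(disc, path2)
  meta <- jsonlite::read_json(file.path(path2, "meta.json"),
                              simplifyVector = TRUE)
  meta$schema_version <- 99
  jsonlite::write_json(meta, file.path(path2, "meta.json"), auto_unbox = TRUE)
  expect_error(read_snapshot(path2, disc$scenario), "schema")
  # genotype mismatch between snapshot and supplied scenario
  path3 <- tempfile("snapdir3")
  write_snapshot(disc, path3)
  expect_error(read_snapshot(path3, build_scenario(scenario_config("ft_null"))),
               "genotype")
  unlink(c(path, path2, path3), recursive = TRUE)
})

test_that("run export writes summary, per-snapshot tables, and a resumable final state", {
  cfg <- run_config(n_steps = 112, n_cells = 20, target_radius = 5, seed = 7)
  rr <- run_scenario(cfg, build_scenario(scenario_config("wildtype")))
  out <- tempfile("rundir")
  write_run(rr, out)
  expect_true(file.exists(file.path(out, "summary.csv")))
  expect_true(file.exists(file.path(out, "cells_110.csv")))
  expect_true(file.exists(file.path(out, "final", "cells.csv")))
  smry <- readr::read_csv(file.path(out, "summary.csv"),
                          show_col_types = FALSE)
  expect_equal(nrow(smry), length(rr$snapshots))
  unlink(out, recursive = TRUE)
})

test_that("tidiers and plots produce well-formed objects", {
  cfg <- run_config(n_steps = 110, n_cells = 25, target_radius = 6, seed = 8)
  rr <- run_scenario(cfg, build_scenario(scenario_config("wildtype")))
  expect_s3_class(tidy(rr), "tbl_df")
  g <- glance(rr)
  expect_equal(nrow(g), 1L)
  expect_equal(g$genotype, "wildtype")
  expect_s3_class(autoplot(rr$final), "ggplot")
  expect_s3_class(autoplot(rr), "ggplot")
  pm <- polarization_map(tidy(rr$final))
  expect_s3_class(autoplot(pm), "ggplot")
})
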