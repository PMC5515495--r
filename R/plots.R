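# ggplot2 views of discs, runs, and polarization maps.

#' Plot a wing disc
#'
#' Cells as points colored by a per-cell quantity (Dachs magnitude by
#' default), optionally with Dachs direction arrows.
#'
#' @param object A `wing_disc`.
#' @param color Column of `tidy(object)` to map to color.
#' @param arrows Draw Dachs direction arrows (scaled by magnitude).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.wing_disc <- function(object, color = "dachs_mag", arrows = FALSE,
                               ...) {
  cells <- tidy(object)
  p <- ggplot2::ggplot(cells, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(ggplot2::aes(color = .data[[color]],
                                     size = .data$radius)) +
    ggplot2::scale_size_identity() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)", color = color) +
    ggplot2::theme_minimal()
  if (arrows) {
    seg <- dplyr::filter(cells, !is.na(.data$dachs_dx), .data$dachs_mag > 0)
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(xend = .data$x + 3 * .data$dachs_mag * .data$dachs_dx,
                   yend = .data$y + 3 * .data$dachs_mag * .data$dachs_dy),
      linewidth = 0.3,
      arrow = ggplot2::arrow(length = ggplot2::unit(0.1, "cm")))
  }
  p
}

#' Plot a smoothed polarization map
#'
#' Arrows are the vector-averaged Dachs polarization of nearby cells;
#' the color is the scalar mean magnitude.
#'
#' @param object A `fatds_polmap` from [polarization_map()].
#' @param arrow_scale Arrow length per unit polarization, in um.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fatds_polmap <- function(object, arrow_scale = 4, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$gx, .data$gy)) +
    ggplot2::geom_point(ggplot2::aes(color = .data$mean_mag), size = 2) +
    ggplot2::geom_segment(
      ggplot2::aes(xend = .data$gx + arrow_scale * .data$vx,
                   yend = .data$gy + arrow_scale * .data$vy),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.12, "cm")),
      linewidth = 0.3) +
    ggplot2::scale_color_viridis_c(limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)",
                  color = "mean |Dachs|") +
    ggplot2::theme_minimal()
}

#' Plot the summary series of a run
#'
#' @param object A `disc_run`.
#' @param ... Unused.
#' @return A ggplot of cell count, disc and front radius, and mean
#'   asymmetry over time.
#' @export
autoplot.disc_run <- function(object, ...) {
  long <- tidyr::pivot_longer(object$summary,
                              cols = c("n_cells", "disc_radius_um",
                                       "front_radius_um", "mean_x_ft"),
                              names_to = "series")
  ggplot2::ggplot(long, ggplot2::aes(.data$step, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y") +
    ggplot2::labs(x = "step (min)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Tidy a run record into its summary series
#'
#' @param x A `disc_run`.
#' @param ... Unused.
#' @return The summary tibble (one row per recorded snapshot).
#' @export
tidy.disc_run <- function(x, ...) x$summary

#' One-row summary of a completed run
#'
#' @param x A `disc_run`.
#' @param ... Unused.
#' @return A one-row tibble with the genotype, front mode, run length, and
#'   final cell count, disc radius, and mean Dachs magnitude.
#' @export
glance.disc_run <- function(x, ...) {
  fin <- glance(x$final)
  tibble::tibble(genotype = x$scenario$config$genotype,
                 front_mode = x$scenario$config$front_mode,
                 n_steps = x$config$n_steps, seed = x$seed,
                 n_cells = fin$n_cells,
                 disc_radius_um = fin$disc_radius_um,
                 mean_dachs_mag = fin$mean_dachs_mag)
}
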