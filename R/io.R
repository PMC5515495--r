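# Snapshot reading and writing: one self-contained directory per saved
# state, CSV for the per-cell and per-edge tables, JSON for metadata
# (including the RNG state, so resumed runs continue bit-identically).

.SNAPSHOT_SCHEMA <- 1L

#' Write a resumable disc snapshot
#'
#' Writes `cells.csv`, `edges.csv`, `bonds.csv`, and `meta.json` (schema
#' version, step, dt, scenario configuration, RNG state) into `path`. The
#' snapshot round-trips losslessly through [read_snapshot()].
#'
#' @param disc A `wing_disc`.
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_snapshot <- function(disc, path) {
  stopifnot(inherits(disc, "wing_disc"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  cells <- tibble::tibble(
    id = disc$id, mother_id = disc$mother_id,
    x_um = disc$x, y_um = disc$y, radius_um = disc$r,
    birth_step = disc$birth_step, clone = disc$clone,
    ft_u = disc$ft_u, ft_p = disc$ft_p, ds_u = disc$ds_u, ds_p = disc$ds_p,
    y_m = disc$y_m, y_ft = disc$y_ft, y_ds = disc$y_ds,
    x_ft = disc$x_ft, x_ds = disc$x_ds,
    x_m_ad = disc$x_m_ad, x_ft_ad = disc$x_ft_ad, x_ds_ad = disc$x_ds_ad,
    dachs_dx = disc$dachs_dx, dachs_dy = disc$dachs_dy,
    dachs_mag = disc$dachs_mag)
  readr::write_csv(cells, file.path(path, "cells.csv"), progress = FALSE)
  edges <- tibble::tibble(cell_a = disc$edges[, 1], cell_b = disc$edges[, 2],
                          established_step = disc$established)
  readr::write_csv(edges, file.path(path, "edges.csv"), progress = FALSE)
  bonds <- tibble::tibble(
    cell_a = disc$edges[, 1], cell_b = disc$edges[, 2],
    ij_uu = disc$bonds_ij[, "uu"], ij_up = disc$bonds_ij[, "up"],
    ij_pu = disc$bonds_ij[, "pu"], ij_pp = disc$bonds_ij[, "pp"],
    ji_uu = disc$bonds_ji[, "uu"], ji_up = disc$bonds_ji[, "up"],
    ji_pu = disc$bonds_ji[, "pu"], ji_pp = disc$bonds_ji[, "pp"])
  readr::write_csv(bonds, file.path(path, "bonds.csv"), progress = FALSE)
  meta <- list(
    schema_version = .SNAPSHOT_SCHEMA,
    step = disc$step, dt = disc$dt,
    rng_state = get(".Random.seed", envir = globalenv()),
    genotype = disc$scenario$config$genotype %||% NA,
    front_mode = disc$scenario$config$front_mode %||% NA,
    clone_active = !is.null(disc$clone_active),
    clone = if (!is.null(disc$clone_active)) unclass(disc$clone_active))
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a disc snapshot
#'
#' Rebuilds a `wing_disc` from a directory written by [write_snapshot()].
#' The scenario must be supplied (scenarios are code-backed parameter sets,
#' not data); the genotype recorded in the metadata is checked against it.
#' Missing files or a schema-version mismatch raise explicit errors.
#'
#' @param path Snapshot directory.
#' @param scenario The [build_scenario()] result the snapshot was run with.
#' @return A `wing_disc` ready for [resume_run()].
#' @export
read_snapshot <- function(path, scenario = build_scenario()) {
  need <- c("cells.csv", "edges.csv", "bonds.csv", "meta.json")
  missing <- need[!file.exists(file.path(path, need))]
  if (length(missing)) {
    abort(sprintf("Snapshot at '%s' is missing: %s.", path,
                  paste(missing, collapse = ", ")))
  }
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  if (!identical(as.integer(meta$schema_version), .SNAPSHOT_SCHEMA)) {
    abort(sprintf("Snapshot schema version %s does not match supported %d.",
                  meta$schema_version, .SNAPSHOT_SCHEMA))
  }
  if (inherits(scenario, "fatds_scenario_config")) {
    scenario <- build_scenario(scenario)
  }
  if (!is.na(meta$genotype) &&
      !identical(meta$genotype, scenario$config$genotype)) {
    abort(sprintf("Snapshot genotype '%s' does not match scenario '%s'.",
                  meta$genotype, scenario$config$genotype))
  }
  cells <- readr::read_csv(file.path(path, "cells.csv"),
                           show_col_types = FALSE, progress = FALSE)
  edges <- readr::read_csv(file.path(path, "edges.csv"),
                           show_col_types = FALSE, progress = FALSE)
  bonds <- readr::read_csv(file.path(path, "bonds.csv"),
                           show_col_types = FALSE, progress = FALSE)
  disc <- .new_wing_disc(cells$x_um, cells$y_um, cells$radius_um,
                         step = meta$step, dt = meta$dt)
  disc$mother_id <- cells$mother_id
  disc$birth_step <- as.integer(cells$birth_step)
  disc$clone <- as.logical(cells$clone)
  for (p in c("ft_u", "ft_p", "ds_u", "ds_p", "y_m", "y_ft", "y_ds",
              "x_ft", "x_ds", "x_m_ad", "x_ft_ad", "x_ds_ad",
              "dachs_dx", "dachs_dy", "dachs_mag")) {
    disc[[p]] <- cells[[p]]
  }
  disc$edges <- cbind(edges$cell_a, edges$cell_b, deparse.level = 0)
  disc$established <- as.integer(edges$established_step)
  disc$bonds_ij <- as.matrix(bonds[, c("ij_uu", "ij_up", "ij_pu", "ij_pp")])
  disc$bonds_ji <- as.matrix(bonds[, c("ji_uu", "ji_up", "ji_pu", "ji_pp")])
  colnames(disc$bonds_ij) <- colnames(disc$bonds_ji) <-
    c("uu", "up", "pu", "pp")
  disc$scenario <- scenario
  disc$params$mech <- scenario$mech
  disc$params$adjacency <- scenario$adjacency
  if (isTRUE(meta$clone_active)) {
    disc$clone_active <- structure(meta$clone, class = "fatds_clone_spec")
  }
  disc$rng_state <- as.integer(meta$rng_state)
  disc
}

#' Write the derived tables of a run
#'
#' Writes `summary.csv` plus one `cells_<step>.csv` per recorded snapshot
#' and a `meta.json` with the run configuration, and a full final-state
#' snapshot (resumable) under `final/`.
#'
#' @param record A `disc_run`.
#' @param path Output directory.
#' @return `path`, invisibly.
#' @export
write_run <- function(record, path) {
  stopifnot(inherits(record, "disc_run"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(record$summary, file.path(path, "summary.csv"),
                   progress = FALSE)
  for (step in names(record$snapshots)) {
    readr::write_csv(record$snapshots[[step]],
                     file.path(path, sprintf("cells_%s.csv", step)),
                     progress = FALSE)
  }
  meta <- list(schema_version = .SNAPSHOT_SCHEMA,
               seed = record$seed,
               n_steps = record$config$n_steps, dt = record$config$dt,
               genotype = record$scenario$config$genotype,
               front_mode = record$scenario$config$front_mode)
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  write_snapshot(record$final, file.path(path, "final"))
  invisible(path)
}
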