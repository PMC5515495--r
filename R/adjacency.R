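#' Delaunay edge set of a point cloud
#'
#' Edges of the Delaunay triangulation: every triangle's circumscribed circle
#' contains no other input point. Positions receive a deterministic,
#' index-based jitter of about 1e-9 um before triangulation so that exactly
#' cocircular quadruples are resolved reproducibly. Degenerate inputs return
#' all pairs (two points give one edge, one point none).
#'
#' @param points A two-column matrix or data frame of x/y positions.
#' @return A tibble with integer columns `cell_a`, `cell_b` (`cell_a <
#'   cell_b`), sorted; row indices refer to the input order.
#' @examples
#' pts <- rbind(c(-2, 0), c(2, 0), c(0, 1), c(0, -1))
#' delaunay_edges(pts)  # hull quad plus the short diagonal only
#' @export
delaunay_edges <- function(points) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n <= 1L) {
    return(tibble::tibble(cell_a = integer(0), cell_b = integer(0)))
  }
  if (n <= 3L) {
    idx <- utils::combn(n, 2L)
    return(tibble::tibble(cell_a = idx[1, ], cell_b = idx[2, ]))
  }
  jit <- .tie_jitter(n)
  jx <- points[, 1] + jit[, 1]
  jy <- points[, 2] + jit[, 2]
  e <- delaunay_edges_cpp(jx, jy)
  # Hull edges are always Delaunay but their only interior witness triangle
  # can be displaced by the enclosing super-triangle; union them explicitly.
  h <- grDevices::chull(jx, jy)
  hull <- cbind(h, c(h[-1], h[1]))
  a <- c(e[, 1], pmin(hull[, 1], hull[, 2]))
  b <- c(e[, 2], pmax(hull[, 1], hull[, 2]))
  keep <- !duplicated(.edge_key(a, b))
  ord <- order(a[keep], b[keep])
  tibble::tibble(cell_a = as.integer(a[keep][ord]),
                 cell_b = as.integer(b[keep][ord]))
}

#' Prune triangulation edges that span non-adjacent cells
#'
#' Delaunay edges near the disc hull can connect cells that are not truly
#' adjacent. Edges whose center distance exceeds `cutoff_factor` times the sum
#' of the two cell radii are removed. Edges present in `prev` keep their
#' original establishment step; new edges are stamped with `step`.
#'
#' @param edges A tibble from [delaunay_edges()] (columns `cell_a`, `cell_b`).
#' @param cells A data frame with columns `x`, `y`, `radius`, indexed by cell.
#' @param cutoff_factor Distance cutoff in units of summed radii (default 1.5).
#' @param prev Optional previous graph tibble (with `established_step`) whose
#'   stamps persist for surviving edges.
#' @param step Current step index used to stamp newly created edges.
#' @return A tibble `cell_a`, `cell_b`, `established_step`.
#' @export
prune_edges <- function(edges, cells, cutoff_factor = 1.5, prev = NULL,
                        step = 0L) {
  a <- edges$cell_a; b <- edges$cell_b
  d <- sqrt((cells$x[a] - cells$x[b])^2 + (cells$y[a] - cells$y[b])^2)
  keep <- d <= cutoff_factor * (cells$radius[a] + cells$radius[b])
  out <- tibble::tibble(cell_a = a[keep], cell_b = b[keep],
                        established_step = as.integer(step))
  if (!is.null(prev) && nrow(prev) > 0L) {
    m <- match(.edge_key(out$cell_a, out$cell_b),
               .edge_key(prev$cell_a, prev$cell_b))
    hit <- !is.na(m)
    out$established_step[hit] <- prev$established_step[m[hit]]
  }
  out
}

#' Mature neighbors of a cell
#'
#' Neighbors whose shared interface is at least `grace_period` steps old.
#' Recently created interfaces (e.g., after a division) are excluded from
#' polarity and asymmetry readouts -- Ft-Ds binding itself is *not* gated and
#' proceeds with all pruned neighbors.
#'
#' @param disc A `wing_disc`.
#' @param cell_id Cell index.
#' @param step Step at which maturity is assessed (default: current step).
#' @param grace_period Steps an interface must exist before it counts
#'   (default: the disc's adjacency setting, 30).
#' @return Integer vector of neighbor ids.
#' @export
mature_neighbors <- function(disc, cell_id, step = NULL, grace_period = NULL) {
  stopifnot(inherits(disc, "wing_disc"))
  if (is.null(step)) step <- disc$step
  if (is.null(grace_period)) grace_period <- disc$params$adjacency$grace_period
  if (!cell_id %in% disc$id) abort(sprintf("Unknown cell id %s.", cell_id))
  e <- disc$edges
  inc <- e[, 1] == cell_id | e[, 2] == cell_id
  mature <- inc & (step - disc$established >= grace_period)
  partners <- ifelse(e[mature, 1] == cell_id, e[mature, 2], e[mature, 1])
  as.integer(partners)
}

# Release all bonds on the given edge rows back to the free pools of the
# protein owners (Ft to the contributing cell, Ds to the other), preserving
# phosphorylation state. Used when edges vanish from the graph.
.release_edge_bonds <- function(disc, rows) {
  if (length(rows) == 0L) return(disc)
  a <- disc$edges[rows, 1]; b <- disc$edges[rows, 2]
  bij <- disc$bonds_ij[rows, , drop = FALSE]
  bji <- disc$bonds_ji[rows, , drop = FALSE]
  n <- .n_cells(disc)
  disc$ft_u <- disc$ft_u +
    .group_sum(c(bij[, "uu"] + bij[, "up"], bji[, "uu"] + bji[, "up"]),
               c(a, b), n)
  disc$ft_p <- disc$ft_p +
    .group_sum(c(bij[, "pu"] + bij[, "pp"], bji[, "pu"] + bji[, "pp"]),
               c(a, b), n)
  disc$ds_u <- disc$ds_u +
    .group_sum(c(bij[, "uu"] + bij[, "pu"], bji[, "uu"] + bji[, "pu"]),
               c(b, a), n)
  disc$ds_p <- disc$ds_p +
    .group_sum(c(bij[, "up"] + bij[, "pp"], bji[, "up"] + bji[, "pp"]),
               c(b, a), n)
  disc
}

#' Rebuild the neighbor graph of a disc
#'
#' Re-triangulates all cell positions, prunes over-long edges, preserves the
#' establishment step (and the Ft-Ds bond ledger) of persisting edges, stamps
#' new edges with the current step, and releases the bonds of vanished edges
#' back to the free pools of their owners.
#'
#' @param disc A `wing_disc`.
#' @return The disc with updated `edges`, `established`, and bond matrices.
#' @export
rebuild_graph <- function(disc) {
  stopifnot(inherits(disc, "wing_disc"))
  n <- .n_cells(disc)
  pts <- cbind(disc$x, disc$y)
  de <- delaunay_edges(pts)
  a <- de$cell_a; b <- de$cell_b
  d <- sqrt((disc$x[a] - disc$x[b])^2 + (disc$y[a] - disc$y[b])^2)
  cutoff <- disc$params$adjacency$cutoff_factor
  keep <- d <= cutoff * (disc$r[a] + disc$r[b])
  a <- a[keep]; b <- b[keep]
  new_keys <- .edge_key(a, b)
  old_keys <- if (nrow(disc$edges)) .edge_key(disc$edges[, 1], disc$edges[, 2])
              else numeric(0)
  m <- match(new_keys, old_keys)
  hit <- !is.na(m)

  dropped <- setdiff(seq_along(old_keys), m[hit])
  disc <- .release_edge_bonds(disc, dropped)

  est <- rep(disc$step, length(a))
  bij <- matrix(0, length(a), 4, dimnames = list(NULL, c("uu", "up", "pu", "pp")))
  bji <- bij
  if (any(hit)) {
    est[hit] <- disc$established[m[hit]]
    bij[hit, ] <- disc$bonds_ij[m[hit], , drop = FALSE]
    bji[hit, ] <- disc$bonds_ji[m[hit], , drop = FALSE]
  }
  disc$edges <- cbind(a, b, deparse.level = 0)
  disc$established <- as.integer(est)
  disc$bonds_ij <- bij
  disc$bonds_ji <- bji
  disc
}

#' Repair the neighbor graph locally after a cell division
#'
#' Re-triangulates only the mother, the daughter, and the mother's former
#' neighbors. Former neighbors end up adjacent to the mother, the daughter, or
#' both; spurious new edges between two former neighbors are expunged rather
#' than added to the global graph. The mother-daughter interface is created
#' with `established_step` set to the current step; interfaces the mother
#' retains keep their original stamp, while interfaces acquired by the
#' daughter are new. Bonds follow their interface: retained interfaces keep
#' their ledger, transferred interfaces move wholesale to the daughter, and
#' shared interfaces split each bond independently (binomially) between the
#' two daughter interfaces.
#'
#' @param disc A `wing_disc` whose cell table already contains the daughter.
#' @param mother_id,daughter_id Cell indices.
#' @return The disc with a locally repaired graph and bond ledger.
#' @export
update_after_division <- function(disc, mother_id, daughter_id) {
  stopifnot(inherits(disc, "wing_disc"))
  e <- disc$edges
  inc <- which(e[, 1] == mother_id | e[, 2] == mother_id)
  formers <- ifelse(e[inc, 1] == mother_id, e[inc, 2], e[inc, 1])
  old_est <- disc$established[inc]
  # Bonds on each former interface, oriented so "ft_m" is the mother's Ft.
  bond_m <- vector("list", length(inc))
  bond_f <- vector("list", length(inc))
  for (k in seq_along(inc)) {
    if (e[inc[k], 1] == mother_id) {
      bond_m[[k]] <- disc$bonds_ij[inc[k], ]
      bond_f[[k]] <- disc$bonds_ji[inc[k], ]
    } else {
      bond_m[[k]] <- disc$bonds_ji[inc[k], ]
      bond_f[[k]] <- disc$bonds_ij[inc[k], ]
    }
  }

  local_ids <- c(mother_id, daughter_id, formers)
  pts <- cbind(disc$x[local_ids], disc$y[local_ids])
  le <- delaunay_edges(pts)
  la <- local_ids[le$cell_a]; lb <- local_ids[le$cell_b]
  touches <- la %in% c(mother_id, daughter_id) |
             lb %in% c(mother_id, daughter_id)
  la <- la[touches]; lb <- lb[touches]
  lkey <- .edge_key(la, lb)

  adj_m <- .edge_key(rep(mother_id, length(formers)), formers) %in% lkey
  adj_d <- .edge_key(rep(daughter_id, length(formers)), formers) %in% lkey
  # A former neighbor the local triangulation dropped entirely stays with the
  # mother (conservative: no interface is silently destroyed by division).
  adj_m[!adj_m & !adj_d] <- TRUE

  # Remove the mother's old rows, then append the repaired neighborhood.
  keep_rows <- setdiff(seq_len(nrow(e)), inc)
  new_a <- integer(0); new_b <- integer(0); new_est <- integer(0)
  new_bij <- NULL; new_bji <- NULL
  add_edge <- function(p, q, est, ft_p_side, ft_q_side) {
    # store with smaller index first; bonds_ij holds Ft of the first endpoint
    if (p < q) {
      new_a <<- c(new_a, p); new_b <<- c(new_b, q)
      new_bij <<- rbind(new_bij, ft_p_side); new_bji <<- rbind(new_bji, ft_q_side)
    } else {
      new_a <<- c(new_a, q); new_b <<- c(new_b, p)
      new_bij <<- rbind(new_bij, ft_q_side); new_bji <<- rbind(new_bji, ft_p_side)
    }
    new_est <<- c(new_est, as.integer(est))
  }

  zero4 <- setNames(numeric(4), c("uu", "up", "pu", "pp"))
  for (k in seq_along(formers)) {
    f <- formers[k]
    if (adj_m[k] && adj_d[k]) {
      keep_m <- setNames(rbinom(4, size = as.integer(bond_m[[k]]), prob = 0.5),
                         names(zero4))
      keep_f <- setNames(rbinom(4, size = as.integer(bond_f[[k]]), prob = 0.5),
                         names(zero4))
      add_edge(mother_id, f, old_est[k], keep_m, keep_f)
      add_edge(daughter_id, f, disc$step, bond_m[[k]] - keep_m,
               bond_f[[k]] - keep_f)
    } else if (adj_d[k]) {
      add_edge(daughter_id, f, disc$step, bond_m[[k]], bond_f[[k]])
    } else {
      add_edge(mother_id, f, old_est[k], bond_m[[k]], bond_f[[k]])
    }
  }
  add_edge(mother_id, daughter_id, disc$step, zero4, zero4)

  disc$edges <- rbind(e[keep_rows, , drop = FALSE],
                      cbind(new_a, new_b, deparse.level = 0))
  disc$established <- c(disc$established[keep_rows], new_est)
  colnames(new_bij) <- colnames(new_bji) <- c("uu", "up", "pu", "pp")
  disc$bonds_ij <- rbind(disc$bonds_ij[keep_rows, , drop = FALSE], new_bij)
  disc$bonds_ji <- rbind(disc$bonds_ji[keep_rows, , drop = FALSE], new_bji)
  disc
}
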