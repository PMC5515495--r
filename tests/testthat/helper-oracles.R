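# Brute-force Delaunay oracle: a triangle belongs to the triangulation iff
# its circumcircle contains no other input point. Quadratic-to-cubic in n;
# used only on small point sets.
oracle_delaunay_edges <- function(pts, tol = 1e-12) {
  n <- nrow(pts)
  if (n == 2L) return(matrix(c(1L, 2L), 1))
  edges <- matrix(integer(0), 0, 2)
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    ax <- pts[i, 1]; ay <- pts[i, 2]
    bx <- pts[j, 1]; by <- pts[j, 2]
    cx <- pts[k, 1]; cy <- pts[k, 2]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(d) < 1e-12) next
    a2 <- ax^2 + ay^2; b2 <- bx^2 + by^2; c2 <- cx^2 + cy^2
    ux <- (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d
    uy <- (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d
    r2 <- (ax - ux)^2 + (ay - uy)^2
    others <- setdiff(seq_len(n), c(i, j, k))
    if (all((pts[others, 1] - ux)^2 + (pts[others, 2] - uy)^2 >=
            r2 * (1 - tol))) {
      edges <- rbind(edges, c(i, j), c(i, k), c(j, k))
    }
  }
  unique(t(apply(edges, 1, sort)))
}

edge_keys <- function(a, b) paste(pmin(a, b), pmax(a, b))

# A small disc with a wild-type scenario attached, ready to step.
make_test_disc <- function(n = 40, R = 8, seed = 1, genotype = "wildtype",
                           n_steps_cfg = 200, overrides = list()) {
  cfg <- run_config(n_steps = n_steps_cfg, n_cells = n, target_radius = R,
                    seed = seed)
  scen <- build_scenario(scenario_config(genotype, overrides = overrides))
  disc <- init_disc(cfg$n_cells, cfg$target_radius, seed = cfg$seed,
                    params = scen$mech)
  attach_scenario(disc, scen)
}

# Free + bound protein owned by each cell (Ft it contributed, Ds it
# contributed), used for exact mass-balance audits.
owned_totals <- function(disc) {
  bt <- fatds:::.bound_totals(disc)
  list(ft = disc$ft_u + disc$ft_p + bt$ft,
       ds = disc$ds_u + disc$ds_p + bt$ds)
}
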