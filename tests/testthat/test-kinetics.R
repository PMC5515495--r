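test_that("expression adds Poisson protein with Fj-dependent phosphorylation", {
  kin <- kinetic_params()
  zero <- list(ft_u = numeric(1e4), ft_p = numeric(1e4),
               ds_u = numeric(1e4), ds_p = numeric(1e4))
  set.seed(1)
  # no Fj: nothing phosphorylated
  p0 <- express_proteins(zero, fj_level = rep(0, 1e4),
                         ds_rate = rep(20, 1e4), kin)
  expect_equal(sum(p0$ft_p) + sum(p0$ds_p), 0)
  # Fj at the half-saturation point: half the new protein phosphorylated
  p5 <- express_proteins(zero, fj_level = rep(kin$phos_K, 1e4),
                         ds_rate = rep(20, 1e4), kin)
  n_new <- sum(attr(p5, "produced_ds"))
  frac <- sum(p5$ds_p) / n_new
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / n_new))
  # mean production matches the rate
  expect_lt(abs(mean(attr(p5, "produced_ds")) - 20), 3 * sqrt(20 / 1e4))
  expect_lt(abs(mean(attr(p5, "produced_ft")) - kin$ft_rate),
            3 * sqrt(kin$ft_rate / 1e4))
})

test_that("partition_free splits pools evenly with a random integer remainder", {
  even <- partition_free(c(ft_u = 12, ft_p = 0, ds_u = 0, ds_p = 0), 6)
  expect_equal(unname(even[, "ft_u"]), rep(2L, 6))
  set.seed(2)
  odd <- partition_free(c(ft_u = 13, ft_p = 5, ds_u = 7, ds_p = 0), 6)
  expect_equal(sum(odd[, "ft_u"]), 13)
  expect_setequal(unique(odd[, "ft_u"]), c(2L, 3L))
  expect_equal(sum(odd[, "ft_u"] == 3L), 1L)
  expect_equal(sum(odd[, "ds_u"]), 7)
  expect_true(max(odd[, "ds_u"]) - min(odd[, "ds_u"]) <= 1)
  none <- partition_free(c(ft_u = 9, ft_p = 1, ds_u = 2, ds_p = 0), 0)
  expect_equal(nrow(none), 0L)
  expect_error(partition_free(c(ft_u = 1, ft_p = 1, ds_u = 1, ds_p = 1), -1),
               ">= 0")
})

test_that("bond formation respects capacity and the state-dependent weights", {
  w <- kinetic_params()$w
  # no Ft allocated: no bonds
  none <- form_bonds(c(u = 0, p = 0), c(u = 50, p = 50), w)
  expect_equal(sum(none$bonds), 0)
  expect_equal(none$leftover_ds, c(u = 50, p = 50))
  # single-type interfaces: binomial oracle at the weight
  set.seed(3)
  pu <- replicate(200, form_bonds(c(u = 0, p = 100), c(u = 100, p = 0),
                                  w)$bonds[["pu"]])
  sem <- sqrt(100 * 0.7 * 0.3 / 200)
  expect_lt(abs(mean(pu) - 70), 3 * sem)
  up <- replicate(200, form_bonds(c(u = 100, p = 0), c(u = 0, p = 100),
                                  w)$bonds[["up"]])
  sem2 <- sqrt(100 * 0.05 * 0.95 / 200)
  expect_lt(abs(mean(up) - 5), 3 * sem2)
  # mixed states: per-type bond count is capped by both allocations,
  # and used + leftover reproduces the allocation exactly
  for (i in 1:20) {
    ft <- c(u = sample(0:30, 1), p = sample(0:30, 1))
    ds <- c(u = sample(0:30, 1), p = sample(0:30, 1))
    res <- form_bonds(ft, ds, w)
    b <- res$bonds
    expect_lte(b[["uu"]] + b[["up"]], ft[["u"]])
    expect_lte(b[["pu"]] + b[["pp"]], ft[["p"]])
    expect_lte(b[["uu"]] + b[["pu"]], ds[["u"]])
    expect_lte(b[["up"]] + b[["pp"]], ds[["p"]])
    expect_equal(res$leftover_ft[["u"]] + b[["uu"]] + b[["up"]], ft[["u"]])
    expect_equal(res$leftover_ds[["p"]] + b[["up"]] + b[["pp"]], ds[["p"]])
    expect_true(all(res$leftover_ft >= 0) && all(res$leftover_ds >= 0))
  }
  # deterministic-expectation mode
  det <- form_bonds(c(u = 0, p = 100), c(u = 100, p = 0), w,
                    stochastic = FALSE)
  expect_equal(unname(det$bonds[["pu"]]), 70)
})

test_that("bond dissolution is binomial thinning that conserves protein", {
  b <- matrix(100, 4, 4, dimnames = list(NULL, c("uu", "up", "pu", "pp")))
  set.seed(4)
  reps <- replicate(200, sum(dissolve_bonds(b[1, , drop = FALSE],
                                            0.08)$released))
  p <- 1 - exp(-0.08)
  sem <- sqrt(400 * p * (1 - p) / 200)
  expect_lt(abs(mean(reps) - 400 * p), 3 * sem)
  frozen <- dissolve_bonds(b, 0)
  expect_equal(frozen$bonds, b)
  expect_equal(sum(frozen$released), 0)
  once <- dissolve_bonds(b, 0.08)
  expect_equal(once$bonds + once$released, b)  # conservation per state
  expect_error(dissolve_bonds(b, -1), "non-negative")
})

test_that("degradation thins only free pools and dephosphorylation conserves totals", {
  pools <- list(ft_u = rep(500, 50), ft_p = rep(500, 50),
                ds_u = rep(500, 50), ds_p = rep(500, 50))
  set.seed(5)
  thinned <- degrade_free(pools, 0.08, 0.08)
  p <- 1 - exp(-0.08)
  expect_lt(abs(mean(attr(thinned, "degraded_ds")) - 1000 * p),
            3 * sqrt(1000 * p * (1 - p) / 50))
  all_gone <- degrade_free(pools, 1e9, 1e9)
  expect_equal(sum(all_gone$ft_u) + sum(all_gone$ds_p), 0)
  same <- degrade_free(pools, 0, 0)
  expect_equal(same$ft_u, pools$ft_u)

  deph <- dephosphorylate(list(ft_u = 0, ft_p = 100, ds_u = 0, ds_p = 100),
                          k_dephos = -log(1 - 0.1))  # exact 10% per step
  expect_equal(deph$ft_u + deph$ft_p, 100)
  expect_equal(deph$ds_u + deph$ds_p, 100)
  noop <- dephosphorylate(list(ft_u = 5, ft_p = 0, ds_u = 5, ds_p = 0), 0.5)
  expect_equal(noop$ft_p, 0)
  frozen <- dephosphorylate(list(ft_u = 0, ft_p = 50, ds_u = 0, ds_p = 0), 0)
  expect_equal(frozen$ft_p, 50)
})

test_that("an isolated cell's free pool settles at expression over degradation", {
  kin <- kinetic_params()
  pools <- list(ft_u = 0, ft_p = 0, ds_u = 0, ds_p = 0)
  set.seed(6)
  vals <- numeric(3000)
  for (k in 1:3000) {
    pools <- express_proteins(pools, fj_level = 0, ds_rate = 20, kin)
    pools <- degrade_free(pools, kin$k_deg_ft, kin$k_deg_ds)
    vals[k] <- pools$ds_u
  }
  # birth-death equilibrium, sampled right after the degradation substep:
  # N = rate * (1 - p) / p with p the per-step degradation probability
  p <- 1 - exp(-0.08)
  expected <- 20 * (1 - p) / p
  expect_equal(mean(vals[500:3000]), expected, tolerance = 0.05)
})

test_that("the bond ledger is symmetric between the two cells of an interface", {
  disc <- make_test_disc(n = 40, R = 8, seed = 8)
  for (k in 1:30) disc <- sim_step(disc)
  tb <- bond_table(disc)
  # one shared ledger: each ordered pair appears exactly once, and the count
  # of "Ft of i bound with j" read from the table equals the ledger row, so
  # cell i's bound Ft with j and cell j's bound Ds with i are the same number
  expect_equal(nrow(tb), 2L * nrow(disc$edges))
  expect_false(any(duplicated(paste(tb$cell_i, tb$cell_j))))
  ft_of <- function(i, j) {
    row <- tb$cell_i == i & tb$cell_j == j
    sum(tb$n_uu[row] + tb$n_up[row] + tb$n_pu[row] + tb$n_pp[row])
  }
  for (r in 1:10) {
    expect_equal(ft_of(disc$edges[r, 1], disc$edges[r, 2]),
                 sum(disc$bonds_ij[r, ]))
    expect_equal(ft_of(disc$edges[r, 2], disc$edges[r, 1]),
                 sum(disc$bonds_ji[r, ]))
  }
})

test_that("per-cell mass balance holds exactly through full steps", {
  disc <- make_test_disc(n = 30, R = 7, seed = 10)
  for (k in 1:40) {
    before <- owned_totals(disc)
    n0 <- length(disc$x)
    disc <- sim_step(disc)
    after <- owned_totals(disc)
    d <- disc$diag
    divided <- d$divided
    daughters <- setdiff(seq_along(disc$x), seq_len(n0))
    keep <- setdiff(seq_len(n0), divided)
    expect_equal(after$ft[keep],
                 before$ft[keep] + d$produced_ft[keep] - d$degraded_ft[keep])
    expect_equal(after$ds[keep],
                 before$ds[keep] + d$produced_ds[keep] - d$degraded_ds[keep])
    # dividing lineages conserve protein across mother + daughter
    if (length(divided)) {
      for (i in seq_along(divided)) {
        m <- divided[i]; dd <- daughters[i]
        expect_equal(after$ft[m] + after$ft[dd],
                     before$ft[m] + d$produced_ft[m] - d$degraded_ft[m])
        expect_equal(after$ds[m] + after$ds[dd],
                     before$ds[m] + d$produced_ds[m] - d$degraded_ds[m])
      }
    }
  }
})
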