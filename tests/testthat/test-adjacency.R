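test_that("delaunay_edges matches hand-checked configurations", {
  # Quad where only the short diagonal is Delaunay: the circumcircle of
  # (-2,0),(0,1),(0,-1) has center (-0.75, 0) and radius 1.25, excluding (2,0).
  pts <- rbind(c(-2, 0), c(2, 0), c(0, 1), c(0, -1))
  e <- delaunay_edges(pts)
  k <- edge_keys(e$cell_a, e$cell_b)
  expect_setequal(k, c("1 3", "1 4", "2 3", "2 4", "3 4"))
  expect_false("1 2" %in% k)

  tri <- delaunay_edges(rbind(c(0, 0), c(1, 0), c(0.4, 1)))
  expect_equal(nrow(tri), 3L)

  # one point inside a triangle: 3 hull + 3 spokes
  inner <- delaunay_edges(rbind(c(0, 0), c(4, 0), c(2, 3), c(2, 1)))
  expect_equal(nrow(inner), 6L)
  ok <- oracle_delaunay_edges(rbind(c(0, 0), c(4, 0), c(2, 3), c(2, 1)))
  expect_setequal(edge_keys(inner$cell_a, inner$cell_b),
                  edge_keys(ok[, 1], ok[, 2]))
})

test_that("delaunay_edges handles degenerate inputs as all-pairs", {
  expect_equal(nrow(delaunay_edges(matrix(c(0, 0), 1))), 0L)
  two <- delaunay_edges(rbind(c(0, 0), c(1, 1)))
  expect_equal(nrow(two), 1L)
})

test_that("delaunay_edges agrees with the empty-circumcircle oracle on random sets", {
  set.seed(31)
  for (rep in 1:50) {
    n <- sample(8:12, 1)
    pts <- matrix(runif(2 * n, 0, 10), ncol = 2)
    e <- delaunay_edges(pts)
    ok <- oracle_delaunay_edges(pts)
    expect_setequal(edge_keys(e$cell_a, e$cell_b),
                    edge_keys(ok[, 1], ok[, 2]))
  }
})

test_that("prune_edges drops over-long edges and preserves establishment stamps", {
  cells <- data.frame(x = c(0, 10), y = c(0, 0), radius = c(1.5, 1.5))
  e <- tibble::tibble(cell_a = 1L, cell_b = 2L)
  expect_equal(nrow(prune_edges(e, cells, cutoff_factor = 1.5)), 0L) # 10 > 4.5
  cells$x[2] <- 3.0
  kept <- prune_edges(e, cells, cutoff_factor = 1.5, step = 5L)
  expect_equal(nrow(kept), 1L)            # 3.0 <= 4.5
  expect_equal(kept$established_step, 5L)
  prev <- tibble::tibble(cell_a = 1L, cell_b = 2L, established_step = 2L)
  kept2 <- prune_edges(e, cells, cutoff_factor = 1.5, prev = prev, step = 9L)
  expect_equal(kept2$established_step, 2L)  # persisting pair keeps its stamp
  # pruning never adds edges
  expect_lte(nrow(kept2), nrow(e))
})

test_that("mature_neighbors applies the grace period and errors on unknown cells", {
  disc <- fatds:::.new_wing_disc(x = c(0, 2, 4), y = c(0, 0, 0), r = rep(1, 3))
  disc$edges <- rbind(c(1L, 2L), c(2L, 3L))
  disc$established <- c(100L, 0L)
  disc$bonds_ij <- disc$bonds_ji <-
    matrix(0, 2, 4, dimnames = list(NULL, c("uu", "up", "pu", "pp")))
  expect_equal(mature_neighbors(disc, 2, step = 120, grace_period = 30), 3L)
  expect_setequal(mature_neighbors(disc, 2, step = 140, grace_period = 30),
                  c(1L, 3L))
  expect_setequal(mature_neighbors(disc, 2, step = 500, grace_period = 30),
                  c(1L, 3L))
  expect_error(mature_neighbors(disc, 99), "Unknown cell")
})

test_that("mature neighbors are a subset of pruned neighbors", {
  disc <- make_test_disc(n = 50, R = 9, seed = 4)
  for (k in 1:40) disc <- sim_step(disc)
  all_nb <- function(id) {
    e <- disc$edges
    inc <- e[, 1] == id | e[, 2] == id
    ifelse(e[inc, 1] == id, e[inc, 2], e[inc, 1])
  }
  for (id in c(1L, 10L, 25L)) {
    expect_true(all(mature_neighbors(disc, id) %in% all_nb(id)))
  }
})

test_that("division repair keeps former neighbors and expunges spurious pairs", {
  # a hexagonal neighborhood: mother (1) with six former neighbors
  set.seed(12)
  th <- seq(0, 2 * pi, length.out = 7)[-7]
  disc <- fatds:::.new_wing_disc(x = c(0, 2 * cos(th)), y = c(0, 2 * sin(th)),
                                 r = rep(1, 7))
  disc <- rebuild_graph(disc)
  before_keys <- fatds:::.edge_key(disc$edges[, 1], disc$edges[, 2])
  former <- mature_neighbors(disc, 1, step = 100, grace_period = 0)
  disc$step <- 50L
  disc <- divide_cell(disc, 1L, orientation_mode = "axis", angle = 0.3)
  e <- disc$edges
  keys <- fatds:::.edge_key(e[, 1], e[, 2])
  # every former neighbor is adjacent to mother (1), daughter (8), or both
  for (f in former) {
    expect_true(fatds:::.edge_key(1L, f) %in% keys ||
                fatds:::.edge_key(8L, f) %in% keys)
  }
  # the mother-daughter interface exists and is stamped with the current step
  md <- which(keys == fatds:::.edge_key(1L, 8L))
  expect_length(md, 1L)
  expect_equal(disc$established[md], 50L)
  # no former-neighbor pair gained a new mutual edge
  new_keys <- setdiff(keys, before_keys)
  pair_of_formers <- outer(former, former, function(a, b)
    fatds:::.edge_key(a, b))
  expect_length(intersect(new_keys, pair_of_formers[upper.tri(pair_of_formers)]),
                0L)
})

test_that("division repair handles a single-neighbor mother and is seed-deterministic", {
  mk <- function() {
    d <- fatds:::.new_wing_disc(x = c(0, 2), y = c(0, 0), r = c(1, 1))
    d$edges <- matrix(c(1L, 2L), 1)
    d$established <- 0L
    d$bonds_ij <- d$bonds_ji <-
      matrix(0, 1, 4, dimnames = list(NULL, c("uu", "up", "pu", "pp")))
    d
  }
  set.seed(5)
  d1 <- divide_cell(mk(), 1L)
  set.seed(5)
  d2 <- divide_cell(mk(), 1L)
  expect_identical(d1$edges, d2$edges)
  expect_identical(d1$x, d2$x)
  keys <- fatds:::.edge_key(d1$edges[, 1], d1$edges[, 2])
  expect_true(fatds:::.edge_key(1L, 3L) %in% keys)  # daughter next to mother
  expect_true(fatds:::.edge_key(2L, 1L) %in% keys ||
              fatds:::.edge_key(2L, 3L) %in% keys)  # old neighbor retained
})

test_that("interior cells of a relaxed disc have about six neighbors", {
  disc <- init_disc(500, 28, seed = 2)
  de <- delaunay_edges(cbind(disc$x, disc$y))
  cells <- data.frame(x = disc$x, y = disc$y, radius = disc$r)
  pr <- prune_edges(de, cells)
  n <- length(disc$x)
  full <- tabulate(c(de$cell_a, de$cell_b), nbins = n)
  kept <- tabulate(c(pr$cell_a, pr$cell_b), nbins = n)
  interior <- full == kept
  expect_gt(mean(interior), 0.8)
  expect_equal(mean(kept[interior]), 6, tolerance = 0.1)
})
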