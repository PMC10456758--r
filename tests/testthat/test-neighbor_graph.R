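test_that("three non-collinear points give the complete Voronoi graph", {
  ps <- point_set(cbind(c(0, 1, 0.5), c(0, 0, 1)))
  g <- build_voronoi_graph(ps)
  expect_equal(nrow(g$edges), 3)
  expect_equal(g$degree, rep(2L, 3))
})

test_that("degenerate inputs are rejected with informative errors", {
  expect_error(build_voronoi_graph(point_set(cbind(c(0, 1), c(0, 0)))),
               "at least 3")
  expect_error(build_voronoi_graph(point_set(cbind(0:3, 0:3))), "collinear")
  expect_error(
    build_voronoi_graph(point_set(cbind(c(0, 0, 1), c(0, 0, 1)))),
    "duplicate points at indices 1, 2")
})

test_that("metric graphs follow the closed-radius rule and minimum image", {
  ps <- point_set(cbind(c(0, 1, 2), c(0, 0, 0)))
  g <- build_metric_graph(ps, 1.5)
  expect_equal(edge_key(g$edges), c("1-2", "2-3"))
  expect_equal(nrow(build_metric_graph(ps, 0)$edges), 0)
  # closed comparison: distance exactly equal to the radius is an edge
  expect_equal(edge_key(build_metric_graph(ps, 1)$edges), c("1-2", "2-3"))
  per <- point_set(cbind(c(1, 999), c(0, 0)), "periodic", c(1000, 1000))
  gm <- build_metric_graph(per, 5)
  expect_equal(nrow(gm$edges), 1)
  expect_equal(gm$distance, 2)
  expect_error(build_metric_graph(ps, -1), "non-negative")
})

test_that("periodic hexagonal lattice has uniform degree 6", {
  lat <- hexagonal_lattice(12, 12, spacing = 10)
  g <- build_voronoi_graph(lat)
  expect_equal(g$degree, rep(6L, 144))
  expect_equal(g$distance, rep(10, nrow(g$edges)), tolerance = 1e-12)
})

test_that("periodic Voronoi graphs satisfy the torus handshake 2E = 6N", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(10:40, 1)
    ps <- point_set(cbind(runif(n, 0, 500), runif(n, 0, 500)), "periodic",
                    c(500, 500))
    g <- build_voronoi_graph(ps)
    expect_equal(2 * nrow(g$edges), 6 * n)
  }
})

test_that("Voronoi adjacency matches the brute-force circumcircle oracle", {
  set.seed(42)
  for (rep in 1:12) {
    n <- sample(4:22, 1)
    ps <- rand_open_points(n)
    got <- edge_key(build_voronoi_graph(ps)$edges)
    want <- edge_key(brute_delaunay_edges(ps$coords))
    expect_identical(got, want)
  }
})

test_that("periodic adjacency matches the oracle on the explicit tiling", {
  set.seed(7)
  for (rep in 1:4) {
    n <- sample(4:7, 1)
    ps <- point_set(cbind(runif(n, 0, 100), runif(n, 0, 100)), "periodic",
                    c(100, 100))
    got <- edge_key(build_voronoi_graph(ps)$edges)
    want <- edge_key(brute_periodic_edges(ps$coords, ps$box))
    expect_identical(got, want)
  }
})

test_that("Voronoi adjacency agrees with an independent tessellation library", {
  set.seed(11)
  for (rep in 1:5) {
    n <- 40
    ps <- rand_open_points(n, scale = 50)
    got <- edge_key(build_voronoi_graph(ps)$edges)
    dd <- deldir::deldir(ps$coords[, 1], ps$coords[, 2],
                         rw = c(-500, 550, -500, 550))
    want <- edge_key(as.matrix(dd$delsgs[, c("ind1", "ind2")]))
    expect_identical(got, want)
  }
})

test_that("edge-distance multiset is invariant under translation and shift", {
  set.seed(5)
  ps <- rand_open_points(25)
  d1 <- sort(build_voronoi_graph(ps)$distance)
  shifted <- point_set(sweep(ps$coords, 2, c(123.4, -56.7), "+"))
  expect_equal(sort(build_voronoi_graph(shifted)$distance), d1,
               tolerance = 1e-9)
  per <- point_set(cbind(runif(20, 0, 200), runif(20, 0, 200)), "periodic",
                   c(200, 200))
  d2 <- sort(build_voronoi_graph(per)$distance)
  rolled <- point_set(sweep(per$coords, 2, c(60, 140), "+"), "periodic",
                      per$box)
  expect_equal(sort(build_voronoi_graph(rolled)$distance), d2,
               tolerance = 1e-9)
})

test_that("metric and Voronoi graphs coincide on the hexagonal lattice", {
  lat <- hexagonal_lattice(8, 8, spacing = 10)
  gv <- build_voronoi_graph(lat)
  for (r in c(10.5, 12, 17)) { # between one and sqrt(3) spacings
    gm <- build_metric_graph(lat, r)
    expect_identical(edge_key(gm$edges), edge_key(gv$edges))
  }
})

test_that("neighbor distances follow the per-agent directed convention", {
  lat <- hexagonal_lattice(6, 6, spacing = 7)
  g <- build_voronoi_graph(lat)
  s <- neighbor_distances(lat, g)
  expect_equal(length(s$values), 2 * nrow(g$edges))
  expect_equal(length(s$values), sum(g$degree))
  expect_true(all(abs(s$values - 7) < 1e-9))
  se <- neighbor_distances(lat, g, "per_edge")
  expect_equal(length(se$values), nrow(g$edges))
  # two points within metric range sample both directed incidences
  two <- point_set(cbind(c(0, 3), c(0, 0)))
  gm <- build_metric_graph(two, 5)
  expect_equal(neighbor_distances(two, gm)$values, c(3, 3))
  # size mismatch is a consistency error
  expect_error(neighbor_distances(hexagonal_lattice(4, 4), g),
               "different size")
})
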