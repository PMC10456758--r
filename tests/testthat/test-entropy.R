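test_that("histogram binning is right-open, zero-anchored and conservative", {
  h <- make_histogram(c(1, 1, 2, 2), 1)
  expect_equal(h$counts, c(0, 2, 2)) # 2.0 falls in [2, 3)
  expect_equal(h$breaks, 0:3)
  expect_equal(h$total, 4)
  h1 <- make_histogram(c(0.5), 1)
  expect_equal(h1$counts, 1)
  set.seed(1)
  d <- runif(50, 0, 30)
  expect_equal(length(make_histogram(d, 100)$counts), 1) # w > max distance
  expect_equal(sum(make_histogram(d, 0.7)$counts), 50)
  expect_error(make_histogram(numeric(0), 1), "empty")
  expect_error(make_histogram(d, 0), "positive")
  expect_error(make_histogram(d, -2), "positive")
})

test_that("shannon entropy matches closed forms and the literal oracle", {
  expect_equal(shannon_entropy(make_histogram(rep(2.5, 9), 1)), 0)
  expect_equal(shannon_entropy(make_histogram(c(0.5, 1.5), 1)), 1)
  # counts (1, 1, 2) -> 1.5 bits
  expect_equal(shannon_entropy(make_histogram(c(0.1, 1.1, 2.1, 2.2), 1)), 1.5)
  set.seed(2)
  for (rep in 1:20) {
    d <- runif(sample(5:500, 1), 0, 50)
    h <- make_histogram(d, runif(1, 0.1, 5))
    expect_equal(shannon_entropy(h), entropy_literal(h$counts),
                 tolerance = 1e-12)
    expect_gte(shannon_entropy(h), 0)
    expect_lte(shannon_entropy(h), log2(sum(h$counts > 0)) + 1e-12)
  }
})

test_that("entropy is invariant under label permutation and count duplication", {
  set.seed(3)
  counts <- c(4, 0, 7, 1, 0, 9, 3)
  base <- entropy_literal(counts)
  expect_equal(entropy_literal(sample(counts)), base)
  expect_equal(entropy_literal(counts * 5L), base)
  # per-edge vs per-agent-directed counting: the factor 2 cancels
  lat <- jittered_lattice(hexagonal_lattice(8, 8), 2, seed = 4)
  g <- build_voronoi_graph(lat)
  h_dir <- shannon_entropy(make_histogram(neighbor_distances(lat, g), 0.5))
  h_edge <- shannon_entropy(
    make_histogram(neighbor_distances(lat, g, "per_edge"), 0.5))
  expect_equal(h_dir, h_edge, tolerance = 1e-12)
})

test_that("normalized entropy is 1 for uniform histograms and 1/3 for the split example", {
  for (m in c(2, 5, 16)) {
    for (w in c(0.5, 1, 3)) {
      if (m * w <= 1) next
      d <- (0:(m - 1)) * w + w / 2 # one distance per bin
      expect_equal(normalized_entropy(make_histogram(d, w)), 1,
                   tolerance = 1e-12)
    }
  }
  h <- make_histogram(c(rep(0.5, 8), rep(7.5, 8)), 1)
  expect_equal(normalized_entropy(h), 1 / 3, tolerance = 1e-12)
  expect_error(normalized_entropy(make_histogram(c(0.2, 0.3), 0.25)),
               "rescale")
})

test_that("normalized entropy is stable across bin sizes on a uniform sample", {
  set.seed(9)
  d <- runif(4000, 0, 120)
  hn <- sapply(c(1, 2, 4), function(w)
    normalized_entropy(make_histogram(d, w)))
  expect_lt(max(abs(hn - mean(hn))) / mean(hn), 0.1)
})

test_that("coarsening nested bins never increases entropy", {
  set.seed(8)
  for (rep in 1:10) {
    d <- c(runif(300, 0, 40), rnorm(200, 20, 2))
    d <- d[d >= 0]
    hs <- sapply(c(1, 2, 4, 8), function(w)
      shannon_entropy(make_histogram(d, w)))
    expect_true(all(diff(hs) <= 1e-12))
  }
})

test_that("entropy by neighbor distance composes the full pipeline", {
  lat <- hexagonal_lattice(10, 10, spacing = 10)
  r <- entropy_by_neighbor_distance(lat, 1)
  expect_equal(r$h_ndist, 0)
  expect_equal(r$occupied_bins, 1L)
  expect_equal(r$n_samples, 600) # 100 agents x degree 6
  # two points (metric mode): one distinct distance, zero entropy
  two <- point_set(cbind(c(0, 4), c(0, 0)))
  r2 <- entropy_by_neighbor_distance(two, 1, "metric", metric_radius = 10)
  expect_equal(r2$h_ndist, 0)
  expect_error(entropy_by_neighbor_distance(two, 1, "metric"),
               "metric_radius")
})

test_that("gas is higher-entropy than clusters and sweeps are monotone", {
  gas <- uniform_gas(500, seed = 1)
  cl <- gaussian_clusters(5, 100, 10, seed = 1)
  rg <- entropy_by_neighbor_distance(gas, 1)
  rc <- entropy_by_neighbor_distance(cl, 1)
  expect_gt(rg$h_ndist, rc$h_ndist)
  sw <- bin_size_sweep(gas, c(1, 2, 5, 10, 20))
  expect_true(all(diff(sw$h_ndist) <= 1e-12))
  # a single-distance sample has zero entropy at every width
  lat <- hexagonal_lattice(6, 6, spacing = 10)
  sl <- bin_size_sweep(lat, c(0.5, 1, 2, 5))
  expect_equal(sl$h_ndist, rep(0, 4))
  expect_error(bin_size_sweep(gas, c(1, -1)), "positive")
})
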