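test_that("initial states are seed-deterministic with uniform headings", {
  p <- boid_params(n_boids = 50, seed = 9)
  s1 <- init_state(p)
  s2 <- init_state(p)
  expect_identical(s1, s2)
  expect_true(all(s1$positions[, 1] >= 0 & s1$positions[, 1] < 1000))
  p1 <- boid_params(n_boids = 1, seed = 2)
  expect_equal(nrow(init_state(p1)$positions), 1)
  # circular uniformity: mean resultant length of many headings ~ 0
  pbig <- boid_params(n_boids = 10000, seed = 3)
  sb <- init_state(pbig)
  expect_lt(average_velocity(sb), 3 / sqrt(10000))
})

test_that("rule forces match direct evaluation for a single neighbor pair", {
  p <- boid_params(n_boids = 2, speed = 1, neighbor_mode = "metric",
                   metric_radius = 10, seed = 1)
  st <- structure(list(positions = cbind(c(100, 104), c(50, 50)),
                       headings = c(0, 0), step_index = 0L,
                       box = p$box), class = "boid_state")
  f <- compute_forces(st, params = p)
  d <- 4
  expect_equal(f$f_sep[1, ], c(-1 / d, 0)) # direction (-1, 0), magnitude 1/d
  expect_equal(f$f_alg[1, ], c(0, 0)) # identical headings
  expect_equal(f$f_coh[1, ], c(d, 0)) # toward the neighbor centroid
  # Newton-pair symmetry of the separation rule
  expect_equal(f$f_sep[1, ], -f$f_sep[2, ])
  # separation (-1,0) and cohesion (+1,0) unit vectors cancel
  expect_equal(f$f_total[1, ], c(0, 0))
})

test_that("boids without neighbors feel zero force", {
  p <- boid_params(n_boids = 3, neighbor_mode = "metric", metric_radius = 1,
                   seed = 1)
  st <- structure(list(positions = cbind(c(0, 500, 900), c(0, 500, 100)),
                       headings = c(0, 1, 2), step_index = 0L, box = p$box),
                  class = "boid_state")
  f <- compute_forces(st, params = p)
  expect_equal(f$f_total, matrix(0, 3, 2))
  expect_equal(f$degree, rep(0L, 3))
})

test_that("R reference forces equal the compiled fast path", {
  for (mode in c("voronoi", "metric")) {
    p <- boid_params(n_boids = 40, speed = 3, neighbor_mode = mode,
                     metric_radius = 150, seed = 5)
    st <- init_state(p)
    fr <- compute_forces(st, params = p)
    fc <- swarmentropy:::.boid_forces_cpp(st$positions, boid_velocities(st, 3),
                                          1000, 1000, mode == "metric", 150)
    expect_equal(fr$f_total, fc$f_total, tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(fr$f_sep, fc$f_sep, tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(fr$degree, fc$degree, ignore_attr = TRUE)
  }
})

test_that("zero steering and zero noise give straight-line constant-speed motion", {
  p <- boid_params(n_boids = 20, speed = 2, steering = 0.001, noise = 0,
                   seed = 4)
  p$steering <- 0
  st <- init_state(p)
  st2 <- boid_step(st, p)
  # heading field conserved as directions (atan2 renormalizes to (-pi, pi])
  expect_equal(cos(st2$headings), cos(st$headings), tolerance = 1e-12)
  expect_equal(sin(st2$headings), sin(st$headings), tolerance = 1e-12)
  disp <- st2$positions - st$positions
  disp <- cbind(swarmentropy:::minimum_image(disp[, 1], 1000),
                swarmentropy:::minimum_image(disp[, 2], 1000))
  expect_equal(sqrt(rowSums(disp^2)), rep(2, 20), tolerance = 1e-12)
})

test_that("speed is conserved exactly at every step", {
  p <- boid_params(n_boids = 30, speed = 2.5, steering = 0.1, noise = 3,
                   seed = 6)
  st <- init_state(p)
  for (k in 1:5) {
    st2 <- boid_step(st, p)
    disp <- st2$positions - st$positions
    disp <- cbind(swarmentropy:::minimum_image(disp[, 1], 1000),
                  swarmentropy:::minimum_image(disp[, 2], 1000))
    expect_equal(sqrt(rowSums(disp^2)), rep(2.5, 30), tolerance = 1e-12)
    st <- st2
  }
})

test_that("positions wrap periodically", {
  p <- boid_params(n_boids = 1, speed = 1, steering = 0.1, seed = 1)
  st <- structure(list(positions = cbind(999.5, 10), headings = 0,
                       step_index = 0L, box = p$box), class = "boid_state")
  st2 <- boid_step(st, p)
  expect_equal(unname(st2$positions[1, 1]), 0.5, tolerance = 1e-12)
  expect_equal(unname(st2$positions[1, 2]), 10)
})

test_that("runs are bitwise reproducible and respect the recording cadence", {
  p <- boid_params(n_boids = 25, speed = 4, steering = 0.05, noise = 2,
                   seed = 11)
  t1 <- run_boids(p, n_steps = 200, record_every = 50)
  t2 <- run_boids(p, n_steps = 200, record_every = 50)
  expect_identical(t1$va, t2$va)
  expect_identical(t1$positions, t2$positions)
  t3 <- run_boids(p, n_steps = 120, record_every = 120)
  expect_equal(length(t3$positions), 2) # initial and final frames only
  expect_equal(t3$rec_steps, c(0L, 120L))
})

test_that("a single compiled step equals init plus one R-level step", {
  p <- boid_params(n_boids = 30, speed = 4, steering = 0.1, noise = 1,
                   seed = 13)
  tr <- run_boids(p, n_steps = 1, record_every = 1)
  st <- init_state(p)
  st1 <- boid_step(st, p)
  expect_equal(tr$positions[[2]], st1$positions, tolerance = 1e-14)
  expect_equal(as.numeric(tr$headings[[2]]), st1$headings,
               tolerance = 1e-14)
})

test_that("zero-noise topological runs order toward v_a near 1 at desk scale", {
  p <- boid_params(n_boids = 50, speed = 4, steering = 0.1, noise = 0,
                   seed = 2)
  tr <- run_boids(p, n_steps = 3000, record_every = 1000)
  expect_gt(mean(tail(tr$va, 200)), 0.95)
  expect_gt(mean(tail(tr$va, 200)), mean(head(tr$va, 200)))
})

test_that("parameter validation catches inconsistent settings", {
  expect_warning(boid_params(steering = 0.5), "outside")
  expect_error(boid_params(neighbor_mode = "metric"), "metric_radius")
  expect_error(boid_params(speed = 0))
})
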