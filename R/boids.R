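#' Boid simulation parameters
#'
#' The rule coefficients of the boid model: each boid feels separation,
#' alignment and cohesion forces from its neighbors; the unit-normalized sum
#' is scaled by the steering factor `S` and added to the current velocity,
#' the new heading is the direction of that vector, a uniform angular noise
#' of half-width `eta` (degrees) is added, and the boid moves at constant
#' speed `V` for one time step in a periodic box.
#'
#' @param n_boids number of boids. The boid count is a free parameter of the
#'   model; 200 gives meaningful Voronoi statistics at desk scale.
#' @param box periodic box extents `(Lx, Ly)`; default 1000 x 1000 (pixel
#'   units).
#' @param speed constant speed `V` in length units per step. The default of
#'   4 px/step makes headings relax over a few hundred steps while spatial
#'   structure reorganizes over thousands, so velocity order emerges well
#'   before topological order, as observed in flocking systems.
#' @param steering steering factor `S`; values are tuned in `[0.001, 0.1]`
#'   and a warning is issued outside that range.
#' @param noise noise factor `eta` in degrees: half-width of the uniform
#'   angular perturbation applied per boid per step.
#' @param neighbor_mode `"voronoi"` (topological) or `"metric"`.
#' @param metric_radius interaction radius for metric mode.
#' @param dt step duration.
#' @param seed integer seed; together with the parameters it fully
#'   determines a run.
#' @return An object of class `boid_params`.
#' @export
boid_params <- function(n_boids = 200, box = c(1000, 1000), speed = 4,
                        steering = 0.1, noise = 0,
                        neighbor_mode = c("voronoi", "metric"),
                        metric_radius = NULL, dt = 1, seed = 1L) {
  neighbor_mode <- match.arg(neighbor_mode)
  stopifnot(n_boids >= 1, length(box) == 2, all(box > 0), speed > 0,
            noise >= 0, dt > 0)
  if (steering < 0.001 || steering > 0.1)
    warning("steering factor ", steering,
            " is outside the tuned range [0.001, 0.1]")
  if (neighbor_mode == "metric") {
    if (is.null(metric_radius) || metric_radius < 0)
      stop("metric neighbor mode requires a non-negative `metric_radius`")
  }
  structure(list(n_boids = as.integer(n_boids), box = as.numeric(box),
                 speed = speed, steering = steering, noise = noise,
                 neighbor_mode = neighbor_mode,
                 metric_radius = metric_radius, dt = dt,
                 seed = as.integer(seed)),
            class = "boid_params")
}

#' @export
print.boid_params <- function(x, ...) {
  cat(sprintf("<boid_params> N = %d, box %g x %g, V = %g, S = %g, eta = %g deg, %s neighbors%s, dt = %g, seed = %d\n",
              x$n_boids, x$box[1], x$box[2], x$speed, x$steering, x$noise,
              x$neighbor_mode,
              if (x$neighbor_mode == "metric")
                sprintf(" (R = %g)", x$metric_radius) else "",
              x$dt, x$seed))
  invisible(x)
}

#' Random initial boid state
#'
#' Positions uniform over the box, headings uniform over `[0, 2*pi)`, fully
#' determined by `params$seed` (the R RNG is seeded here; subsequent noise
#' draws continue the same stream).
#'
#' @param params a [boid_params()].
#' @return An object of class `boid_state`: `positions` (`N x 2`),
#'   `headings` (radians), `step_index`, `box`.
#' @export
init_state <- function(params) {
  stopifnot(inherits(params, "boid_params"))
  set.seed(params$seed)
  n <- params$n_boids
  pos <- cbind(runif(n, 0, params$box[1]), runif(n, 0, params$box[2]))
  colnames(pos) <- c("x", "y")
  structure(list(positions = pos, headings = runif(n, 0, 2 * pi),
                 step_index = 0L, box = params$box),
            class = "boid_state")
}

#' @export
print.boid_state <- function(x, ...) {
  cat(sprintf("<boid_state> %d boids at step %d, box %g x %g\n",
              nrow(x$positions), x$step_index, x$box[1], x$box[2]))
  invisible(x)
}

#' Velocity vectors of a boid state
#' @param state a [init_state()] result.
#' @param speed constant speed `V`.
#' @return `N x 2` matrix of velocities.
#' @export
boid_velocities <- function(state, speed) {
  stopifnot(inherits(state, "boid_state"))
  speed * cbind(vx = cos(state$headings), vy = sin(state$headings))
}

#' Rule forces acting on every boid
#'
#' Reference implementation of the three interaction rules over an explicit
#' neighbor graph, in R. For neighbor set `phi_i` with `n_i` members (all
#' displacements minimum-image in the periodic box):
#' separation `F_sep,i = sum_j (r_i - r_j) / r_ij^2`,
#' alignment `F_alg,i = mean_j(v_j) - v_i`,
#' cohesion `F_coh,i = mean_j(r_j) - r_i`.
#' The combined force is the sum of the three terms each normalized to unit
#' length; a term with norm below `1e-12` (e.g. the alignment term among
#' perfectly aligned neighbors) is dropped rather than divided by its norm,
#' and boids without neighbors feel zero force.
#'
#' The fast path inside [run_boids()] is the same computation in compiled
#' code; the two agree to machine precision.
#'
#' @param state a [init_state()] result.
#' @param graph a `neighbor_graph` built on the current positions, or `NULL`
#'   to build it from `params`.
#' @param params a [boid_params()].
#' @return A list of `N x 2` matrices `f_sep`, `f_alg`, `f_coh`, `f_total`
#'   plus the per-boid `degree`.
#' @export
compute_forces <- function(state, graph = NULL, params) {
  stopifnot(inherits(state, "boid_state"), inherits(params, "boid_params"))
  pts <- point_set(state$positions, "periodic", box = params$box)
  if (is.null(graph))
    graph <- build_neighbor_graph(pts, params$neighbor_mode,
                                  params$metric_radius)
  n <- nrow(state$positions)
  vel <- boid_velocities(state, params$speed)
  f_sep <- f_alg <- f_coh <- f_total <- matrix(0, n, 2)
  deg <- graph$degree
  if (nrow(graph$edges)) {
    ei <- c(graph$edges[, 1], graph$edges[, 2])
    ej <- c(graph$edges[, 2], graph$edges[, 1])
    d <- pair_displacements(pts, ei, ej) # r_i - r_j, minimum image
    r2 <- d[, 1]^2 + d[, 2]^2
    acc <- function(values, idx) {
      out <- matrix(0, n, 2)
      s <- rowsum(values, idx)
      out[as.integer(rownames(s)), ] <- s
      out
    }
    f_sep <- acc(d / r2, ei)
    sv <- acc(vel[ej, , drop = FALSE], ei)
    has <- deg > 0
    f_alg[has, ] <- sv[has, ] / deg[has] - vel[has, , drop = FALSE]
    f_coh <- acc(-d, ei)
    f_coh[has, ] <- f_coh[has, ] / deg[has]
    unit <- function(f) {
      nrm <- sqrt(f[, 1]^2 + f[, 2]^2)
      keep <- nrm >= 1e-12
      f[keep, ] <- f[keep, ] / nrm[keep]
      f[!keep, ] <- 0
      f
    }
    f_total <- unit(f_sep) + unit(f_alg) + unit(f_coh)
    f_total[!has, ] <- 0
  }
  list(f_sep = f_sep, f_alg = f_alg, f_coh = f_coh, f_total = f_total,
       degree = deg)
}

#' Advance a boid state
#'
#' One (or more) update steps: new heading = direction of `v_i + S * F_i`
#' plus a per-boid uniform angular noise in `(-eta, eta)` degrees; speed is
#' reset to exactly `V`; positions advance by `v * dt` and wrap
#' periodically. Uses the current R RNG stream (seed it, e.g. via
#' [init_state()], for reproducibility).
#'
#' @param state a `boid_state`.
#' @param params a [boid_params()].
#' @param n_steps number of steps to advance.
#' @return The advanced `boid_state`.
#' @export
boid_step <- function(state, params, n_steps = 1) {
  stopifnot(inherits(state, "boid_state"), inherits(params, "boid_params"))
  res <- .boids_run_cpp(state$positions, state$headings, params$box[1],
                        params$box[2], params$speed, params$steering,
                        params$noise, params$dt,
                        params$neighbor_mode == "metric",
                        params$metric_radius %||% 0, n_steps,
                        n_steps, 0, 1000L)
  k <- length(res$rec_steps)
  pos <- res$positions[[k]]
  colnames(pos) <- c("x", "y")
  structure(list(positions = pos, headings = as.numeric(res$headings[[k]]),
                 step_index = state$step_index + as.integer(n_steps),
                 box = params$box),
            class = "boid_state")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a boid simulation
#'
#' Seeds the RNG from `params$seed`, draws the initial state, then advances
#' the dynamics, rebuilding the neighbor graph at every step. The
#' average-velocity order parameter is recorded at every step; full
#' configurations (positions and headings) are recorded every
#' `record_every` steps plus the initial and final states. Runs are bitwise
#' reproducible given the seed.
#'
#' @param params a [boid_params()].
#' @param n_steps maximum number of steps (at least 1).
#' @param record_every configuration recording cadence in steps.
#' @param conv_tol optional early stop: if positive, the run stops once the
#'   mean of `v_a` over the latest `conv_window` steps changes by less than
#'   `conv_tol` relative to the previous window.
#' @param conv_window window (steps) for the convergence check.
#' @return An object of class `boid_trajectory`: `params`, `va` (per-step
#'   order parameter), `rec_steps`, `positions` and `headings` (lists of
#'   recorded frames), `steps_done`, `converged`.
#' @examples
#' p <- boid_params(n_boids = 30, steering = 0.1, seed = 7)
#' tr <- run_boids(p, n_steps = 50, record_every = 25)
#' tail(tr$va, 3)
#' @export
run_boids <- function(params, n_steps, record_every = 100, conv_tol = 0,
                      conv_window = 1000) {
  stopifnot(inherits(params, "boid_params"), n_steps >= 1)
  state <- init_state(params) # seeds the RNG
  res <- .boids_run_cpp(state$positions, state$headings, params$box[1],
                        params$box[2], params$speed, params$steering,
                        params$noise, params$dt,
                        params$neighbor_mode == "metric",
                        params$metric_radius %||% 0, as.integer(n_steps),
                        as.integer(record_every), conv_tol,
                        as.integer(conv_window))
  structure(list(params = params, va = res$va, rec_steps = res$rec_steps,
                 positions = lapply(res$positions, function(p) {
                   colnames(p) <- c("x", "y"); p
                 }),
                 headings = res$headings, steps_done = res$steps_done,
                 converged = res$converged),
            class = "boid_trajectory")
}

#' @export
print.boid_trajectory <- function(x, ...) {
  cat(sprintf("<boid_trajectory> %d boids, %d steps (%s), %d recorded frames, final v_a = %.3f\n",
              x$params$n_boids, x$steps_done,
              if (x$converged) "converged" else "step budget",
              length(x$rec_steps), tail(x$va, 1)))
  invisible(x)
}

#' Recorded frame of a trajectory as a point set
#' @param traj a [run_boids()] result.
#' @param which frame index (1-based into the recorded frames).
#' @return A periodic [point_set()].
#' @export
frame_point_set <- function(traj, which) {
  stopifnot(inherits(traj, "boid_trajectory"))
  point_set(traj$positions[[which]], "periodic", box = traj$params$box)
}
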