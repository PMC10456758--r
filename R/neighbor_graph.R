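#' Topological (Voronoi) neighbor graph
#'
#' Two agents are neighbors iff their Voronoi cells share an edge,
#' equivalently iff they are adjacent in the Delaunay triangulation. Under
#' periodic boundaries the tessellation is computed on a 3x3 ghost tiling of
#' the box and adjacencies are mapped back to canonical indices with
#' minimum-image distances; under open boundaries adjacencies involving
#' unbounded Voronoi cells are retained.
#'
#' Co-circular degeneracies (e.g. a perfect square lattice) are broken by a
#' deterministic fixed-seed jitter of magnitude `1e-9` times the data extent
#' applied only inside the tessellation; reported distances always use the
#' unperturbed coordinates, so results are bitwise reproducible.
#'
#' @param points a [point_set()]. Open boundaries require at least 3
#'   non-collinear points; duplicate points are rejected.
#' @return An object of class `neighbor_graph`: `n_agents`, `edges` (an
#'   `m x 2` integer matrix of unordered pairs, `i < j`), `distance` (per
#'   edge), `degree` (per agent) and `mode`.
#' @seealso [build_metric_graph()], [neighbor_distances()]
#' @examples
#' ps <- point_set(cbind(c(0, 1, 0.5), c(0, 0, 1)))
#' build_voronoi_graph(ps) # a triangle: complete graph on 3 points
#' @export
build_voronoi_graph <- function(points) {
  stopifnot(inherits(points, "point_set"))
  n <- nrow(points$coords)
  dup <- which(duplicated(points$coords) |
                 duplicated(points$coords, fromLast = TRUE))
  if (length(dup))
    stop("degenerate geometry: duplicate points at indices ",
         paste(dup, collapse = ", "))
  if (points$boundary == "open") {
    if (n < 3)
      stop("open-boundary Voronoi tessellation needs at least 3 points")
    check_not_collinear(points$coords)
    edges <- .delaunay_edges_cpp(points$coords)
  } else {
    edges <- .periodic_delaunay_edges_cpp(points$coords, points$box[1],
                                          points$box[2])
  }
  new_neighbor_graph(points, edges, "voronoi")
}

check_not_collinear <- function(coords) {
  p1 <- coords[1, ]
  dif <- sweep(coords, 2, p1)
  r2 <- dif[, 1]^2 + dif[, 2]^2
  i2 <- which.max(r2)
  cross <- dif[, 1] * dif[i2, 2] - dif[, 2] * dif[i2, 1]
  if (all(abs(cross) <= 1e-9 * max(r2)))
    stop("degenerate geometry: all points are collinear")
  invisible(TRUE)
}

#' Metric neighbor graph
#'
#' Edge `(i, j)` is present iff the distance between agents i and j is at
#' most `radius` (closed comparison; minimum-image distance under periodic
#' boundaries).
#'
#' @param points a [point_set()].
#' @param radius non-negative interaction radius, in the length unit of the
#'   coordinates.
#' @return A `neighbor_graph` (see [build_voronoi_graph()]).
#' @examples
#' ps <- point_set(cbind(c(0, 1, 2), c(0, 0, 0)))
#' build_metric_graph(ps, radius = 1.5) # edges (1,2) and (2,3) only
#' @export
build_metric_graph <- function(points, radius) {
  stopifnot(inherits(points, "point_set"))
  if (!is.numeric(radius) || length(radius) != 1 || !is.finite(radius) ||
      radius < 0)
    stop("`radius` must be a single non-negative number")
  n <- nrow(points$coords)
  if (n < 2 || radius == 0) {
    edges <- matrix(integer(0), ncol = 2)
  } else {
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    d <- pair_distances_idx(points, idx[, 1], idx[, 2])
    keep <- d <= radius
    edges <- cbind(idx[keep, 1], idx[keep, 2])
  }
  new_neighbor_graph(points, edges, "metric", radius = radius)
}

new_neighbor_graph <- function(points, edges, mode, radius = NULL) {
  n <- nrow(points$coords)
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges)) {
    o <- order(edges[, 1], edges[, 2])
    edges <- edges[o, , drop = FALSE]
    dist <- pair_distances_idx(points, edges[, 1], edges[, 2])
  } else {
    dist <- numeric(0)
  }
  colnames(edges) <- c("i", "j")
  structure(list(n_agents = n, edges = edges, distance = dist,
                 degree = tabulate(c(edges), nbins = n), mode = mode,
                 radius = radius),
            class = "neighbor_graph")
}

#' @export
print.neighbor_graph <- function(x, ...) {
  cat(sprintf("<neighbor_graph> %s mode: %d agents, %d edges, mean degree %.3g\n",
              x$mode, x$n_agents, nrow(x$edges),
              if (x$n_agents) 2 * nrow(x$edges) / x$n_agents else 0))
  invisible(x)
}

#' Neighbor-distance sample of a configuration
#'
#' Collects one distance per agent--neighbor incidence. With the default
#' `per_agent_directed` convention each undirected edge contributes twice
#' (once per endpoint), matching a count over "all agents"; the derived
#' probabilities, and hence the entropy, are identical under the `per_edge`
#' convention because the uniform factor 2 cancels.
#'
#' @param points the [point_set()] the graph was built from.
#' @param graph a [build_voronoi_graph()]/[build_metric_graph()] result.
#' @param convention `"per_agent_directed"` (default) or `"per_edge"`.
#' @return An object of class `distance_sample`: `values`, `convention`.
#' @export
neighbor_distances <- function(points, graph,
                               convention = c("per_agent_directed",
                                              "per_edge")) {
  convention <- match.arg(convention)
  stopifnot(inherits(points, "point_set"), inherits(graph, "neighbor_graph"))
  if (graph$n_agents != nrow(points$coords))
    stop("graph was built from a point set of different size (",
         graph$n_agents, " vs ", nrow(points$coords), " agents)")
  values <- graph$distance
  if (convention == "per_agent_directed") values <- rep(values, each = 2L)
  structure(list(values = values, convention = convention),
            class = "distance_sample")
}

#' @export
print.distance_sample <- function(x, ...) {
  cat(sprintf("<distance_sample> %d distances (%s)\n", length(x$values),
              x$convention))
  invisible(x)
}

#' Write a neighbor graph as an edge-list CSV
#'
#' Columns `i`, `j`, `distance`, one row per undirected edge.
#'
#' @param graph a `neighbor_graph`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  stopifnot(inherits(graph, "neighbor_graph"))
  df <- data.frame(i = graph$edges[, 1], j = graph$edges[, 2],
                   distance = graph$distance)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
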