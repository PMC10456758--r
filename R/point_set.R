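#' Construct a 2-D point set
#'
#' The basic container for agent positions: an `N x 2` coordinate matrix plus
#' boundary metadata. Under periodic boundaries the coordinates are wrapped
#' canonically into `[0, Lx) x [0, Ly)`.
#'
#' @param coords numeric matrix or data frame with two columns (x, y).
#' @param boundary `"open"` or `"periodic"`.
#' @param box numeric length-2 vector `(Lx, Ly)`; required iff `boundary`
#'   is `"periodic"`.
#' @return An object of class `point_set` with elements `coords`, `boundary`,
#'   `box`.
#' @examples
#' ps <- point_set(cbind(runif(10, 0, 100), runif(10, 0, 100)),
#'                 boundary = "periodic", box = c(100, 100))
#' ps
#' @export
point_set <- function(coords, boundary = c("open", "periodic"), box = NULL) {
  boundary <- match.arg(boundary)
  coords <- as.matrix(coords)
  if (ncol(coords) != 2)
    stop("`coords` must have exactly two columns (x, y)")
  storage.mode(coords) <- "double"
  if (nrow(coords) < 1) stop("a point set needs at least one point")
  if (!all(is.finite(coords))) stop("all coordinates must be finite")
  if (boundary == "periodic") {
    if (is.null(box) || length(box) != 2 || !all(is.finite(box)) ||
        any(box <= 0))
      stop("periodic boundaries require a strictly positive `box = c(Lx, Ly)`")
    box <- as.numeric(box)
    coords[, 1] <- coords[, 1] %% box[1]
    coords[, 2] <- coords[, 2] %% box[2]
  } else {
    box <- NULL
  }
  colnames(coords) <- c("x", "y")
  structure(list(coords = coords, boundary = boundary, box = box),
            class = "point_set")
}

#' @export
print.point_set <- function(x, ...) {
  cat(sprintf("<point_set> %d points, %s boundary", nrow(x$coords),
              x$boundary))
  if (x$boundary == "periodic")
    cat(sprintf(", box %g x %g", x$box[1], x$box[2]))
  cat("\n")
  invisible(x)
}

#' Number of points in a point set
#' @param points a [point_set()].
#' @return Integer count.
#' @export
n_points <- function(points) {
  stopifnot(inherits(points, "point_set"))
  nrow(points$coords)
}

# minimum-image displacement components for a periodic box
minimum_image <- function(d, L) d - L * round(d / L)

# pairwise displacement rows pts[i,] - pts[j,] honoring the boundary
pair_displacements <- function(points, i, j) {
  d <- points$coords[i, , drop = FALSE] - points$coords[j, , drop = FALSE]
  if (points$boundary == "periodic") {
    d[, 1] <- minimum_image(d[, 1], points$box[1])
    d[, 2] <- minimum_image(d[, 2], points$box[2])
  }
  d
}

pair_distances_idx <- function(points, i, j) {
  d <- pair_displacements(points, i, j)
  unname(sqrt(d[, 1]^2 + d[, 2]^2))
}
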