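#' Hexagonal (triangular) lattice
#'
#' The zero-entropy calibration pattern: every nearest-neighbor distance
#' equals `spacing`, so the neighbor-distance histogram has a single
#' occupied bin and `H_NDist = 0`. The periodic box is commensurate with
#' the lattice (`nx * a` by `ny * a * sqrt(3)/2`), which requires an even
#' number of rows.
#'
#' @param nx,ny columns and rows (each at least 2; `ny` even for the
#'   periodic tiling to close).
#' @param spacing lattice constant `a`.
#' @param boundary `"periodic"` (default) or `"open"`.
#' @return A [point_set()] of `nx * ny` points.
#' @export
hexagonal_lattice <- function(nx, ny, spacing = 10,
                              boundary = c("periodic", "open")) {
  boundary <- match.arg(boundary)
  stopifnot(nx >= 2, ny >= 2, spacing > 0)
  if (boundary == "periodic" && ny %% 2 != 0)
    stop("incommensurate lattice: a periodic hexagonal tiling needs an ",
         "even number of rows `ny`")
  j <- rep(0:(ny - 1), each = nx)
  i <- rep(0:(nx - 1), times = ny)
  x <- (i + 0.5 * (j %% 2)) * spacing
  y <- j * spacing * sqrt(3) / 2
  box <- if (boundary == "periodic")
    c(nx * spacing, ny * spacing * sqrt(3) / 2) else NULL
  point_set(cbind(x, y), boundary, box)
}

#' Square lattice
#'
#' A densely packed square arrangement of circles of equal diameter
#' (`spacing`), the base pattern for the letter configurations.
#'
#' @param nx,ny columns and rows.
#' @param spacing lattice constant (circle diameter).
#' @param boundary `"open"` (default) or `"periodic"`.
#' @return A [point_set()].
#' @export
square_lattice <- function(nx, ny, spacing = 10,
                           boundary = c("open", "periodic")) {
  boundary <- match.arg(boundary)
  stopifnot(nx >= 2, ny >= 2, spacing > 0)
  g <- expand.grid(x = (0:(nx - 1)) * spacing, y = (0:(ny - 1)) * spacing)
  box <- if (boundary == "periodic") c(nx * spacing, ny * spacing) else NULL
  point_set(as.matrix(g), boundary, box)
}

#' Jitter the sites of a point set
#'
#' Adds an independent uniform displacement in `[-amplitude, amplitude]^2`
#' to every site (rewrapped under periodic boundaries). Any positive
#' amplitude breaks the distance degeneracy of a perfect lattice, so
#' `H_NDist` rises strictly above zero, while the torus Euler invariant
#' keeps the mean Voronoi degree at 6.
#'
#' @param points a [point_set()].
#' @param amplitude non-negative jitter half-width.
#' @param seed integer seed (the generator is a pure function of its
#'   arguments).
#' @return A new [point_set()] with the same boundary metadata.
#' @export
jittered_lattice <- function(points, amplitude, seed = 1L) {
  stopifnot(inherits(points, "point_set"), amplitude >= 0)
  set.seed(seed)
  n <- nrow(points$coords)
  d <- matrix(runif(2 * n, -amplitude, amplitude), n, 2)
  point_set(points$coords + d, points$boundary, points$box)
}

#' Uniform gas configuration
#'
#' `n` points uniform over a periodic box: the structureless, high-entropy
#' reference state standing in for a gas-like steady state.
#'
#' @param n number of points (at least 3).
#' @param box box extents.
#' @param seed integer seed.
#' @return A periodic [point_set()].
#' @export
uniform_gas <- function(n, box = c(1000, 1000), seed = 1L) {
  stopifnot(n >= 3)
  set.seed(seed)
  point_set(cbind(runif(n, 0, box[1]), runif(n, 0, box[2])), "periodic",
            box)
}

#' Gaussian cluster configuration
#'
#' `k` isotropic Gaussian clusters of `n_per_cluster` points each: the
#' aggregated, low-entropy reference state. Cluster centers are rejection
#' sampled until all pairwise (minimum-image) separations exceed
#' `6 * sigma`, so clusters do not overlap.
#'
#' @param k number of clusters.
#' @param n_per_cluster points per cluster.
#' @param sigma cluster standard deviation (length units).
#' @param box box extents.
#' @param seed integer seed.
#' @param centers optional fixed `k x 2` matrix of cluster centers; when
#'   supplied only the within-cluster offsets are redrawn (an aggregated
#'   state that fluctuates around persistent clusters).
#' @return A periodic [point_set()].
#' @export
gaussian_clusters <- function(k, n_per_cluster, sigma, box = c(1000, 1000),
                              seed = 1L, centers = NULL) {
  stopifnot(k >= 1, n_per_cluster >= 1, sigma > 0)
  set.seed(seed)
  if (is.null(centers)) {
    centers <- draw_cluster_centers(k, sigma, box)
  } else {
    centers <- as.matrix(centers)
    stopifnot(nrow(centers) == k, ncol(centers) == 2)
  }
  x <- rep(centers[, 1], each = n_per_cluster) +
    rnorm(k * n_per_cluster, 0, sigma)
  y <- rep(centers[, 2], each = n_per_cluster) +
    rnorm(k * n_per_cluster, 0, sigma)
  ps <- point_set(cbind(x, y), "periodic", box)
  attr(ps, "centers") <- centers
  ps
}

draw_cluster_centers <- function(k, sigma, box) {
  for (try in 1:1000) {
    centers <- cbind(runif(k, 0, box[1]), runif(k, 0, box[2]))
    if (k == 1) return(centers)
    idx <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
    dx <- minimum_image(centers[idx[, 1], 1] - centers[idx[, 2], 1], box[1])
    dy <- minimum_image(centers[idx[, 1], 2] - centers[idx[, 2], 2], box[2])
    if (min(sqrt(dx^2 + dy^2)) >= 6 * sigma) return(centers)
  }
  stop("could not place ", k, " cluster centers at least 6*sigma apart")
}

#' Synthetic steady-state configuration series
#'
#' Stand-ins for the temporal statistics of two dynamical steady states of
#' an active system. A gas-like state decorrelates between analysis frames,
#' so its series consists of independent uniform redraws; an aggregated
#' state keeps its clusters in place and only vibrates, so its series jitters
#' one fixed cluster configuration by a small amplitude. The entropy of the
#' gas series therefore fluctuates from frame to frame much more than that
#' of the aggregated series, mirroring the larger temporal standard
#' deviation of the gas state.
#'
#' @param state `"gas"` or `"aggregated"`.
#' @param n_frames number of frames in the series.
#' @param n total number of agents per frame.
#' @param box box extents.
#' @param k clusters in the aggregated state.
#' @param sigma cluster standard deviation.
#' @param vibration per-frame positional jitter of the aggregated state
#'   (length units).
#' @param seed integer seed; the series is a pure function of its arguments.
#' @return A list of [point_set()] frames.
#' @export
synthetic_state_series <- function(state = c("gas", "aggregated"),
                                   n_frames = 20, n = 500,
                                   box = c(1000, 1000), k = 5, sigma = 10,
                                   vibration = 1, seed = 1L) {
  state <- match.arg(state)
  if (state == "gas") {
    lapply(seq_len(n_frames), function(f) uniform_gas(n, box, seed + f))
  } else {
    base <- gaussian_clusters(k, n %/% k, sigma, box, seed)
    lapply(seq_len(n_frames),
           function(f) jittered_lattice(base, vibration, seed + f))
  }
}

# glyph cache ----------------------------------------------------------------

the_glyphs <- new.env(parent = emptyenv())

load_glyphs <- function() {
  if (!is.null(the_glyphs$bitmaps)) return(the_glyphs$bitmaps)
  path <- system.file("extdata", "letter_glyphs.txt",
                      package = "swarmentropy", mustWork = TRUE)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(;|$)", lines)] # ';' comments: '#' is a glyph cell

  bitmaps <- list()
  i <- 1
  while (i <= length(lines)) {
    letter <- lines[i]
    rows <- lines[(i + 1):(i + 7)]
    bitmaps[[letter]] <- t(vapply(rows, function(r) {
      strsplit(r, "")[[1]] == "#"
    }, logical(5)))
    i <- i + 8
  }
  the_glyphs$bitmaps <- bitmaps
  bitmaps
}

#' Letter mask
#'
#' A fixed binary 5 x 7 glyph for one of the 26 capital letters (defined in
#' the package's `extdata/letter_glyphs.txt` asset), expanded so that every
#' glyph cell covers `scale x scale` lattice sites.
#'
#' @param letter a single capital letter `"A"`--`"Z"`.
#' @param scale lattice sites per glyph cell (at least 1).
#' @return An object of class `letter_mask`: `letter`, `bitmap` (7 x 5
#'   logical matrix, row 1 on top), `scale`.
#' @export
letter_mask <- function(letter, scale = 3) {
  stopifnot(is.character(letter), length(letter) == 1, scale >= 1)
  letter <- toupper(letter)
  if (!letter %in% LETTERS) stop("`letter` must be one of A-Z")
  bitmaps <- load_glyphs()
  structure(list(letter = letter, bitmap = bitmaps[[letter]],
                 scale = as.integer(scale)),
            class = "letter_mask")
}

#' Letter-shaped swarm configuration
#'
#' Masks a densely packed square lattice of circles of equal diameter
#' (`spacing`) with a letter glyph: a lattice site is retained iff it falls
#' in a filled glyph cell. Open boundary, no randomness: each letter yields
#' one deterministic configuration whose entropy differences arise from the
#' different edge profiles of the glyphs.
#'
#' @param mask a [letter_mask()].
#' @param spacing lattice constant (circle diameter).
#' @return An open-boundary [point_set()].
#' @export
letter_configuration <- function(mask, spacing = 10) {
  stopifnot(inherits(mask, "letter_mask"), spacing > 0)
  s <- mask$scale
  nr <- nrow(mask$bitmap) * s
  nc <- ncol(mask$bitmap) * s
  g <- expand.grid(r = 1:nr, c = 1:nc)
  keep <- mask$bitmap[cbind(ceiling(g$r / s), ceiling(g$c / s))]
  g <- g[keep, ]
  if (nrow(g) < 3)
    stop("mask retains fewer than 3 lattice sites; increase `scale`")
  point_set(cbind((g$c - 1) * spacing, (nr - g$r) * spacing), "open")
}

#' Entropy table of the 26 letter configurations
#'
#' Deterministic `H_NDist` of every requested letter configuration. The
#' default bin width of one tenth of the spacing resolves the distinct
#' lattice and edge distances.
#'
#' @param letters character vector of capital letters.
#' @param spacing lattice constant.
#' @param bin_size histogram bin width.
#' @param scale lattice sites per glyph cell.
#' @return A data frame: `letter`, `n_sites`, `h_ndist`, `h_norm`,
#'   `occupied_bins`.
#' @export
letter_entropies <- function(letters = LETTERS, spacing = 10,
                             bin_size = spacing / 10, scale = 3) {
  rows <- lapply(letters, function(l) {
    ps <- letter_configuration(letter_mask(l, scale), spacing)
    r <- entropy_by_neighbor_distance(ps, bin_size)
    data.frame(letter = l, n_sites = n_points(ps), h_ndist = r$h_ndist,
               h_norm = r$h_norm, occupied_bins = r$occupied_bins)
  })
  do.call(rbind, rows)
}
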