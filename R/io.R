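#' Read a trajectory CSV
#'
#' The trajectory dialect: a comma-separated file with a header and columns
#' `frame` (integer, 0-based or otherwise), `id` (integer), `x`, `y`, and
#' optionally `vx`, `vy`. Extra columns are preserved. Frames are analyzed
#' independently, so unlinked per-frame detections are acceptable input.
#'
#' @param path file path.
#' @return A data frame with at least `frame`, `id`, `x`, `y`.
#' @export
read_trajectory <- function(path) {
  tbl <- read.csv(path, stringsAsFactors = FALSE)
  validate_trajectory(tbl)
  tbl
}

validate_trajectory <- function(tbl) {
  required <- c("frame", "id", "x", "y")
  missing <- setdiff(required, names(tbl))
  if (length(missing))
    stop("trajectory format error: missing required column(s) ",
         paste(missing, collapse = ", "))
  dup <- which(duplicated(tbl[c("frame", "id")]))
  if (length(dup))
    stop("trajectory format error: duplicated (frame, id) pair at data ",
         "row ", dup[1])
  if (!all(is.finite(tbl$x)) || !all(is.finite(tbl$y)))
    stop("trajectory format error: non-finite coordinates")
  invisible(tbl)
}

#' Write a trajectory CSV
#' @param tbl a trajectory data frame (see [read_trajectory()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(tbl, path) {
  validate_trajectory(tbl)
  write.csv(tbl, path, row.names = FALSE)
  invisible(path)
}

#' Trajectory table of a simulation run
#'
#' Long-format table of the recorded frames with velocities, in the
#' trajectory CSV dialect (`frame` = step index, `id` = boid index).
#'
#' @param traj a [run_boids()] result.
#' @return A data frame: `frame`, `id`, `x`, `y`, `vx`, `vy`.
#' @export
as_trajectory_table <- function(traj) {
  stopifnot(inherits(traj, "boid_trajectory"))
  v <- traj$params$speed
  do.call(rbind, lapply(seq_along(traj$rec_steps), function(k) {
    th <- as.numeric(traj$headings[[k]])
    data.frame(frame = traj$rec_steps[k],
               id = seq_along(th),
               x = traj$positions[[k]][, 1], y = traj$positions[[k]][, 2],
               vx = v * cos(th), vy = v * sin(th))
  }))
}

#' One frame of a trajectory table as a point set
#'
#' @param tbl a trajectory data frame.
#' @param frame frame label to extract.
#' @param boundary,box boundary metadata for the resulting [point_set()].
#' @return A [point_set()].
#' @export
frame_from_table <- function(tbl, frame, boundary = "open", box = NULL) {
  validate_trajectory(tbl)
  rows <- tbl[tbl$frame == frame, ]
  if (!nrow(rows)) stop("no rows for frame ", frame)
  point_set(cbind(rows$x, rows$y), boundary, box)
}

#' Entropy by neighbor distance for every frame of a trajectory table
#'
#' @param tbl a trajectory data frame.
#' @inheritParams entropy_by_neighbor_distance
#' @param boundary,box boundary metadata applied to every frame.
#' @return A data frame: `frame`, `n_samples`, `bin_size`, `h_ndist`,
#'   `h_norm`, `occupied_bins`.
#' @export
entropy_over_frames <- function(tbl, bin_size = 1,
                                neighbor_mode = c("voronoi", "metric"),
                                metric_radius = NULL, boundary = "open",
                                box = NULL) {
  validate_trajectory(tbl)
  neighbor_mode <- match.arg(neighbor_mode)
  frames <- sort(unique(tbl$frame))
  rows <- lapply(frames, function(f) {
    ps <- frame_from_table(tbl, f, boundary, box)
    r <- entropy_by_neighbor_distance(ps, bin_size, neighbor_mode,
                                      metric_radius)
    data.frame(frame = f, n_samples = r$n_samples, bin_size = r$bin_size,
               h_ndist = r$h_ndist, h_norm = r$h_norm,
               occupied_bins = r$occupied_bins)
  })
  do.call(rbind, rows)
}

#' Dump a distance histogram as CSV
#'
#' Columns `bin_left`, `bin_right`, `count`, one row per bin (empty bins
#' included), for inspecting the neighbor-distance distribution.
#'
#' @param hist a [make_histogram()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_histogram <- function(hist, path) {
  stopifnot(inherits(hist, "distance_histogram"))
  nb <- length(hist$counts)
  df <- data.frame(bin_left = hist$breaks[1:nb],
                   bin_right = hist$breaks[2:(nb + 1)],
                   count = hist$counts)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a plain key-value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment; values that parse
#' as numbers become numeric. Used by the command-line interface, where
#' explicit flags override configuration values.
#'
#' @param path file path.
#' @return A named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2)
      stop("configuration format error in line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(kv[2])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}
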