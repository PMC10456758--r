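# Independent oracles used across the suite.

# circumcircle through three points; NULL if collinear
circumcircle <- function(a, b, c) {
  d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) +
              c[1] * (a[2] - b[2]))
  if (abs(d) < 1e-14 * max(abs(c(a, b, c)), 1)^2) return(NULL)
  a2 <- sum(a^2); b2 <- sum(b^2); c2 <- sum(c^2)
  ux <- (a2 * (b[2] - c[2]) + b2 * (c[2] - a[2]) + c2 * (a[2] - b[2])) / d
  uy <- (a2 * (c[1] - b[1]) + b2 * (a[1] - c[1]) + c2 * (b[1] - a[1])) / d
  list(x = ux, y = uy, r2 = (a[1] - ux)^2 + (a[2] - uy)^2)
}

# Brute-force Delaunay adjacency: (i, j) adjacent iff some circumcircle
# through i, j and a third point contains no other point (n >= 3), or the
# two-point diameter circle is empty (n == 2).
brute_delaunay_edges <- function(coords) {
  n <- nrow(coords)
  if (n == 2) return(matrix(c(1L, 2L), 1))
  edges <- NULL
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      for (k in setdiff(seq_len(n), c(i, j))) {
        cc <- circumcircle(coords[i, ], coords[j, ], coords[k, ])
        if (is.null(cc)) next
        d2 <- (coords[, 1] - cc$x)^2 + (coords[, 2] - cc$y)^2
        others <- setdiff(seq_len(n), c(i, j, k))
        if (!length(others) || all(d2[others] > cc$r2 * (1 - 1e-12))) {
          edges <- rbind(edges, c(i, j))
          break
        }
      }
    }
  }
  edges
}

# Brute-force periodic Voronoi adjacency via explicit 3x3 tiling: for each
# pair with a canonical member, search an empty circumcircle among all tiled
# points.
brute_periodic_edges <- function(coords, box) {
  n <- nrow(coords)
  offs <- expand.grid(ox = c(0, box[1], -box[1]), oy = c(0, box[2], -box[2]))
  tiled <- do.call(rbind, lapply(seq_len(nrow(offs)), function(t) {
    cbind(coords[, 1] + offs$ox[t], coords[, 2] + offs$oy[t])
  }))
  m <- nrow(tiled)
  hit <- matrix(FALSE, n, n)
  for (u in seq_len(n)) {
    for (v in seq_len(m)) {
      a <- (u - 1) %% n + 1
      b <- (v - 1) %% n + 1
      if (v == u || a == b) next
      if (hit[min(a, b), max(a, b)]) next
      for (k in setdiff(seq_len(m), c(u, v))) {
        cc <- circumcircle(tiled[u, ], tiled[v, ], tiled[k, ])
        if (is.null(cc)) next
        d2 <- (tiled[, 1] - cc$x)^2 + (tiled[, 2] - cc$y)^2
        others <- setdiff(seq_len(m), c(u, v, k))
        if (all(d2[others] > cc$r2 * (1 - 1e-12))) {
          hit[min(a, b), max(a, b)] <- TRUE
          break
        }
      }
    }
  }
  which(hit, arr.ind = TRUE)
}

# literal, unoptimized Shannon entropy in bits
entropy_literal <- function(counts) {
  total <- sum(counts)
  h <- 0
  for (ci in counts) {
    if (ci > 0) {
      p <- ci / total
      h <- h - p * log2(p)
    }
  }
  h
}

edge_key <- function(edges) {
  if (is.null(edges) || nrow(edges) == 0) return(character(0))
  sort(paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]),
             sep = "-"))
}

rand_open_points <- function(n, scale = 100) {
  point_set(cbind(runif(n, 0, scale), runif(n, 0, scale)))
}
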