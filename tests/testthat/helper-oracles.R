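# Independent oracles and small fixture builders shared across tests.

# exhaustive Fisher partition search: all ways to cut sorted x into k
# contiguous classes; returns the minimal total within-class SSD
jenks_oracle <- function(x, k) {
  x <- sort(x)
  n <- length(x)
  sse <- function(v) sum((v - mean(v))^2)
  cuts <- utils::combn(n - 1, k - 1)
  best <- Inf; best_breaks <- NULL
  for (j in seq_len(ncol(cuts))) {
    b <- c(0, cuts[, j], n)
    tot <- 0
    for (c_i in seq_len(k)) tot <- tot + sse(x[(b[c_i] + 1):b[c_i + 1]])
    if (tot < best - 1e-12) {
      best <- tot
      best_breaks <- (x[cuts[, j]] + x[cuts[, j] + 1]) / 2
    }
  }
  list(objective = best, breaks = best_breaks)
}

# independent cost-distance oracle on the 8-connected grid graph via igraph
igraph_cwd <- function(vals, cell_size, source_idx) {
  nr <- nrow(vals); nc <- ncol(vals)
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    if (is.na(vals[r, cc])) next
    u <- (cc - 1) * nr + r
    for (d in list(c(0, 1, 1), c(1, 0, 1), c(1, 1, sqrt(2)), c(-1, 1, sqrt(2)))) {
      r2 <- r + d[1]; c2 <- cc + d[2]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (is.na(vals[r2, c2])) next
      v <- (c2 - 1) * nr + r2
      from <- c(from, u); to <- c(to, v)
      w <- c(w, (vals[r, cc] + vals[r2, c2]) / 2 * cell_size * d[3])
    }
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to), directed = FALSE,
    vertices = data.frame(name = seq_len(nr * nc)))
  d <- igraph::distances(g, v = as.character(source_idx),
                         weights = w, algorithm = "dijkstra")
  apply(d, 2, min)[as.character(seq_len(nr * nc))]
}

# random AHP reciprocal matrix (exactly reciprocal)
rand_recip_matrix <- function(n) {
  a <- matrix(1, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a[i, j] <- exp(stats::runif(1, -1.5, 1.5))
    a[j, i] <- 1 / a[i, j]
  }
  a
}

# bowtie landscape: two broad low-resistance lobes joined by a thin neck.
# Returns resistance grid plus a patch polygon layer (one patch per lobe).
make_bowtie <- function(cell_size = 100, neck_rows = 2) {
  nr <- 31; nc <- 41
  v <- matrix(100, nr, nc)                 # hostile matrix
  v[4:28, 2:14] <- 1                       # west lobe
  v[4:28, 28:40] <- 1                      # east lobe
  rows <- 15:(15 + neck_rows - 1)
  v[rows, 15:27] <- 1                      # the neck
  g <- pan_grid(v, cell_size = cell_size)
  sq <- function(r1, r2, c1, c2) {
    cbind(c(g$origin[1] + (c1 - 1) * cell_size, g$origin[1] + c2 * cell_size,
            g$origin[1] + c2 * cell_size, g$origin[1] + (c1 - 1) * cell_size),
          c(g$origin[2] - (r1 - 1) * cell_size, g$origin[2] - (r1 - 1) * cell_size,
            g$origin[2] - r2 * cell_size, g$origin[2] - r2 * cell_size))
  }
  pa <- pan_vector(list(feat_polygon(sq(10, 22, 3, 9), id = 1, category = "nature reserve"),
                        feat_polygon(sq(10, 22, 33, 39), id = 2, category = "nature reserve")))
  list(resistance = g, pa = pa, neck_rows = rows, neck_cols = 15:27)
}

# two-patch uniform landscape with a single high-resistance wall strip
make_walled_strip <- function(nr = 25, nc = 41, wall_col = 21, cell_size = 30,
                              background = 1, wall = 100) {
  v <- matrix(background, nr, nc)
  v[, wall_col] <- wall
  g <- pan_grid(v, cell_size = cell_size)
  lab <- matrix(0L, nr, nc)
  mid <- (nr + 1) %/% 2
  rows <- (mid - 2):(mid + 2)
  lab[rows, 3:6] <- 1L
  lab[rows, (nc - 5):(nc - 2)] <- 2L
  patches <- structure(list(
    labels = grid_like(g, lab),
    patches = tibble::tibble(id = 1:2, category = NA_character_,
                             n_cells = c(20L, 20L),
                             centroid_row = mid, centroid_col = c(4.5, nc - 3.5),
                             area_km2 = 20 * cell_size^2 / 1e6)),
    class = "pan_patches")
  list(resistance = g, patches = patches, wall_cells = which(col(v) == wall_col))
}

expect_tbl_rows <- function(x, n) testthat::expect_equal(nrow(x), n)
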