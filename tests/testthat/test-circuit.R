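# series / parallel closed forms use tiny grids where the circuit is exact

test_that("a 1x3 chain behaves as two resistors in series", {
  g <- pan_grid(matrix(1, 1, 3), cell_size = 30)
  cm <- solve_current(g, source_cells = 1L, ground_cells = 3L, injection = 1)
  # all 1 A passes through the middle node
  expect_equal(cm$current$values[1, 2], 1, tolerance = 1e-10)
  edge_cost <- 1 * 30  # conductance g = 1/30 per edge
  v_src <- cm$voltage$values[1, 1]
  expect_equal(v_src / 1, 2 * edge_cost, tolerance = 1e-8)  # R_eff = 2/g
})

test_that("two equal parallel branches split the current in half", {
  # 3x3 ring: source centre-left, ground centre-right, two 2-edge branches
  v <- matrix(NA_real_, 3, 3)
  v[2, 1] <- 1; v[1, 2] <- 1; v[3, 2] <- 1; v[2, 3] <- 1
  g <- pan_grid(v, cell_size = 30)
  src <- which(!is.na(v) & col(v) == 1)
  gnd <- which(!is.na(v) & col(v) == 3)
  cm <- solve_current(g, src, gnd, injection = 1)
  expect_equal(cm$current$values[1, 2], 0.5, tolerance = 1e-10)
  expect_equal(cm$current$values[3, 2], 0.5, tolerance = 1e-10)
  # parallel effective resistance is half the single-branch value
  branch_r <- 2 * sqrt(2) * 30  # two diagonal edges at R = 1
  expect_equal(cm$voltage$values[2, 1], branch_r / 2, tolerance = 1e-8)
})

test_that("voltages match a dense direct solve and Kirchhoff holds on random grids", {
  skip_if_not_installed("MASS")
  set.seed(55)
  vals <- matrix(stats::runif(12 * 12, 1, 60), 12, 12)
  g <- pan_grid(vals, cell_size = 30)
  src <- 1L; gnd <- 144L
  cm <- solve_current(g, src, gnd, injection = 1)
  # independent dense solve: build the Laplacian explicitly from edge costs
  nr <- 12; nc <- 12; n <- nr * nc
  L <- matrix(0, n, n)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    u <- (cc - 1) * nr + r
    for (d in list(c(0, 1, 1), c(1, 0, 1), c(1, 1, sqrt(2)), c(-1, 1, sqrt(2)))) {
      r2 <- r + d[1]; c2 <- cc + d[2]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      w <- 1 / ((vals[r, cc] + vals[r2, c2]) / 2 * 30 * d[3])
      vv <- (c2 - 1) * nr + r2
      L[u, vv] <- L[u, vv] - w; L[vv, u] <- L[vv, u] - w
      L[u, u] <- L[u, u] + w; L[vv, vv] <- L[vv, vv] + w
    }
  }
  b <- numeric(n); b[src] <- 1
  keep <- setdiff(seq_len(n), gnd)
  volts_dense <- numeric(n)
  volts_dense[keep] <- solve(L[keep, keep], b[keep])
  expect_equal(as.vector(cm$voltage$values), volts_dense, tolerance = 1e-8)
  # Kirchhoff: net current zero at every interior node
  net <- L %*% volts_dense
  interior <- setdiff(seq_len(n), c(src, gnd))
  expect_lt(max(abs(net[interior])), 1e-8)
})

test_that("all-to-one on two patches equals the two symmetric pairwise solves", {
  # single-cell patches make the supernode contraction trivial, so the
  # all-to-one map must equal exactly twice one pairwise solve
  set.seed(91)
  g <- pan_grid(matrix(stats::runif(12 * 20, 1, 30), 12, 20), cell_size = 30)
  lab <- matrix(0L, 12, 20); lab[6, 3] <- 1L; lab[6, 18] <- 2L
  patches <- structure(list(labels = grid_like(g, lab),
                            patches = tibble::tibble(id = 1:2, category = NA,
                                                     n_cells = 1L,
                                                     centroid_row = 6,
                                                     centroid_col = c(3, 18),
                                                     area_km2 = 900 / 1e6)),
                       class = "pan_patches")
  cm <- cumulative_current(g, patches)
  one <- solve_current(g, which(lab == 1L), which(lab == 2L), injection = 1)
  free <- lab == 0
  expect_equal(cm$current$values[free], 2 * one$current$values[free],
               tolerance = 1e-8)
  expect_equal(cm$absorbed, 2)
})

test_that("mirror-symmetric landscapes give mirror-symmetric current", {
  ws <- make_walled_strip(nr = 25, nc = 41, wall_col = 21, background = 1, wall = 50)
  cm <- cumulative_current(ws$resistance, ws$patches)
  cur <- cm$current$values
  expect_equal(cur, cur[25:1, ], tolerance = 1e-8)   # vertical mirror
  expect_equal(cur, cur[, 41:1], tolerance = 1e-8)   # horizontal mirror
})

test_that("the bowtie neck carries the global current maximum and is the pinch", {
  bt <- make_bowtie(cell_size = 100, neck_rows = 2)
  patches <- label_patches(bt$pa, bt$resistance)
  expect_equal(nrow(patches$patches), 2)
  cm <- cumulative_current(bt$resistance, patches)
  cur <- cm$current$values
  lab <- patches$labels$values
  free <- lab == 0 & is.finite(cur)
  best <- which(cur == max(cur[free]) & free, arr.ind = TRUE)
  expect_true(all(best[, 1] %in% bt$neck_rows))
  expect_true(all(best[, 2] %in% bt$neck_cols))
  # pinch extraction returns exactly the neck region (>= 0.1 km2 at 100 m cells)
  pinch <- extract_pinch_points(cm, k = 5, min_area_km2 = 0.1, exclude = lab > 0)
  expect_equal(nrow(pinch$points), 1)
  picked <- which(pinch$mask$values == 1, arr.ind = TRUE)
  expect_true(all(picked[, 1] %in% bt$neck_rows))
  expect_true(all(picked[, 2] %in% bt$neck_cols))
})

test_that("degenerate current maps and dominating area filters give empty pinch sets", {
  bt <- make_bowtie()
  patches <- label_patches(bt$pa, bt$resistance)
  cm <- cumulative_current(bt$resistance, patches)
  # min_area larger than any region: empty set
  big <- extract_pinch_points(cm, k = 5, min_area_km2 = 1e6,
                              exclude = patches$labels$values > 0)
  expect_equal(nrow(big$points), 0)
  # constant current: no class separation
  cm2 <- cm
  cm2$current$values[] <- 1
  expect_warning(none <- extract_pinch_points(cm2), "distinct")
  expect_equal(nrow(none$points), 0)
})

test_that("disconnected grounds are reported as singular systems", {
  v <- matrix(1, 5, 5)
  v[, 3] <- NA  # split the grid in two
  g <- pan_grid(v, cell_size = 30)
  expect_error(solve_current(g, source_cells = 1L, ground_cells = 25L),
               "disconnected")
})
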