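mk_simple_patches <- function(g, blocks) {
  lab <- matrix(0L, nrow(g$values), ncol(g$values))
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    lab[b[1]:b[2], b[3]:b[4]] <- i
  }
  structure(list(labels = grid_like(g, lab),
                 patches = tibble::tibble(id = seq_along(blocks))),
            class = "pan_patches")
}

test_that("footprint with no corridors equals the PA share exactly", {
  g <- pan_grid(matrix(1, 20, 20), cell_size = 30)
  patches <- mk_simple_patches(g, list(c(3, 6, 3, 6)))  # 16 cells of 400
  fp <- pan_footprint(patches, paths = NULL)
  expect_equal(fp$coverage_pct, 100 * 16 / 400)
  expect_equal(fp$area_km2, 16 * 900 / 1e6)
  expect_false(fp$meets_target)
})

test_that("coverage is monotone in the corridor threshold and bounded by reach", {
  g <- pan_grid(matrix(1, 20, 40), cell_size = 30)
  patches <- mk_simple_patches(g, list(c(9, 12, 2, 5), c(9, 12, 36, 39)))
  paths <- least_cost_paths(patches, g, pairing = "all_pairs")
  covs <- vapply(c(0, 500, 2000, 8000, Inf), function(t)
    pan_footprint(patches, paths, t = t)$coverage_pct, 0)
  expect_true(all(diff(covs) >= 0))
  expect_lte(max(covs), 100)
  # mean-LCP threshold strictly exceeds the PA-only share on this fixture
  fp <- pan_footprint(patches, paths, t = "mean_lcp")
  expect_gt(fp$coverage_pct, pan_footprint(patches, NULL)$coverage_pct)
  expect_error(pan_footprint(patches, paths, t = -5), "non-negative")
})

test_that("priority-area overlap handles nested, disjoint and half-covered cases", {
  g <- pan_grid(matrix(1, 20, 20), cell_size = 30)
  patches <- mk_simple_patches(g, list(c(1, 10, 1, 20)))  # top half protected
  fp <- pan_footprint(patches, NULL)
  inside <- matrix(FALSE, 20, 20); inside[2:5, 2:5] <- TRUE
  expect_equal(overlap_pct(fp, inside), 100)
  outside <- matrix(FALSE, 20, 20); outside[15:18, 2:5] <- TRUE
  expect_equal(overlap_pct(fp, outside), 0)
  straddle <- matrix(FALSE, 20, 20); straddle[6:15, 3:8] <- TRUE  # half in
  expect_equal(overlap_pct(fp, straddle), 50)
  expect_error(overlap_pct(fp, matrix(FALSE, 20, 20)), "zero cells")
})

test_that("composition shares sum to 100 and match direct counts", {
  lc <- pan_grid(matrix(c(rep(2, 30), rep(1, 50), rep(6, 20)), 10, 10),
                 cell_size = 30)
  fp <- matrix(TRUE, 10, 10)
  comp <- composition(fp, lc)
  expect_equal(sum(comp$share_pct), 100, tolerance = 1e-6)
  expect_equal(comp$share_pct[comp$class == "forest"], 30)
  expect_equal(comp$share_pct[comp$class == "cropland"], 50)
  # single-class footprint
  one <- composition(lc$values == 2, lc)
  expect_equal(one$share_pct[one$class == "forest"], 100)
})

test_that("SDG indicators reduce to closed forms on constructed zones", {
  nr <- 20; nc <- 20
  lc <- pan_grid(matrix(1, nr, nc), cell_size = 30)
  lc$values[1:10, ] <- 2  # top half forest
  dem <- pan_grid(matrix(0, nr, nc), cell_size = 30)
  dem$values[, 11:20] <- 500  # right half mountainous
  bcpa <- matrix(FALSE, nr, nc); bcpa[6:15, 6:15] <- TRUE
  degraded <- matrix(FALSE, nr, nc); degraded[16:20, 1:4] <- TRUE
  zones <- list(all_forest = lc$values == 2,
                lowland = dem$values < 300,
                region = matrix(TRUE, nr, nc))
  ind <- sdg_indicators(zones, lc, dem, bcpa, degraded)
  expect_equal(ind$sdg_15_1_1[ind$zone == "all_forest"], 100)
  # zone without mountain cells: the index is missing, not zero
  expect_true(is.na(ind$sdg_15_4_1[ind$zone == "lowland"]))
  # region row: direct mask arithmetic
  expect_equal(ind$sdg_15_1_2[ind$zone == "region"], 100)
  expect_equal(ind$sdg_15_3_1[ind$zone == "region"], 100 * 20 / 400)
  mg <- dem$values >= 300
  expect_equal(ind$sdg_15_4_1[ind$zone == "region"],
               100 * sum(mg & lc$values == 2) / sum(mg))
  expect_error(sdg_indicators(list(empty = matrix(FALSE, nr, nc)),
                              lc, dem, bcpa, degraded), "zero area")
})

test_that("Spearman matrix reproduces signed monotone and hand-computed tie cases", {
  tbl <- tibble::tibble(up = 1:5, down = 5:1, tied = c(1, 2, 2, 3, 4))
  m <- spearman_matrix(tbl)
  expect_equal(m["up", "down"], -1)
  expect_equal(m["up", "up"], 1)
  expect_true(isSymmetric(m))
  # hand computation with average ranks: ranks(tied) = 1, 2.5, 2.5, 4, 5
  r1 <- 1:5; r2 <- c(1, 2.5, 2.5, 4, 5)
  hand <- sum((r1 - 3) * (r2 - 3)) / sqrt(sum((r1 - 3)^2) * sum((r2 - 3)^2))
  expect_equal(m["up", "tied"], hand, tolerance = 1e-12)
  # constant column: undefined, reported missing
  m2 <- spearman_matrix(tibble::tibble(a = 1:4, b = rep(2, 4)))
  expect_true(is.na(m2["a", "b"]))
  expect_error(spearman_matrix(tibble::tibble(a = 1:3, b = 3:1)), "at least 4")
})

test_that("indicators depend on masks only, not on resistance scaling", {
  b <- generate_landscape(landscape_config(nrows = 80, ncols = 80, seed = 3,
                                           n_pa = 3, n_roads = 2,
                                           n_settlements = 3,
                                           planted_corridors = list()))
  lc <- b$landcover
  land <- b$land_mask$values > 0
  bcpa <- rasterize_features(b$bcpa_polygons, lc)$values != 0
  zones <- list(region = land)
  i1 <- sdg_indicators(zones, lc, b$dem, bcpa, b$degraded$values > 0)
  i2 <- sdg_indicators(zones, lc, b$dem, bcpa, b$degraded$values > 0)
  expect_identical(i1, i2)
  # subzone table feeds the correlation analysis with one row per tile
  sub <- subzone_indicators(lc, b$dem, bcpa, b$degraded$values > 0,
                            valid_mask = land)
  expect_gte(nrow(sub), 4)
  expect_true(all(grepl("^tile", sub$zone)))
  m <- spearman_matrix(sub, cols = grep("^sdg", names(sub), value = TRUE))
  expect_true(all(abs(m[!is.na(m)]) <= 1 + 1e-12))
})
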