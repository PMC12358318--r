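test_that("patch labelling merges by 8-connectivity and reports areas", {
  tmpl <- pan_grid(matrix(0, 20, 20), cell_size = 30)
  sq <- function(r1, r2, c1, c2) {
    s <- tmpl$cell_size
    feat_polygon(cbind(c((c1 - 1) * s, c2 * s, c2 * s, (c1 - 1) * s),
                       c(tmpl$origin[2] - (r1 - 1) * s, tmpl$origin[2] - (r1 - 1) * s,
                         tmpl$origin[2] - r2 * s, tmpl$origin[2] - r2 * s)),
                 id = 1, category = "forest park")
  }
  one <- label_patches(pan_vector(list(sq(3, 6, 3, 6))), tmpl)
  expect_equal(nrow(one$patches), 1)
  expect_equal(one$patches$n_cells, 16L)
  expect_equal(one$patches$area_km2, 16 * 900 / 1e6)
  expect_equal(one$patches$category, "forest park")

  # diagonal touch merges under 8-connectivity
  two_diag <- pan_vector(list(sq(3, 5, 3, 5), sq(6, 8, 6, 8)))
  expect_equal(nrow(label_patches(two_diag, tmpl)$patches), 1)
  # separated by one cell: two patches
  two_apart <- pan_vector(list(sq(3, 5, 3, 5), sq(3, 5, 8, 10)))
  expect_equal(nrow(label_patches(two_apart, tmpl)$patches), 2)
  expect_error(label_patches(pan_vector(), tmpl), "empty")
})

test_that("uniform-surface cost distances have the 30 / 30*sqrt(2) closed forms", {
  R1 <- pan_grid(matrix(1, 10, 10), cell_size = 30)
  cd <- cost_distance(R1, 1L)  # source at (1,1)
  expect_equal(cd$cwd$values[1, 1], 0)
  expect_equal(cd$cwd$values[2, 1], 30)
  expect_equal(cd$cwd$values[1, 2], 30)
  expect_equal(cd$cwd$values[2, 2], 30 * sqrt(2))
  expect_equal(cd$cwd$values[1, 10], 9 * 30)
  expect_error(cost_distance(R1, integer(0)), "no source")
})

test_that("cost-distance fields equal an independent shortest-path oracle", {
  skip_if_not_installed("igraph")
  set.seed(77)
  for (rep in 1:6) {
    nr <- sample(8:15, 1); nc <- sample(8:15, 1)
    vals <- matrix(stats::runif(nr * nc, 1, 100), nr, nc)
    if (rep > 3) vals[sample(nr * nc, 5)] <- NA  # impassable holes
    src <- sample(which(!is.na(vals)), 1)
    got <- cost_distance(pan_grid(vals, cell_size = 30), src)$cwd$values
    want <- igraph_cwd(vals, 30, src)
    ok <- !is.na(vals)
    expect_equal(as.vector(got)[ok], unname(want[ok]), tolerance = 1e-9)
  }
})

test_that("least-cost paths are symmetric, straight on uniform surfaces, and oracle-exact", {
  ws <- make_walled_strip(wall_col = 21, background = 2, wall = 2)  # uniform R = 2
  paths <- least_cost_paths(ws$patches, ws$resistance, pairing = "all_pairs")
  expect_equal(nrow(paths$paths), 1)
  p <- paths$paths[1, ]
  # straight grid geodesic between facing patch edges: 30 horizontal steps
  # at uniform step cost R * cell_size
  expect_equal(p$cost, 2 * 30 * 30, tolerance = 1e-9)
  expect_equal(p$ratio, 2, tolerance = 1e-9)
  # symmetry of the pair cost
  cwd1 <- cost_distance(ws$resistance, ws$patches$labels$values == 1)$cwd$values
  cwd2 <- cost_distance(ws$resistance, ws$patches$labels$values == 2)$cwd$values
  expect_equal(min(cwd1[ws$patches$labels$values == 2]),
               min(cwd2[ws$patches$labels$values == 1]), tolerance = 1e-9)
})

test_that("corridor rasters are zero on the path, non-negative, and threshold correctly", {
  set.seed(13)
  vals <- matrix(stats::runif(20 * 20, 1, 50), 20, 20)
  g <- pan_grid(vals, cell_size = 30)
  lab <- matrix(0L, 20, 20); lab[9:11, 2:3] <- 1L; lab[9:11, 18:19] <- 2L
  patches <- structure(list(labels = grid_like(g, lab),
                            patches = tibble::tibble(id = 1:2, category = NA,
                                                     n_cells = 6L, centroid_row = 10,
                                                     centroid_col = c(2.5, 18.5),
                                                     area_km2 = 6 * 900 / 1e6)),
                       class = "pan_patches")
  paths <- least_cost_paths(patches, g, pairing = "all_pairs")
  corr <- corridor_raster(paths, 1)
  free <- lab == 0 & is.finite(corr$values)
  expect_true(all(corr$values[free] >= -1e-9))
  pc <- paths$paths$cells[[1]]
  expect_true(all(abs(corr$values[pc[lab[pc] == 0]]) < 1e-9))
  # t = 0 keeps exactly the zero set; t = Inf keeps all reachable cells
  m0 <- threshold_corridor(corr, 0)
  expect_true(all(corr$values[m0] <= 1e-12))
  mInf <- threshold_corridor(corr, Inf)
  expect_equal(sum(mInf), sum(is.finite(corr$values)))
  expect_error(threshold_corridor(corr, -1), "non-negative")
})

test_that("cost scaling leaves paths and classes unchanged, scales costs linearly", {
  set.seed(14)
  vals <- matrix(stats::runif(18 * 18, 1, 40), 18, 18)
  g1 <- pan_grid(vals, cell_size = 30)
  g2 <- pan_grid(vals * 3.7, cell_size = 30)
  lab <- matrix(0L, 18, 18); lab[3:4, 3:4] <- 1L; lab[14:15, 14:15] <- 2L
  mkp <- function(g) structure(list(labels = grid_like(g, lab),
                                    patches = tibble::tibble(id = 1:2, category = NA,
                                                             n_cells = 4L,
                                                             centroid_row = c(3.5, 14.5),
                                                             centroid_col = c(3.5, 14.5),
                                                             area_km2 = 4 * 900 / 1e6)),
                               class = "pan_patches")
  p1 <- least_cost_paths(mkp(g1), g1, pairing = "all_pairs")
  p2 <- least_cost_paths(mkp(g2), g2, pairing = "all_pairs")
  expect_equal(p2$paths$cost, p1$paths$cost * 3.7, tolerance = 1e-9)
  expect_equal(p2$paths$ratio, p1$paths$ratio * 3.7, tolerance = 1e-9)
  expect_identical(p1$paths$cells, p2$paths$cells)
})

test_that("adjacent-allocation pairing links neighbouring patches only", {
  # three patches in a row on a uniform surface: 1-2 and 2-3 share allocation
  # boundaries; 1-3 do not
  g <- pan_grid(matrix(1, 15, 45), cell_size = 30)
  lab <- matrix(0L, 15, 45)
  lab[7:9, 2:4] <- 1L; lab[7:9, 21:23] <- 2L; lab[7:9, 41:43] <- 3L
  patches <- structure(list(labels = grid_like(g, lab),
                            patches = tibble::tibble(id = 1:3, category = NA,
                                                     n_cells = 9L, centroid_row = 8,
                                                     centroid_col = c(3, 22, 42),
                                                     area_km2 = 9 * 900 / 1e6)),
                       class = "pan_patches")
  paths <- least_cost_paths(patches, g, pairing = "adjacent_allocation")
  got <- paths$paths[c("patch_a", "patch_b")]
  expect_true(all(apply(got, 1, paste, collapse = "-") %in% c("1-2", "2-3")))
  expect_equal(nrow(got), 2)
  all_pairs <- least_cost_paths(patches, g, pairing = "all_pairs")
  expect_equal(nrow(all_pairs$paths), 3)
})

test_that("ratio classification gives three ordered classes or collapses with warning", {
  fake_paths <- function(ratios) {
    structure(list(paths = tibble::tibble(patch_a = 1, patch_b = 2,
                                          cost = ratios, length_m = 1,
                                          ratio = ratios,
                                          cells = replicate(length(ratios), 1L,
                                                            simplify = FALSE)),
                   cwd = list(), patchset = NULL), class = "pan_paths")
  }
  cls <- classify_ratios(fake_paths(c(1, 1.1, 5, 5.2, 20)))$paths$ratio_class
  expect_equal(as.character(cls), c("low", "low", "medium", "medium", "high"))
  expect_warning(one <- classify_ratios(fake_paths(c(2, 2, 2))), "one class")
  expect_equal(length(unique(one$paths$ratio_class)), 1)
})
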