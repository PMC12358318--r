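#' Label protected-area patches on the grid
#'
#' Rasterizes PA polygons onto the template and labels 8-connected
#' components; polygons sharing cells merge into one patch. Labels are
#' dense `1..P` in row-major discovery order.
#'
#' @param pa a `pan_vector` of PA polygons (attributes `id`, `category`
#'   are carried through when present).
#' @param template a `pan_grid`.
#' @param valid_mask optional logical matrix of analyzable cells; patch
#'   cells falling outside it are dropped.
#' @return an object of class `pan_patches`: `labels` (`pan_grid` of patch
#'   ids, 0 = background) and `patches` (tibble: id, category, n_cells,
#'   area_km2, centroid row/col).
#' @export
label_patches <- function(pa, template, valid_mask = NULL) {
  stopifnot(inherits(pa, "pan_vector"))
  if (length(pa$features) == 0) stop("PA layer is empty")
  burned <- rasterize_features(pa, template)
  mask <- burned$values != 0
  if (!is.null(valid_mask)) mask <- mask & valid_mask
  if (!any(mask)) stop("no PA cells after rasterization")
  lab <- cpp_label8(mask)
  P <- max(lab)
  s <- template$cell_size
  # majority polygon category per patch
  cat_of <- rep(NA_character_, P)
  for (f in pa$features) {
    if (f$type != "polygon" || is.null(f$attrs$category)) next
    cc <- grid_coords(template)
    hit <- cpp_points_in_ring(cc$x, cc$y, f$coords[, 1], f$coords[, 2])
    ids <- unique(lab[cbind(cc$row[hit], cc$col[hit])])
    ids <- ids[ids > 0]
    cat_of[ids][is.na(cat_of[ids])] <- f$attrs$category
  }
  rows <- matrix(rep(seq_len(nrow(lab)), ncol(lab)), nrow(lab))
  cols <- matrix(rep(seq_len(ncol(lab)), each = nrow(lab)), nrow(lab))
  patches <- tibble::tibble(
    id = seq_len(P),
    category = cat_of,
    n_cells = as.integer(tabulate(lab[lab > 0], P)),
    centroid_row = vapply(seq_len(P), function(i) mean(rows[lab == i]), 0),
    centroid_col = vapply(seq_len(P), function(i) mean(cols[lab == i]), 0))
  patches$area_km2 <- patches$n_cells * s^2 / 1e6
  structure(list(labels = grid_like(template, lab), patches = patches),
            class = "pan_patches")
}

#' @exportS3Method base::print
print.pan_patches <- function(x, ...) {
  cat(sprintf("<pan_patches> %d patch(es), %.2f km2 total\n",
              nrow(x$patches), sum(x$patches$area_km2)))
  invisible(x)
}

#' Cost-weighted distance from source cells
#'
#' Multi-source Dijkstra over the 8-connected grid graph; the step cost
#' between adjacent cells is the mean of their resistances times the cell
#' size (times sqrt(2) on diagonals), so the accumulated value is in
#' resistance-metre units. `NA` resistance (sea/nodata) is impassable.
#' Ties settle in (row, col) order, making the backlink field deterministic.
#'
#' @param resistance a `pan_resistance` or `pan_grid`.
#' @param sources integer cell indices (column-major) or a logical matrix.
#' @return an object of class `pan_costdist`: `cwd` grid (Inf where
#'   unreachable), `back` predecessor grid (0-based column-major cell index,
#'   -1 at sources and unreached cells).
#' @export
cost_distance <- function(resistance, sources) {
  R <- if (inherits(resistance, "pan_resistance")) resistance$grid else resistance
  stopifnot(inherits(R, "pan_grid"))
  if (is.matrix(sources)) sources <- which(sources)
  if (length(sources) == 0) stop("no source cells")
  if (all(is.na(R$values[sources]))) stop("all source cells are nodata")
  res <- cpp_cost_distance(R$values, as.integer(sources - 1L), R$cell_size)
  structure(list(cwd = grid_like(R, res$cwd), back = grid_like(R, res$back)),
            class = "pan_costdist")
}

# walk the backlink field from cell idx (1-based) down to a source
trace_back <- function(cd, idx) {
  back <- cd$back$values
  path <- integer(0)
  cur <- idx
  repeat {
    path <- c(path, cur)
    nxt <- back[cur]
    if (nxt < 0) break
    cur <- nxt + 1L
  }
  path
}

path_length_m <- function(grid, cells) {
  if (length(cells) < 2) return(0)
  rc <- cell_rowcol(grid, cells)
  steps <- sqrt(diff(rc[, 1])^2 + diff(rc[, 2])^2)
  sum(steps) * grid$cell_size
}

#' Least-cost paths between protected-area patches
#'
#' Computes a cost-distance field per patch (patch cells as a merged
#' source), selects patch pairs, and backtracks the least-cost path of each
#' pair through the cell minimising `cwd_a + cwd_b`. Under the default
#' `"adjacent_allocation"` pairing a pair is linked iff their minimum-cwd
#' allocation regions share an 8-neighbour boundary, which yields the sparse
#' planar linkage set of standard corridor-mapping practice;
#' `"all_pairs"` links every reachable pair, `"max_neighbors"` keeps each
#' patch's `k` cheapest links.
#'
#' @param patchset a `pan_patches`.
#' @param resistance a `pan_resistance` or `pan_grid`.
#' @param pairing pairing rule.
#' @param k neighbour cap for `"max_neighbors"`.
#' @return an object of class `pan_paths`: `paths` tibble (patch_a, patch_b,
#'   cost, length_m, ratio, cells list-column), the per-patch `cwd` fields,
#'   and the patch set. Unreachable pairs are dropped with a warning.
#' @export
least_cost_paths <- function(patchset, resistance,
                             pairing = c("adjacent_allocation", "all_pairs",
                                         "max_neighbors"),
                             k = 4) {
  pairing <- match.arg(pairing)
  stopifnot(inherits(patchset, "pan_patches"))
  R <- if (inherits(resistance, "pan_resistance")) resistance$grid else resistance
  lab <- patchset$labels$values
  P <- nrow(patchset$patches)
  if (P < 2) stop("need at least two patches")
  fields <- lapply(seq_len(P), function(i) cost_distance(R, lab == i))
  cwds <- lapply(fields, function(f) f$cwd$values)

  pairs <- if (pairing == "all_pairs") {
    which(upper.tri(matrix(0, P, P)), arr.ind = TRUE)
  } else if (pairing == "adjacent_allocation") {
    stack <- array(unlist(cwds), dim = c(nrow(lab), ncol(lab), P))
    alloc <- apply(stack, c(1, 2), function(v)
      if (all(!is.finite(v))) NA_integer_ else which.min(v))
    adj <- matrix(FALSE, P, P)
    nr <- nrow(alloc); nc <- ncol(alloc)
    for (sh in list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))) {
      a <- alloc[seq_len(nr - abs(sh[1])) + max(0, sh[1]),
                 seq_len(nc - abs(sh[2])) + max(0, sh[2]), drop = FALSE]
      b <- alloc[seq_len(nr - abs(sh[1])) + max(0, -sh[1]),
                 seq_len(nc - abs(sh[2])) + max(0, -sh[2]), drop = FALSE]
      ok <- !is.na(a) & !is.na(b) & a != b
      if (any(ok)) {
        ij <- cbind(pmin(a[ok], b[ok]), pmax(a[ok], b[ok]))
        adj[unique(ij, MARGIN = 1)] <- TRUE
      }
    }
    which(adj, arr.ind = TRUE)
  } else {
    cost_mat <- matrix(Inf, P, P)
    for (i in seq_len(P)) for (j in seq_len(P)) if (i != j)
      cost_mat[i, j] <- suppressWarnings(min(cwds[[i]][lab == j]))
    keep <- matrix(FALSE, P, P)
    for (i in seq_len(P)) {
      ord <- order(cost_mat[i, ])[seq_len(min(k, P - 1))]
      keep[cbind(i, ord)] <- TRUE
    }
    keep <- keep | t(keep)
    keep[lower.tri(keep, diag = TRUE)] <- FALSE
    which(keep, arr.ind = TRUE)
  }
  if (nrow(pairs) == 0) stop("no patch pairs selected")
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]

  rows <- list(); dropped <- 0L
  for (r in seq_len(nrow(pairs))) {
    a <- pairs[r, 1]; b <- pairs[r, 2]
    total <- cwds[[a]] + cwds[[b]]
    total[lab == a | lab == b] <- NA  # meet outside the sources
    fin <- is.finite(total)
    if (!any(fin)) { dropped <- dropped + 1L; next }
    # deterministic argmin: smallest (row, col) among minima
    mval <- min(total[fin])
    cand <- which(fin & total <= mval + 1e-9)
    rc <- cell_rowcol(patchset$labels, cand)
    cand <- cand[order(rc[, 1], rc[, 2])][1]
    pa_cells <- trace_back(fields[[a]], cand)
    pb_cells <- trace_back(fields[[b]], cand)
    cells <- c(rev(pa_cells), pb_cells[-1])
    cost <- cwds[[a]][cand] + cwds[[b]][cand]
    len <- path_length_m(patchset$labels, cells)
    rows[[length(rows) + 1]] <- tibble::tibble(
      patch_a = a, patch_b = b, cost = cost, length_m = len,
      ratio = cost / max(len, patchset$labels$cell_size),
      cells = list(cells))
  }
  if (dropped > 0)
    warning(dropped, " unreachable pair(s) dropped (infinite cost)")
  if (length(rows) == 0) stop("no reachable patch pairs")
  structure(list(paths = dplyr::bind_rows(rows),
                 cwd = lapply(fields, function(f) f$cwd),
                 patchset = patchset),
            class = "pan_paths")
}

#' @exportS3Method base::print
print.pan_paths <- function(x, ...) {
  cat(sprintf("<pan_paths> %d least-cost path(s) among %d patches; mean cost %.1f, mean length %.0f m\n",
              nrow(x$paths), nrow(x$patchset$patches),
              mean(x$paths$cost), mean(x$paths$length_m)))
  invisible(x)
}

#' Normalized least-cost corridor raster for one pair
#'
#' `nlcc(x) = cwd_a(x) + cwd_b(x) - cost(a,b)`: zero on the least-cost path
#' and growing outward; thresholding gives a corridor of finite width.
#'
#' @param paths a `pan_paths`.
#' @param which_pair row index into `paths$paths`.
#' @return a `pan_grid` (Inf where either side is unreachable).
#' @export
corridor_raster <- function(paths, which_pair) {
  stopifnot(inherits(paths, "pan_paths"))
  p <- paths$paths[which_pair, ]
  nl <- paths$cwd[[p$patch_a]]$values + paths$cwd[[p$patch_b]]$values - p$cost
  grid_like(paths$cwd[[1]], nl)
}

#' Cell-wise minimum corridor value over all pairs
#' @param paths a `pan_paths`.
#' @return a `pan_grid` of `min` over pairs of the normalized corridor value.
#' @export
corridor_min_raster <- function(paths) {
  stopifnot(inherits(paths, "pan_paths"))
  acc <- NULL
  for (r in seq_len(nrow(paths$paths))) {
    nl <- corridor_raster(paths, r)$values
    acc <- if (is.null(acc)) nl else pmin(acc, nl)
  }
  grid_like(paths$cwd[[1]], acc)
}

#' Threshold a corridor raster into a mask
#' @param corridor `pan_grid` of normalized corridor values.
#' @param t threshold in cost-weighted-distance units (>= 0).
#' @return logical matrix mask (`nlcc <= t`).
#' @export
threshold_corridor <- function(corridor, t) {
  if (t < 0) stop("corridor threshold must be non-negative")
  m <- corridor$values <= t
  m[!is.finite(corridor$values)] <- FALSE
  m
}

#' Classify path cost:length ratios into three resistance classes
#'
#' Jenks k = 3 on the cost-to-length ratio of every path: low, medium and
#' high relative resistance. Fewer than three distinct ratios collapse to a
#' single class with a warning.
#'
#' @param paths a `pan_paths`.
#' @return the `pan_paths` with a `ratio_class` factor column added.
#' @export
classify_ratios <- function(paths) {
  stopifnot(inherits(paths, "pan_paths"))
  r <- paths$paths$ratio
  lev <- c("low", "medium", "high")
  if (length(unique(r)) < 3) {
    warning("fewer than 3 distinct ratios; all paths in one class")
    paths$paths$ratio_class <- factor(rep("low", length(r)), levels = lev)
  } else {
    cls <- jenks_classify(r, jenks_breaks(r, 3))
    paths$paths$ratio_class <- factor(lev[cls], levels = lev)
  }
  paths
}

#' Export least-cost paths as a GeoJSON-ready vector layer
#' @param paths a `pan_paths`.
#' @return a `pan_vector` of polylines with path attributes.
#' @export
paths_as_vector <- function(paths) {
  g <- paths$cwd[[1]]
  feats <- lapply(seq_len(nrow(paths$paths)), function(i) {
    p <- paths$paths[i, ]
    rc <- cell_rowcol(g, p$cells[[1]])
    xy <- cbind(g$origin[1] + (rc[, 2] - 0.5) * g$cell_size,
                g$origin[2] - (rc[, 1] - 0.5) * g$cell_size)
    feat_polyline(xy, patch_a = p$patch_a, patch_b = p$patch_b,
                  cost = p$cost, length_m = p$length_m, ratio = p$ratio)
  })
  pan_vector(feats, crs_id = g$crs_id)
}
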