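#' Connectivity improvement from restoring one circular window
#'
#' Sets every cell of the circular window (centre cell + radius in metres)
#' to the landscape's minimum valid resistance, re-solves the least-cost
#' distance between the two patches, and returns the drop in linkage cost
#' `cost(pair) - cost_restored(pair)` (never negative). This is the exact
#' re-solve, not a boundary approximation.
#'
#' @param resistance a `pan_resistance` or `pan_grid`.
#' @param patchset a `pan_patches`.
#' @param pair integer 2-vector of patch ids.
#' @param center cell index (column-major) of the window centre.
#' @param radius_m window radius in metres (>= one cell).
#' @param pair_cost optional precomputed `cost(pair)` to avoid one solve.
#' @return improvement in CWD units.
#' @export
improvement_score <- function(resistance, patchset, pair, center, radius_m,
                              pair_cost = NULL) {
  R <- if (inherits(resistance, "pan_resistance")) resistance$grid else resistance
  if (radius_m < R$cell_size) stop("window radius must be at least one cell")
  lab <- patchset$labels$values
  src <- which(lab == pair[1]) - 1L
  dst <- which(lab == pair[2]) - 1L
  rmin <- min(R$values, na.rm = TRUE)
  rc <- cell_rowcol(R, center)
  win <- which(disk_cells(nrow(R$values), ncol(R$values), R$cell_size,
                          c(rc[1], rc[2]), radius_m) & is.finite(R$values))
  if (is.null(pair_cost))
    pair_cost <- cpp_cost_between(R$values, src, dst, integer(0), 0, R$cell_size)
  restored <- cpp_cost_between(R$values, src, dst, win - 1L, rmin, R$cell_size)
  max(0, pair_cost - restored)
}

#' Moving-window barrier scan
#'
#' For every candidate cell (cells whose normalized corridor value is within
#' `extent` of some linkage) and every detection radius, computes the
#' least-cost improvement from restoring the window to minimum resistance,
#' and keeps the maximum over radii and linkages. Cells outside every
#' corridor search extent score 0. The default radii {100, 300, 500} m
#' follow the min 100 / max 500 / step 200 moving-window convention.
#'
#' @param resistance a `pan_resistance` or `pan_grid`.
#' @param paths a `pan_paths` (with per-pair cwd fields).
#' @param radii_m detection radii in metres.
#' @param extent corridor search extent in CWD units (default 10000).
#' @param per_meter if `TRUE`, scores are divided by the window diameter
#'   (improvement per metre restored).
#' @param aggregate `"max"` (default) or `"sum"` over linkages.
#' @return an object of class `pan_barrierfield`: `score` grid, `radii_m`,
#'   `extent`.
#' @export
scan_barriers <- function(resistance, paths, radii_m = c(100, 300, 500),
                          extent = 10000, per_meter = FALSE,
                          aggregate = c("max", "sum")) {
  aggregate <- match.arg(aggregate)
  R <- if (inherits(resistance, "pan_resistance")) resistance$grid else resistance
  stopifnot(inherits(paths, "pan_paths"))
  if (nrow(paths$paths) < 1) stop("need at least one least-cost path")
  nr <- nrow(R$values); nc <- ncol(R$values); s <- R$cell_size
  rmin <- min(R$values, na.rm = TRUE)
  lab <- paths$patchset$labels$values
  score <- matrix(0, nr, nc)
  # precompute window offsets per radius (row/col deltas)
  offs <- lapply(radii_m, function(rad) {
    k <- floor(rad / s)
    d <- expand.grid(dr = -k:k, dc = -k:k)
    d[sqrt(d$dr^2 + d$dc^2) * s <= rad, , drop = FALSE]
  })
  for (p in seq_len(nrow(paths$paths))) {
    pr <- paths$paths[p, ]
    a <- pr$patch_a; b <- pr$patch_b
    nl <- paths$cwd[[a]]$values + paths$cwd[[b]]$values - pr$cost
    cand <- which(is.finite(nl) & nl <= extent & lab == 0)
    if (!length(cand)) next
    src <- which(lab == a) - 1L
    dst <- which(lab == b) - 1L
    cand_rc <- cell_rowcol(R, cand)
    for (ri in seq_along(radii_m)) {
      off <- offs[[ri]]
      for (ci in seq_along(cand)) {
        rr <- cand_rc[ci, 1] + off$dr
        cc <- cand_rc[ci, 2] + off$dc
        ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
        win <- rr[ok] + (cc[ok] - 1L) * nr
        win <- win[is.finite(R$values[win])]
        if (!length(win)) next
        if (max(R$values[win]) <= rmin) next  # already minimal: improvement 0
        restored <- cpp_cost_between(R$values, src, dst, win - 1L, rmin, s)
        imp <- max(0, pr$cost - restored)
        if (per_meter) imp <- imp / (2 * radii_m[ri])
        cell <- cand[ci]
        score[cell] <- if (aggregate == "max") max(score[cell], imp) else score[cell] + imp
      }
    }
  }
  structure(list(score = grid_like(R, score), radii_m = radii_m,
                 extent = extent, per_meter = per_meter),
            class = "pan_barrierfield")
}

#' @exportS3Method base::print
print.pan_barrierfield <- function(x, ...) {
  cat(sprintf("<pan_barrierfield> radii {%s} m, max score %.1f\n",
              paste(x$radii_m, collapse = ", "), max(x$score$values)))
  invisible(x)
}

#' Extract barrier points from an improvement field
#'
#' Jenks k classes on the positive improvement scores; 8-connected regions
#' of top-class cells with area at least `min_area_km2` are reported by
#' their geometric centre (centroid).
#'
#' @param field a `pan_barrierfield`.
#' @param k number of Jenks classes (default 5).
#' @param min_area_km2 minimum region area (default 0.05).
#' @return an object of class `pan_barriers`: `points` tibble (region,
#'   n_cells, area_km2, max_score, centroid row/col/x/y) and `mask` grid.
#' @export
extract_barrier_points <- function(field, k = 5, min_area_km2 = 0.05) {
  stopifnot(inherits(field, "pan_barrierfield"))
  g <- field$score
  pos <- g$values[is.finite(g$values) & g$values > 0]
  empty <- tibble::tibble(region = integer(), n_cells = integer(),
                          area_km2 = numeric(), max_score = numeric(),
                          centroid_row = numeric(), centroid_col = numeric(),
                          x = numeric(), y = numeric())
  mk <- function(points, mask, rule)
    structure(list(points = points, mask = grid_like(g, mask), breaks = rule,
                   k = k, min_area_km2 = min_area_km2), class = "pan_barriers")
  if (length(pos) == 0)
    return(mk(empty, matrix(0, nrow(g$values), ncol(g$values)), NULL))
  if (length(unique(pos)) < k) {
    warning("fewer than ", k, " distinct positive scores; no barrier points")
    return(mk(empty, matrix(0, nrow(g$values), ncol(g$values)), NULL))
  }
  rule <- jenks_breaks(pos, k)
  cls_all <- matrix(NA_integer_, nrow(g$values), ncol(g$values))
  posm <- is.finite(g$values) & g$values > 0
  cls_all[posm] <- jenks_classify(g$values[posm], rule)
  top <- !is.na(cls_all) & cls_all == k
  labm <- cpp_label8(top)
  s <- g$cell_size
  rows <- list(); keep <- matrix(0, nrow(g$values), ncol(g$values)); rid <- 0
  for (i in seq_len(max(labm))) {
    cells <- which(labm == i)
    area <- length(cells) * s^2 / 1e6
    if (area < min_area_km2) next
    rid <- rid + 1
    rc <- cell_rowcol(g, cells)
    keep[cells] <- rid
    rows[[rid]] <- tibble::tibble(
      region = rid, n_cells = length(cells), area_km2 = area,
      max_score = max(g$values[cells]),
      centroid_row = mean(rc[, 1]), centroid_col = mean(rc[, 2]),
      x = g$origin[1] + (mean(rc[, 2]) - 0.5) * s,
      y = g$origin[2] - (mean(rc[, 1]) - 0.5) * s)
  }
  mk(if (rid) dplyr::bind_rows(rows) else empty, keep, rule)
}

#' @exportS3Method base::print
print.pan_barriers <- function(x, ...) {
  cat(sprintf("<pan_barriers> %d barrier point(s)\n", nrow(x$points)))
  invisible(x)
}
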