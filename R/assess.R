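#' Protected-area-network footprint and coverage
#'
#' The PAN footprint is the union of the PA patches and every cell whose
#' minimum normalized corridor value is within the corridor cost threshold
#' `t` (conventionally the mean least-cost distance between PA patches).
#' Coverage is reported against the study area (valid land cells) and
#' checked against an area target, by default the 30% protection target.
#'
#' @param patchset a `pan_patches`.
#' @param paths a `pan_paths`; may be `NULL` to assess PAs alone.
#' @param t corridor threshold in CWD units; `"mean_lcp"` (default) uses
#'   the mean least-cost path cost.
#' @param study_mask logical matrix of study-area cells (default: all
#'   cells with a finite corridor or patch value... i.e. valid land).
#' @param target_pct coverage target in percent (default 30).
#' @return an object of class `pan_footprint`: `mask` grid, `threshold_used`,
#'   `area_km2`, `coverage_pct`, `target_pct`, `meets_target`.
#' @export
pan_footprint <- function(patchset, paths = NULL, t = "mean_lcp",
                          study_mask = NULL, target_pct = 30) {
  stopifnot(inherits(patchset, "pan_patches"))
  lab <- patchset$labels$values
  if (is.null(paths) && !any(lab > 0)) stop("no PAs and no corridors: footprint undefined")
  fp <- lab > 0
  thr <- 0
  if (!is.null(paths)) {
    if (identical(t, "mean_lcp")) thr <- mean(paths$paths$cost) else thr <- as.numeric(t)
    if (thr < 0) stop("corridor threshold must be non-negative")
    nl <- corridor_min_raster(paths)$values
    fp <- fp | (is.finite(nl) & nl <= thr)
  }
  if (is.null(study_mask)) study_mask <- !is.na(patchset$labels$values)
  fp <- fp & study_mask
  s <- patchset$labels$cell_size
  area <- sum(fp) * s^2 / 1e6
  cov <- 100 * sum(fp) / sum(study_mask)
  structure(list(mask = grid_like(patchset$labels, fp * 1),
                 threshold_used = thr, area_km2 = area, coverage_pct = cov,
                 target_pct = target_pct, meets_target = cov >= target_pct),
            class = "pan_footprint")
}

#' @exportS3Method base::print
print.pan_footprint <- function(x, ...) {
  cat(sprintf("<pan_footprint> %.2f km2, %.2f%% of study area (target %g%%: %s)\n",
              x$area_km2, x$coverage_pct, x$target_pct,
              if (x$meets_target) "met" else "not met"))
  invisible(x)
}

#' Overlap of a footprint with priority-area polygons
#'
#' @param footprint a `pan_footprint` (or logical matrix).
#' @param bcpa a `pan_vector` of priority-area polygons (or logical matrix).
#' @param template grid for rasterization when masks are matrices.
#' @return percentage of the priority area covered by the footprint.
#' @export
overlap_pct <- function(footprint, bcpa, template = NULL) {
  fm <- if (inherits(footprint, "pan_footprint")) footprint$mask$values > 0 else footprint
  tmpl <- if (inherits(footprint, "pan_footprint")) footprint$mask else template
  bm <- if (inherits(bcpa, "pan_vector")) {
    if (length(bcpa$features) == 0) stop("priority-area layer is empty")
    rasterize_features(bcpa, tmpl)$values != 0
  } else bcpa
  if (!any(bm)) stop("priority area rasterizes to zero cells")
  100 * sum(bm & fm) / sum(bm)
}

#' Land-cover composition of a footprint
#'
#' @param footprint a `pan_footprint` or logical matrix.
#' @param landcover a `pan_grid` of land-cover codes.
#' @param legend tibble mapping `code` to `class` (default
#'   [landcover_codes()]).
#' @return tibble with `class`, `n_cells`, `share_pct` (sums to 100).
#' @export
composition <- function(footprint, landcover, legend = landcover_codes()) {
  fm <- if (inherits(footprint, "pan_footprint")) footprint$mask$values > 0 else footprint
  codes <- landcover$values[fm]
  codes <- codes[!is.na(codes)]
  tab <- table(factor(codes, levels = legend$code))
  tibble::tibble(class = legend$class,
                 n_cells = as.integer(tab),
                 share_pct = 100 * as.integer(tab) / max(1, length(codes)))
}

#' SDG 15 indicator capacities per zone
#'
#' Computes four coverage-based indicators for each zone mask:
#' \itemize{
#'   \item \strong{sdg_15_1_1} forest share of the zone (percent);
#'   \item \strong{sdg_15_1_2} share of the important-biodiversity
#'     (priority) area lying inside the zone;
#'   \item \strong{sdg_15_3_1} degraded-land share of the zone (polarity:
#'     lower is better, reported as-is);
#'   \item \strong{sdg_15_4_1} mountain green cover index: share of zone
#'     cells above the mountain elevation threshold covered by green
#'     classes (forest, grassland, wetland); `NA` when the zone has no
#'     mountain cells.
#' }
#'
#' @param zones named list of logical matrices (e.g. PA, PAN, region).
#' @param landcover a `pan_grid` of codes.
#' @param dem elevation grid (metres).
#' @param bcpa_mask logical matrix of priority-area cells.
#' @param degraded_mask logical matrix of degraded cells.
#' @param mountain_elev_m elevation threshold in metres (default 300).
#' @param green_codes land-cover codes counted as green cover.
#' @param forest_codes land-cover codes counted as forest.
#' @return tibble: one row per zone, indicator columns in percent.
#' @export
sdg_indicators <- function(zones, landcover, dem, bcpa_mask, degraded_mask,
                           mountain_elev_m = 300,
                           green_codes = c(2, 3, 7), forest_codes = 2) {
  lc <- landcover$values
  rows <- lapply(names(zones), function(nm) {
    z <- zones[[nm]] & !is.na(lc)
    nz <- sum(z)
    if (nz == 0) stop("zone '", nm, "' has zero area")
    forest <- 100 * sum(z & lc %in% forest_codes) / nz
    s1512 <- if (sum(bcpa_mask) == 0) NA_real_ else
      100 * sum(bcpa_mask & z) / sum(bcpa_mask)
    degraded <- 100 * sum(z & degraded_mask) / nz
    mz <- z & !is.na(dem$values) & dem$values >= mountain_elev_m
    s1541 <- if (!any(mz)) NA_real_ else 100 * sum(mz & lc %in% green_codes) / sum(mz)
    tibble::tibble(zone = nm, sdg_15_1_1 = forest, sdg_15_1_2 = s1512,
                   sdg_15_3_1 = degraded, sdg_15_4_1 = s1541)
  })
  dplyr::bind_rows(rows)
}

#' Indicator table over rectangular sub-zones
#'
#' Tiles the study area into an `n_tiles_r` by `n_tiles_c` grid of
#' city-like blocks and computes the SDG indicators per tile, the sample
#' unit for the synergy correlation analysis.
#'
#' @inheritParams sdg_indicators
#' @param valid_mask logical matrix of study-area cells.
#' @param n_tiles_r,n_tiles_c tiling of the grid.
#' @return tibble, one row per non-empty tile.
#' @export
subzone_indicators <- function(landcover, dem, bcpa_mask, degraded_mask,
                               valid_mask = NULL, n_tiles_r = 3, n_tiles_c = 3,
                               mountain_elev_m = 300) {
  lc <- landcover$values
  nr <- nrow(lc); nc <- ncol(lc)
  if (is.null(valid_mask)) valid_mask <- !is.na(lc)
  rb <- floor(seq(0, nr, length.out = n_tiles_r + 1))
  cb <- floor(seq(0, nc, length.out = n_tiles_c + 1))
  zones <- list()
  for (i in seq_len(n_tiles_r)) for (j in seq_len(n_tiles_c)) {
    m <- matrix(FALSE, nr, nc)
    m[(rb[i] + 1):rb[i + 1], (cb[j] + 1):cb[j + 1]] <- TRUE
    m <- m & valid_mask
    if (sum(m) > 0) zones[[sprintf("tile_%d_%d", i, j)]] <- m
  }
  out <- sdg_indicators(zones, landcover, dem, bcpa_mask, degraded_mask,
                        mountain_elev_m = mountain_elev_m)
  # per-tile 15.1.2: protected share is computed against the tile's own
  # priority-area cells so tiles are comparable
  out$sdg_15_1_2 <- vapply(names(zones), function(nm) {
    z <- zones[[nm]]
    nb <- sum(bcpa_mask & z)
    if (nb == 0) NA_real_ else 100 * nb / sum(z)
  }, 0)
  out
}

#' Spearman correlation matrix of indicators
#'
#' Pairwise Spearman rank correlation (average ranks on ties) across
#' sub-zone rows; constant columns yield `NA` with a warning suppressed to
#' the matrix entries.
#'
#' @param table tibble of sub-zone indicator rows (>= 4 rows).
#' @param cols columns to correlate (default: numeric columns).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
spearman_matrix <- function(table, cols = NULL) {
  d <- as.data.frame(table)
  if (is.null(cols)) cols <- names(d)[vapply(d, is.numeric, TRUE)]
  d <- d[cols]
  if (nrow(d) < 4) stop("need at least 4 sub-zone rows")
  suppressWarnings(stats::cor(d, method = "spearman",
                              use = "pairwise.complete.obs"))
}
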