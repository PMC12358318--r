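#' Land-cover code legend used by the synthetic generator
#'
#' @return tibble with `code`, `class`, and the default five-level
#'   resistance assigned to each class (forest/wetland 1, grassland 10,
#'   cropland 25, bare 50, urban and open water 100; sea is `NA`,
#'   impassable for terrestrial analysis by default).
#' @export
landcover_codes <- function() {
  tibble::tibble(
    code = 1:8,
    class = c("cropland", "forest", "grassland", "water", "bare", "urban",
              "wetland", "sea"),
    resistance_level = c(25, 1, 10, 100, 50, 100, 1, NA))
}

#' Configuration for the synthetic coastal landscape
#'
#' The generator emulates the structure of a densely settled coastal
#' province: a low coastal strip holding settlements, urban cores and the
#' road network (high disturbance), a mountainous forested interior (low
#' resistance), rivers and lakes, fragmented protected-area (PA) patches of
#' several statutory categories placed on high ground, biodiversity
#' conservation priority areas (BCPAs) partially overlapping PAs, plus
#' planted ground truth: forest corridor strips guaranteed to carry a
#' low-resistance route between chosen PA pairs, and urban barrier walls
#' cutting those strips.
#'
#' @param nrows,ncols grid size in cells.
#' @param cell_size cell edge in metres (default 30, the working resolution
#'   of the land-cover and elevation inputs this emulates).
#' @param seed integer seed; identical config + seed gives identical bundles.
#' @param n_pa number of PA patches.
#' @param pa_categories category labels recycled over patches.
#' @param urban_fraction,forest_fraction,cropland_fraction,water_fraction,
#'   wetland_fraction target shares of the land area (must sum to <= 1).
#' @param bare_fraction share of land left degraded/bare.
#' @param n_roads,n_settlements counts of road polylines and settlements.
#' @param coast_side which edge is the sea: "N", "S", "E" or "W".
#' @param coast_width_frac sea strip width as a fraction of the grid.
#' @param planted_corridors list of 2-vectors of PA ids (generation order)
#'   guaranteed a low-resistance forest strip (the strip is also carved as a
#'   gentle valley so terrain factors do not cancel its advantage).
#' @param corridor_width_m width of planted corridor strips.
#' @param planted_barriers list of lists `(corridor = index into
#'   planted_corridors, at = fraction along the strip, thickness_m,
#'   halflength_m)`; each becomes an urban wall crossing the strip
#'   perpendicularly and extending `halflength_m` beyond it on both sides,
#'   emulating linear transport/urban infrastructure.
#' @return a `landscape_config`.
#' @export
landscape_config <- function(nrows = 150, ncols = 150, cell_size = 30,
                             seed = 1, n_pa = 8,
                             pa_categories = c("nature reserve", "scenic spot",
                                               "forest park", "geological park",
                                               "wetland park", "marine park"),
                             urban_fraction = 0.12, forest_fraction = 0.30,
                             cropland_fraction = 0.35, water_fraction = 0.03,
                             wetland_fraction = 0.04, bare_fraction = 0.03,
                             n_roads = 6, n_settlements = 5,
                             coast_side = "E", coast_width_frac = 0.12,
                             planted_corridors = list(c(1, 2)),
                             corridor_width_m = 210,
                             planted_barriers = list()) {
  fr <- c(urban_fraction, forest_fraction, cropland_fraction, water_fraction,
          wetland_fraction, bare_fraction)
  if (any(fr < 0) || sum(fr) > 1) stop("land-cover fractions must be in [0,1] and sum to at most 1")
  if (!coast_side %in% c("N", "S", "E", "W")) stop("coast_side must be one of N, S, E, W")
  for (pc in planted_corridors)
    if (length(pc) != 2 || any(pc < 1) || any(pc > n_pa))
      stop("planted corridors must reference existing PA ids")
  for (pb in planted_barriers)
    if (is.null(pb$corridor) || pb$corridor > length(planted_corridors))
      stop("planted barriers must reference an existing planted corridor")
  structure(as.list(environment()), class = "landscape_config")
}

# 3x3 box blur with edge replication, repeated `passes` times
blur_field <- function(m, passes = 1) {
  nr <- nrow(m); nc <- ncol(m)
  for (p in seq_len(passes)) {
    acc <- matrix(0, nr, nc)
    for (dr in -1:1) for (dc in -1:1) {
      rs <- pmin(pmax(seq_len(nr) + dr, 1), nr)
      cs <- pmin(pmax(seq_len(nc) + dc, 1), nc)
      acc <- acc + m[rs, cs]
    }
    m <- acc / 9
  }
  m
}

# cells within `halfwidth_m` of segment p-q (row/col space, metres)
strip_cells <- function(nr, nc, cell_size, p, q, halfwidth_m) {
  rows <- matrix(rep(seq_len(nr), nc), nr, nc)
  cols <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  px <- p[2]; py <- p[1]; qx <- q[2]; qy <- q[1]
  vx <- qx - px; vy <- qy - py
  len2 <- vx^2 + vy^2
  t <- ((cols - px) * vx + (rows - py) * vy) / max(len2, 1e-12)
  t <- pmin(pmax(t, 0), 1)
  d <- sqrt((cols - (px + t * vx))^2 + (rows - (py + t * vy))^2) * cell_size
  d <= halfwidth_m
}

disk_cells <- function(nr, nc, cell_size, center_rc, radius_m) {
  rows <- matrix(rep(seq_len(nr), nc), nr, nc)
  cols <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  sqrt((rows - center_rc[1])^2 + (cols - center_rc[2])^2) * cell_size <= radius_m
}

circle_polygon <- function(center_xy, radius_m, n = 24) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(center_xy[1] + radius_m * cos(th), center_xy[2] + radius_m * sin(th))
}

#' Generate a synthetic coastal landscape bundle
#'
#' Builds grid-aligned rasters (DEM, NDVI, land cover, degraded mask),
#' vector layers (roads with class attributes, settlements, water, PA and
#' BCPA polygons) and a machine-readable `truth` record of planted corridor
#' routes and barrier footprints. Fully deterministic for a fixed config.
#'
#' @param config a [landscape_config()].
#' @return an object of class `pan_landscape`.
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  set.seed(config$seed)
  nr <- config$nrows; nc <- config$ncols; s <- config$cell_size
  template <- pan_grid(matrix(0, nr, nc), cell_size = s)

  # --- sea strip with a wavy coastline ---------------------------------
  wave_amp <- stats::runif(1, 0.02, 0.05) * min(nr, nc)
  wave_phase <- stats::runif(1, 0, 2 * pi)
  wave <- function(u) wave_amp * sin(2 * pi * u / max(nr, nc) * 2 + wave_phase)
  rows <- matrix(rep(seq_len(nr), nc), nr, nc)
  cols <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  cw <- config$coast_width_frac
  sea <- switch(config$coast_side,
    E = cols > nc * (1 - cw) + wave(rows),
    W = cols < nc * cw + wave(rows),
    N = rows < nr * cw + wave(cols),
    S = rows > nr * (1 - cw) + wave(cols))
  land <- !sea
  n_land <- sum(land)

  # --- DEM: mountainous interior, low coastal strip --------------------
  dist_coast <- sqrt(cpp_edt_sq(sea)) * s
  noise <- blur_field(matrix(stats::runif(nr * nc), nr, nc), passes = 6)
  noise <- (noise - min(noise)) / max(1e-12, diff(range(noise)))
  dmax <- max(dist_coast[land])
  dem_v <- 500 * (dist_coast / max(dmax, 1))^1.3 + 220 * noise
  dem_v[sea] <- 0

  # --- protected-area patches on high interior ground ------------------
  hi <- which(land & dem_v >= stats::quantile(dem_v[land], 0.55))
  radii_cells <- stats::runif(config$n_pa, 5, 9)
  centers <- matrix(NA_real_, config$n_pa, 2)
  # planted-corridor endpoints need room for an actual corridor between them
  corr_sep_cells <- ceiling(1200 / s)
  corr_partner <- lapply(seq_len(config$n_pa), function(i) {
    unlist(lapply(config$planted_corridors,
                  function(pr) if (i %in% pr) setdiff(pr, i) else NULL))
  })
  hi_rc <- cell_rowcol(template, hi)
  placed <- 0
  for (restart in seq_len(40)) {
    placed <- 0; tries <- 0
    centers[] <- NA_real_
    while (placed < config$n_pa && tries < 2000) {
      tries <- tries + 1
      cand <- hi_rc[sample.int(nrow(hi_rc), 1), ]
      r_new <- radii_cells[placed + 1]
      edge_ok <- cand[1] > r_new + 2 && cand[1] < nr - r_new - 2 &&
                 cand[2] > r_new + 2 && cand[2] < nc - r_new - 2
      ok <- edge_ok
      if (ok && placed > 0) {
        d <- sqrt((centers[seq_len(placed), 1] - cand[1])^2 +
                  (centers[seq_len(placed), 2] - cand[2])^2)
        need <- radii_cells[seq_len(placed)] + r_new + 4
        partners <- corr_partner[[placed + 1]]
        partners <- partners[partners <= placed]
        need[partners] <- pmax(need[partners], corr_sep_cells)
        ok <- all(d > need)
      }
      if (ok) { placed <- placed + 1; centers[placed, ] <- cand }
    }
    if (placed == config$n_pa) break
  }
  if (placed < config$n_pa)
    stop("could not place ", config$n_pa, " non-overlapping PA patches; reduce n_pa or enlarge the grid")

  # --- planted corridor strips and barrier walls -----------------------
  corridor_masks <- list(); corridor_routes <- list()
  for (i in seq_along(config$planted_corridors)) {
    pr <- config$planted_corridors[[i]]
    p <- centers[pr[1], ]; q <- centers[pr[2], ]
    corridor_masks[[i]] <- strip_cells(nr, nc, s, p, q, config$corridor_width_m / 2) & land
    nstep <- max(2L, ceiling(sqrt(sum((q - p)^2)) * 2))
    ts <- seq(0, 1, length.out = nstep)
    route <- unique(cbind(round(p[1] + ts * (q[1] - p[1])),
                          round(p[2] + ts * (q[2] - p[2]))))
    corridor_routes[[i]] <- list(pair = pr, route = route,
                                 from = p, to = q)
  }
  planted_corr <- Reduce(`|`, corridor_masks, matrix(FALSE, nr, nc))

  # carve each strip as a gentle valley: elevation along the strip ramps
  # linearly between its endpoints, so slope/relief stay low inside it
  for (i in seq_along(corridor_routes)) {
    cr <- corridor_routes[[i]]
    m <- corridor_masks[[i]]
    if (!any(m)) next
    idx <- which(m)
    rc <- cbind((idx - 1L) %% nr + 1L, (idx - 1L) %/% nr + 1L)
    v <- cr$to - cr$from
    tt <- ((rc[, 1] - cr$from[1]) * v[1] + (rc[, 2] - cr$from[2]) * v[2]) /
      max(sum(v^2), 1e-12)
    tt <- pmin(pmax(tt, 0), 1)
    ramp <- dem_v[cell_index(template, round(cr$from[1]), round(cr$from[2]))] * (1 - tt) +
      dem_v[cell_index(template, round(cr$to[1]), round(cr$to[2]))] * tt
    dem_v[idx] <- pmin(dem_v[idx], ramp)
  }
  dem_sm <- blur_field(dem_v, 2)
  near_corr <- sqrt(cpp_edt_sq(planted_corr)) <= 2
  dem_v[near_corr] <- dem_sm[near_corr]
  dem_v[sea] <- 0

  barrier_masks <- list(); barrier_truth <- list()
  for (i in seq_along(config$planted_barriers)) {
    pb <- config$planted_barriers[[i]]
    at <- if (is.null(pb$at)) 0.5 else pb$at
    thick <- if (is.null(pb$thickness_m)) 600 else pb$thickness_m
    halflen <- if (is.null(pb$halflength_m)) 600 else pb$halflength_m
    cr <- corridor_routes[[pb$corridor]]
    ctr <- cr$from + at * (cr$to - cr$from)
    ax <- cr$to - cr$from
    perp <- c(-ax[2], ax[1]) / max(sqrt(sum(ax^2)), 1e-12)
    p1 <- ctr - perp * halflen / s
    p2 <- ctr + perp * halflen / s
    barrier_masks[[i]] <- strip_cells(nr, nc, s, p1, p2, thick / 2) & land
    barrier_truth[[i]] <- list(corridor = pb$corridor, center_rc = ctr,
                               thickness_m = thick, halflength_m = halflen,
                               cells = which(barrier_masks[[i]]))
  }
  planted_barr <- Reduce(`|`, barrier_masks, matrix(FALSE, nr, nc))

  # --- settlements on low coastal land, away from planted corridors ----
  off_corr <- sqrt(cpp_edt_sq(planted_corr)) * s > 300
  low <- which(land & off_corr & dem_v <= stats::quantile(dem_v[land], 0.35) &
                 dist_coast <= stats::quantile(dist_coast[land], 0.5))
  if (length(low) < config$n_settlements) stop("cannot place settlements on this landscape")
  sett_idx <- sort(sample(low, config$n_settlements))
  sett_rc <- cell_rowcol(template, sett_idx)

  # --- land cover ------------------------------------------------------
  lc <- matrix(NA_integer_, nr, nc)
  lc[sea] <- 8L
  # urban: grow around settlements, never onto planted corridors
  sett_mask <- matrix(FALSE, nr, nc); sett_mask[sett_rc] <- TRUE
  d_sett <- sqrt(cpp_edt_sq(sett_mask)) * s
  urb_score <- d_sett + 900 * blur_field(matrix(stats::runif(nr * nc), nr, nc), 3)
  urb_cand <- which(land & !planted_corr)
  n_urban <- round(config$urban_fraction * n_land)
  urban_idx <- urb_cand[order(urb_score[urb_cand])][seq_len(min(n_urban, length(urb_cand)))]
  lc[urban_idx] <- 6L

  # rivers to the coast + lakes
  n_riv <- 2L
  riv_feats <- list(); water_mask <- matrix(FALSE, nr, nc)
  for (i in seq_len(n_riv)) {
    src <- hi_rc[sample.int(nrow(hi_rc), 1), ]
    sink_pool <- which(sea)
    sink <- cell_rowcol(template, sink_pool[sample.int(length(sink_pool), 1)])
    mid <- (src + sink) / 2 + stats::runif(2, -8, 8)
    pts_rc <- rbind(src, mid, sink)
    xy <- cbind(template$origin[1] + (pts_rc[, 2] - 0.5) * s,
                template$origin[2] - (pts_rc[, 1] - 0.5) * s)
    riv_feats[[length(riv_feats) + 1]] <- feat_polyline(xy, kind = "river")
    for (j in 1:2) {
      seg <- strip_cells(nr, nc, s, pts_rc[j, ], pts_rc[j + 1, ], s * 0.7)
      water_mask <- water_mask | seg
    }
  }
  n_wat_target <- round(config$water_fraction * n_land)
  lake_ctr_pool <- which(land & !planted_corr & !sea)
  while (sum(water_mask & land) < n_wat_target) {
    ctr <- cell_rowcol(template, lake_ctr_pool[sample.int(length(lake_ctr_pool), 1)])
    rad <- stats::runif(1, 3, 6) * s
    water_mask <- water_mask | disk_cells(nr, nc, s, ctr, rad)
    xy <- c(template$origin[1] + (ctr[2] - 0.5) * s,
            template$origin[2] - (ctr[1] - 0.5) * s)
    riv_feats[[length(riv_feats) + 1]] <-
      feat_polygon(circle_polygon(xy, rad), kind = "lake")
  }
  wsel <- water_mask & land & is.na(lc)
  lc[wsel] <- 4L

  # wetland: coastal fringe and river margins
  fringe <- land & is.na(lc) & (dist_coast <= 3 * s | (sqrt(cpp_edt_sq(water_mask)) * s) <= 2 * s)
  n_wet <- round(config$wetland_fraction * n_land)
  wet_idx <- which(fringe)
  if (length(wet_idx) > n_wet) wet_idx <- wet_idx[order(dist_coast[wet_idx])][seq_len(n_wet)]
  lc[wet_idx] <- 7L

  # forest: planted corridors and PA interiors first, then a fragmented
  # mosaic of woodland patches (smoothed-noise suitability weighted toward
  # high ground), emulating remnant forest in an agricultural matrix
  lc[planted_corr & is.na(lc)] <- 2L
  for (i in seq_len(config$n_pa)) {
    pa_disk <- disk_cells(nr, nc, s, centers[i, ], radii_cells[i] * s)
    lc[pa_disk & land & is.na(lc)] <- 2L
  }
  n_forest <- round(config$forest_fraction * n_land)
  need <- n_forest - sum(lc == 2L, na.rm = TRUE)
  if (need > 0) {
    fsuit <- blur_field(matrix(stats::runif(nr * nc), nr, nc), 4)
    fsuit <- (fsuit - min(fsuit)) / max(1e-12, diff(range(fsuit)))
    dem_n <- dem_v / max(dem_v[land])
    fsuit <- 0.55 * fsuit + 0.45 * dem_n
    # planted corridors are remnant strips through an agricultural matrix:
    # ambient woodland keeps off a buffer around each strip so the strip is
    # the corridor, not one option among adjacent forest patches
    for (i in seq_along(config$planted_corridors)) {
      cr <- corridor_routes[[i]]
      buffer <- strip_cells(nr, nc, s, cr$from, cr$to,
                            config$corridor_width_m / 2 + 600) & !corridor_masks[[i]]
      fsuit[buffer] <- fsuit[buffer] - 1
    }
    cand <- which(land & is.na(lc))
    cand <- cand[order(-fsuit[cand])]
    lc[cand[seq_len(min(need, length(cand)))]] <- 2L
  }

  # cropland on remaining low ground, bare sprinkle, grassland remainder
  n_crop <- round(config$cropland_fraction * n_land)
  cand <- which(land & is.na(lc))
  cand <- cand[order(dem_v[cand])]
  lc[cand[seq_len(min(n_crop, length(cand)))]] <- 1L
  cand <- which(land & is.na(lc))
  n_bare <- round(config$bare_fraction * n_land)
  if (length(cand) && n_bare > 0)
    lc[sample(cand, min(n_bare, length(cand)))] <- 5L
  lc[land & is.na(lc)] <- 3L

  # barrier walls stamp urban over everything terrestrial
  lc[planted_barr] <- 6L

  # --- roads between settlements --------------------------------------
  road_classes <- c("expressway", "primary", "secondary")
  road_feats <- list()
  if (config$n_roads > 0 && config$n_settlements >= 2) {
    for (i in seq_len(config$n_roads)) {
      ab <- sample.int(config$n_settlements, 2)
      p <- sett_rc[ab[1], ]; q <- sett_rc[ab[2], ]
      mid <- (p + q) / 2 + stats::runif(2, -6, 6)
      pts_rc <- rbind(p, mid, q)
      xy <- cbind(template$origin[1] + (pts_rc[, 2] - 0.5) * s,
                  template$origin[2] - (pts_rc[, 1] - 0.5) * s)
      road_feats[[i]] <- feat_polyline(xy, class = road_classes[(i - 1) %% 3 + 1])
    }
  }

  # --- NDVI: vegetation signal, anti-correlated with urban -------------
  ndvi_base <- c(`1` = 0.45, `2` = 0.80, `3` = 0.55, `4` = 0.05, `5` = 0.20,
                 `6` = 0.12, `7` = 0.60, `8` = NA)
  ndvi_v <- matrix(ndvi_base[as.character(lc)], nr, nc)
  ndvi_v <- ndvi_v + blur_field(matrix(stats::runif(nr * nc, -0.18, 0.18), nr, nc), 2)
  ndvi_v <- pmin(pmax(ndvi_v, 0), 1)
  ndvi_v[sea] <- NA

  # --- vector layers ----------------------------------------------------
  rc_to_xy <- function(rc) cbind(template$origin[1] + (rc[, 2] - 0.5) * s,
                                 template$origin[2] - (rc[, 1] - 0.5) * s)
  sett_feats <- lapply(seq_len(nrow(sett_rc)), function(i)
    feat_point(rc_to_xy(sett_rc)[i, ], name = paste0("settlement_", i)))
  cats <- rep(config$pa_categories, length.out = config$n_pa)
  pa_feats <- lapply(seq_len(config$n_pa), function(i) {
    ctr <- rc_to_xy(matrix(centers[i, ], 1))[1, ]
    feat_polygon(circle_polygon(ctr, radii_cells[i] * s), id = i, category = cats[i])
  })
  n_bcpa <- min(3L, config$n_pa)
  bcpa_feats <- lapply(seq_len(n_bcpa), function(i) {
    ctr <- rc_to_xy(matrix(centers[i, ], 1))[1, ]
    w <- radii_cells[i] * s * 2.2; h <- radii_cells[i] * s * 1.6
    off <- c(w * 0.45, -h * 0.3)  # shifted so overlap with the PA is partial
    feat_polygon(rbind(
      ctr + off + c(-w / 2, -h / 2), ctr + off + c(w / 2, -h / 2),
      ctr + off + c(w / 2, h / 2), ctr + off + c(-w / 2, h / 2)),
      id = i, name = paste0("BCPA_", i))
  })

  dem <- grid_like(template, dem_v)
  landcover <- grid_like(template, lc)
  degraded <- grid_like(template, (lc == 5L) * 1)
  ndvi <- grid_like(template, ndvi_v)

  structure(list(
    dem = dem, ndvi = ndvi, landcover = landcover, degraded = degraded,
    land_mask = grid_like(template, land * 1),
    roads = pan_vector(road_feats), settlements = pan_vector(sett_feats),
    water = pan_vector(riv_feats), pa_polygons = pan_vector(pa_feats),
    bcpa_polygons = pan_vector(bcpa_feats),
    truth = list(pa_centers = centers, pa_radii_cells = radii_cells,
                 corridors = corridor_routes,
                 corridor_masks = lapply(corridor_masks, which),
                 barriers = barrier_truth),
    config = config), class = "pan_landscape")
}

#' @exportS3Method base::print
print.pan_landscape <- function(x, ...) {
  cat(sprintf("<pan_landscape> %d x %d @ %g m, seed %d: %d PA patches, %d planted corridor(s), %d planted barrier(s)\n",
              nrow(x$dem$values), ncol(x$dem$values), x$dem$cell_size,
              x$config$seed, x$config$n_pa,
              length(x$truth$corridors), length(x$truth$barriers)))
  invisible(x)
}

#' Machine-readable record of the planted ground truth
#'
#' @param bundle a `pan_landscape`.
#' @return list with `corridors` (tibble: pair ids plus route cell lists)
#'   and `barriers` (tibble: corridor index, centre, radius, footprint cell
#'   indices), for recovery scoring of corridor and barrier detectors.
#' @export
truth_report <- function(bundle) {
  stopifnot(inherits(bundle, "pan_landscape"))
  tr <- bundle$truth
  corridors <- tibble::tibble(
    corridor = seq_along(tr$corridors),
    from_pa = vapply(tr$corridors, function(x) x$pair[1], 0),
    to_pa = vapply(tr$corridors, function(x) x$pair[2], 0),
    route = lapply(tr$corridors, function(x) x$route),
    strip_cells = tr$corridor_masks)
  barriers <- tibble::tibble(
    barrier = seq_along(tr$barriers),
    corridor = vapply(tr$barriers, function(x) x$corridor, 0),
    center_row = vapply(tr$barriers, function(x) x$center_rc[1], 0),
    center_col = vapply(tr$barriers, function(x) x$center_rc[2], 0),
    thickness_m = vapply(tr$barriers, function(x) x$thickness_m, 0),
    halflength_m = vapply(tr$barriers, function(x) x$halflength_m, 0),
    cells = lapply(tr$barriers, function(x) x$cells))
  list(corridors = corridors, barriers = barriers)
}
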