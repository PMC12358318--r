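#' Single resistance factor layer
#'
#' Binds a raw raster to a reclassification rule on the standard five-level
#' movement-resistance scale (1 = unimpeded, 10, 25, 50, 100 = complete
#' barrier). Continuous factors are cut with Jenks natural breaks (k = 5 by
#' default) on their valid values; `direction = "ascending"` maps larger raw
#' values to higher resistance, `"descending"` the reverse (e.g. higher NDVI
#' or greater road distance mean lower resistance). Categorical factors
#' (land cover) use an explicit code-to-level table.
#'
#' @param factor_id identifier, e.g. "E1" (elevation) .. "A3" (distance to
#'   settlements).
#' @param raw a `pan_grid` of raw values.
#' @param direction "ascending" or "descending" (continuous factors).
#' @param rule optional `pan_breaks` (continuous) or a named code-to-level
#'   table (categorical); default Jenks k = 5 for continuous layers.
#' @param categorical whether `raw` holds category codes.
#' @return a `factor_layer`.
#' @export
factor_layer <- function(factor_id, raw, direction = c("ascending", "descending"),
                         rule = NULL, categorical = FALSE) {
  direction <- match.arg(direction)
  stopifnot(inherits(raw, "pan_grid"))
  structure(list(factor_id = factor_id, raw = raw, direction = direction,
                 rule = rule, categorical = categorical),
            class = "factor_layer")
}

resistance_levels <- c(1, 10, 25, 50, 100)

#' Reclassify a factor layer to the five resistance levels
#'
#' @param layer a [factor_layer()].
#' @return a `pan_grid` whose valid cells hold one of {1, 10, 25, 50, 100};
#'   `NA` propagates.
#' @export
reclassify_factor <- function(layer) {
  stopifnot(inherits(layer, "factor_layer"))
  v <- layer$raw$values
  if (layer$categorical) {
    tab <- layer$rule
    if (is.null(tab)) stop("categorical factor needs a code-to-level table")
    codes <- unique(v[!is.na(v)])
    missing <- setdiff(as.character(codes), names(tab))
    if (length(missing))
      stop("no resistance level for land-cover code(s): ", paste(missing, collapse = ", "))
    out <- matrix(unname(tab[as.character(v)]), nrow(v), ncol(v))
  } else {
    rule <- layer$rule
    vals <- v[is.finite(v)]
    if (is.null(rule)) {
      if (length(unique(vals)) < 5) {
        # degenerate layer: constant or near-constant input
        out <- ifelse(is.na(v), NA_real_, resistance_levels[1])
        return(grid_like(layer$raw, out))
      }
      rule <- jenks_breaks(vals, 5)
    }
    cls <- jenks_classify(as.vector(v), rule)
    lev <- resistance_levels[seq_len(rule$k)]
    if (layer$direction == "descending") lev <- rev(lev)
    out <- matrix(lev[cls], nrow(v), ncol(v))
  }
  grid_like(layer$raw, out)
}

#' Default land-cover resistance table
#' @return named vector mapping land-cover code to resistance level.
#' @export
default_landcover_table <- function() {
  lc <- landcover_codes()
  stats::setNames(lc$resistance_level, lc$code)
}

#' Build the ten standard factor layers from a landscape bundle
#'
#' E1 elevation, E2 slope, E3 relief, E4 NDVI (descending), E5 distance to
#' water (descending: far from water = dry = more resistant), A1 land cover
#' (table), A2.1/A2.2/A2.3 distance to expressways / primary / secondary
#' roads (descending: near roads = disturbed = more resistant... i.e.
#' greater distance means lower resistance), A3 distance to settlements
#' (descending).
#'
#' @param bundle a `pan_landscape`.
#' @return named list of ten `factor_layer` objects.
#' @export
build_factor_stack <- function(bundle) {
  stopifnot(inherits(bundle, "pan_landscape"))
  tmpl <- bundle$dem
  ter <- terrain(bundle$dem)
  lc <- bundle$landcover$values
  water_mask <- !is.na(lc) & (lc == 4 | lc == 8)
  dist_water <- distance_to(water_mask, tmpl)
  road_dist <- function(klass) {
    has <- any(vapply(bundle$roads$features,
                      function(f) identical(f$attrs$class, klass), TRUE))
    if (!has) {
      # no roads of this class: uniformly far, minimal disturbance
      grid_like(tmpl, matrix(max(dim(tmpl)) * tmpl$cell_size,
                             nrow(tmpl$values), ncol(tmpl$values)))
    } else {
      m <- rasterize_features(bundle$roads, tmpl,
                              subset = function(a) identical(a$class, klass))
      distance_to(m$values != 0, tmpl)
    }
  }
  sett_mask <- rasterize_features(bundle$settlements, tmpl)$values != 0
  sea <- !is.na(lc) & lc == 8
  mask_sea <- function(g) { g$values[sea] <- NA; g }
  list(
    E1 = factor_layer("E1", mask_sea(bundle$dem), "ascending"),
    E2 = factor_layer("E2", mask_sea(ter$slope), "ascending"),
    E3 = factor_layer("E3", mask_sea(ter$relief), "ascending"),
    E4 = factor_layer("E4", bundle$ndvi, "descending"),
    E5 = factor_layer("E5", mask_sea(dist_water), "ascending"),
    A1 = factor_layer("A1", bundle$landcover, rule = default_landcover_table(),
                      categorical = TRUE),
    A2.1 = factor_layer("A2.1", mask_sea(road_dist("expressway")), "descending"),
    A2.2 = factor_layer("A2.2", mask_sea(road_dist("primary")), "descending"),
    A2.3 = factor_layer("A2.3", mask_sea(road_dist("secondary")), "descending"),
    A3 = factor_layer("A3", mask_sea(distance_to(sett_mask, tmpl)), "descending"))
}

#' Composite resistance surface by weighted overlay
#'
#' `R(x) = sum_i w_i * level_i(x)` with unit-sum AHP weights, so the
#' composite stays on the interpretable [1, 100] scale. Any scaling of the
#' weights would only rescale R globally, leaving least-cost paths,
#' corridors, current ratios and all class assignments unchanged.
#'
#' @param layers named list of reclassified `pan_grid`s (or `factor_layer`s,
#'   which are reclassified on the fly), names matching the weight labels.
#' @param weights an `ahp_fit` or tibble with `label` and `weight`.
#' @return an object of class `pan_resistance` (grid + weights used).
#' @export
composite_resistance <- function(layers, weights) {
  w <- if (inherits(weights, "ahp_fit")) weights$weights else tibble::as_tibble(weights)
  stopifnot(all(c("label", "weight") %in% names(w)))
  if (!setequal(names(layers), w$label))
    stop("factor labels of layers and weights do not match: missing ",
         paste(setdiff(w$label, names(layers)), collapse = ", "))
  grids <- lapply(layers, function(l)
    if (inherits(l, "factor_layer")) reclassify_factor(l) else l)
  do.call(check_aligned, unname(grids))
  wn <- w$weight / sum(w$weight)
  acc <- matrix(0, nrow(grids[[1]]$values), ncol(grids[[1]]$values))
  for (i in seq_len(nrow(w))) acc <- acc + wn[i] * grids[[w$label[i]]]$values
  structure(list(grid = grid_like(grids[[1]], acc),
                 weights_used = tibble::tibble(label = w$label, weight = wn)),
            class = "pan_resistance")
}

#' @exportS3Method base::print
print.pan_resistance <- function(x, ...) {
  v <- x$grid$values[is.finite(x$grid$values)]
  cat(sprintf("<pan_resistance> composite of %d factors, range [%.2f, %.2f]\n",
              nrow(x$weights_used), min(v), max(v)))
  invisible(x)
}
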