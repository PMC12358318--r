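#' Vector layer container
#'
#' A `pan_vector` is a list of features in the same projected CRS. Each
#' feature is a list with `type` (`"polygon"`, `"polyline"` or `"point"`),
#' `coords` (two-column x/y matrix; polygon rings need not repeat the first
#' vertex) and `attrs` (named list). GeoJSON is the interchange format.
#'
#' @param features list of features as described above.
#' @param crs_id CRS identifier.
#' @return a `pan_vector`.
#' @export
pan_vector <- function(features = list(), crs_id = "local-projected") {
  for (f in features) {
    stopifnot(is.list(f), f$type %in% c("polygon", "polyline", "point"),
              is.matrix(f$coords), ncol(f$coords) == 2)
    if (f$type == "polygon" && !ring_is_simple(f$coords))
      stop("self-intersecting polygon ring")
  }
  structure(list(features = features, crs_id = crs_id), class = "pan_vector")
}

#' @exportS3Method base::print
print.pan_vector <- function(x, ...) {
  tab <- table(vapply(x$features, function(f) f$type, ""))
  cat(sprintf("<pan_vector> %d feature(s): %s; crs '%s'\n",
              length(x$features),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
              x$crs_id))
  invisible(x)
}

#' @export
length.pan_vector <- function(x) length(x$features)

#' Feature constructors
#' @param coords two-column x/y matrix (metres).
#' @param ... named attributes.
#' @return a feature list usable in [pan_vector()].
#' @export
feat_polygon <- function(coords, ...) {
  list(type = "polygon", coords = close_ring(coords, open = TRUE),
       attrs = list(...))
}
#' @rdname feat_polygon
#' @export
feat_polyline <- function(coords, ...) list(type = "polyline", coords = coords, attrs = list(...))
#' @rdname feat_polygon
#' @export
feat_point <- function(coords, ...) {
  list(type = "point", coords = matrix(coords, ncol = 2), attrs = list(...))
}

# drop a repeated closing vertex (we store open rings)
close_ring <- function(coords, open = TRUE) {
  n <- nrow(coords)
  if (n > 1 && all(coords[1, ] == coords[n, ])) coords <- coords[-n, , drop = FALSE]
  coords
}

# O(m^2) segment-crossing test; fine for the small rings used here
ring_is_simple <- function(coords) {
  n <- nrow(coords)
  if (n < 4) return(TRUE)
  seg <- cbind(coords, coords[c(2:n, 1), , drop = FALSE])
  cross <- function(a, b, c, d) {
    o <- function(p, q, r) sign((q[1]-p[1])*(r[2]-p[2]) - (q[2]-p[2])*(r[1]-p[1]))
    o(a, b, c) != o(a, b, d) && o(c, d, a) != o(c, d, b)
  }
  for (i in seq_len(n - 2)) for (j in (i + 2):n) {
    if (i == 1 && j == n) next
    if (cross(seg[i, 1:2], seg[i, 3:4], seg[j, 1:2], seg[j, 3:4])) return(FALSE)
  }
  TRUE
}

#' Attribute table of a vector layer
#' @param x a `pan_vector`.
#' @param ... unused.
#' @return tibble, one row per feature.
#' @export
as_tibble.pan_vector <- function(x, ...) {
  rows <- purrr::imap(x$features, function(f, i) {
    at <- f$attrs
    tibble::tibble(feature = i, type = f$type, !!!at)
  })
  dplyr::bind_rows(rows)
}

#' Read / write GeoJSON vector layers
#'
#' Supports Point, LineString and Polygon features (outer ring only) with
#' scalar properties.
#'
#' @param path file path.
#' @param crs_id CRS identifier to attach on read.
#' @return `read_vector`: a `pan_vector`.
#' @export
read_vector <- function(path, crs_id = "local-projected") {
  js <- jsonlite::read_json(path)
  stopifnot(identical(js$type, "FeatureCollection"))
  feats <- purrr::map(js$features, function(f) {
    g <- f$geometry
    attrs <- lapply(f$properties, function(v) v)
    co <- function(cc) do.call(rbind, lapply(cc, function(p) c(p[[1]], p[[2]])))
    switch(g$type,
      Point = feat_point(c(g$coordinates[[1]], g$coordinates[[2]])),
      LineString = list(type = "polyline", coords = co(g$coordinates), attrs = attrs),
      Polygon = list(type = "polygon",
                     coords = close_ring(co(g$coordinates[[1]])), attrs = attrs),
      stop("unsupported GeoJSON geometry: ", g$type)) -> ft
    ft$attrs <- attrs
    ft
  })
  pan_vector(feats, crs_id = crs_id)
}

#' @rdname read_vector
#' @param v a `pan_vector` to write.
#' @return `write_vector`: invisibly, `path`.
#' @export
write_vector <- function(v, path) {
  stopifnot(inherits(v, "pan_vector"))
  feats <- purrr::map(v$features, function(f) {
    cc <- unname(lapply(seq_len(nrow(f$coords)),
                        function(i) as.list(unname(f$coords[i, ]))))
    geom <- switch(f$type,
      point = list(type = "Point", coordinates = as.list(unname(f$coords[1, ]))),
      polyline = list(type = "LineString", coordinates = cc),
      polygon = list(type = "Polygon",
                     coordinates = list(c(cc, cc[1]))))
    list(type = "Feature", geometry = geom,
         properties = if (length(f$attrs)) f$attrs else setNames(list(), character()))
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = feats),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Rasterize a vector layer onto a template grid
#'
#' Polygons mark cells whose centre falls inside the ring (even-odd rule);
#' polylines mark every cell the line passes through (dense sampling at
#' quarter-cell steps); points mark their containing cell. Optionally burns
#' a per-feature attribute instead of 1.
#'
#' @param v a `pan_vector`.
#' @param template a `pan_grid`.
#' @param field optional attribute name to burn (later features overwrite).
#' @param subset optional predicate on the attribute list selecting features.
#' @return a `pan_grid`, 0 = background.
#' @export
rasterize_features <- function(v, template, field = NULL, subset = NULL) {
  stopifnot(inherits(v, "pan_vector"), inherits(template, "pan_grid"))
  out <- matrix(0, nrow(template$values), ncol(template$values))
  cc <- grid_coords(template)
  feats <- v$features
  if (!is.null(subset)) feats <- purrr::keep(feats, function(f) isTRUE(subset(f$attrs)))
  for (f in feats) {
    val <- if (is.null(field)) 1 else as.numeric(f$attrs[[field]])
    if (f$type == "polygon") {
      hit <- cpp_points_in_ring(cc$x, cc$y, f$coords[, 1], f$coords[, 2])
      out[cbind(cc$row[hit], cc$col[hit])] <- val
    } else if (f$type == "polyline") {
      step <- template$cell_size / 4
      for (i in seq_len(nrow(f$coords) - 1)) {
        p <- f$coords[i, ]; q <- f$coords[i + 1, ]
        len <- sqrt(sum((q - p)^2))
        ts <- seq(0, 1, length.out = max(2L, ceiling(len / step) + 1L))
        xs <- p[1] + ts * (q[1] - p[1]); ys <- p[2] + ts * (q[2] - p[2])
        rc <- xy_to_rowcol(template, xs, ys)
        rc <- rc[stats::complete.cases(rc), , drop = FALSE]
        out[rc] <- val
      }
    } else {
      rc <- xy_to_rowcol(template, f$coords[1, 1], f$coords[1, 2])
      if (!anyNA(rc)) out[rc] <- val
    }
  }
  grid_like(template, out)
}
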