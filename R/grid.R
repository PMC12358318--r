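#' Raster grid container
#'
#' A `pan_grid` is a matrix of cell values with projected georeferencing:
#' row 1 is the northern edge, `origin` is the top-left corner in metres and
#' `cell_size` the square cell edge. Missing cells are `NA` and propagate
#' through every derived layer. All layers taking part in one analysis must
#' share the same georeferencing; nothing in the package resamples.
#'
#' @param values numeric or integer matrix (row 1 = north).
#' @param origin length-2 numeric, x/y of the top-left corner (metres).
#' @param cell_size cell edge in metres (> 0).
#' @param crs_id free-text identifier of the projected CRS.
#' @return an object of class `pan_grid`.
#' @export
pan_grid <- function(values, origin = c(0, nrow(values) * cell_size),
                     cell_size = 30, crs_id = "local-projected") {
  values <- as.matrix(values)
  stopifnot(is.numeric(values) || is.logical(values))
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("cell_size must be a single positive number")
  structure(
    list(values = values, origin = as.numeric(origin),
         cell_size = as.numeric(cell_size), crs_id = as.character(crs_id)),
    class = "pan_grid")
}

#' @exportS3Method base::print
print.pan_grid <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat(sprintf("<pan_grid> %d x %d cells @ %g m, origin (%g, %g), crs '%s'\n",
              nrow(x$values), ncol(x$values), x$cell_size,
              x$origin[1], x$origin[2], x$crs_id))
  if (length(v))
    cat(sprintf("  values: [%g, %g], %d NA\n", min(v), max(v),
                sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.pan_grid <- function(x) dim(x$values)

grid_same_geo <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$origin, b$origin)) &&
    isTRUE(all.equal(a$cell_size, b$cell_size)) &&
    identical(a$crs_id, b$crs_id)
}

#' Assert that grids share georeferencing
#'
#' @param ... `pan_grid` objects.
#' @return invisibly `TRUE`; errors if any pair differs.
#' @export
check_aligned <- function(...) {
  gs <- list(...)
  if (length(gs) < 2) return(invisible(TRUE))
  for (i in 2:length(gs))
    if (!grid_same_geo(gs[[1]], gs[[i]]))
      stop("grids are not aligned (dimensions, origin, cell size and CRS must match exactly)")
  invisible(TRUE)
}

#' Derive a grid from a template, keeping georeferencing
#' @param template a `pan_grid`.
#' @param values replacement matrix (defaults to template values).
#' @return a `pan_grid`.
#' @export
grid_like <- function(template, values = template$values) {
  g <- template
  stopifnot(identical(dim(values), dim(template$values)))
  g$values <- values
  g
}

#' Cell-centre coordinates
#' @param g a `pan_grid`.
#' @return tibble with `row`, `col`, `x`, `y` for every cell.
#' @export
grid_coords <- function(g) {
  nr <- nrow(g$values); nc <- ncol(g$values); s <- g$cell_size
  tibble::tibble(
    row = rep(seq_len(nr), times = nc),
    col = rep(seq_len(nc), each = nr),
    x = g$origin[1] + (rep(seq_len(nc), each = nr) - 0.5) * s,
    y = g$origin[2] - (rep(seq_len(nr), times = nc) - 0.5) * s)
}

# row/col (1-based) <-> column-major linear index (1-based)
cell_index <- function(g, row, col) (col - 1L) * nrow(g$values) + row
cell_rowcol <- function(g, idx) {
  nr <- nrow(g$values)
  cbind(row = (idx - 1L) %% nr + 1L, col = (idx - 1L) %/% nr + 1L)
}

# x/y -> 1-based row/col (NA outside the grid); half-open cell extents
xy_to_rowcol <- function(g, x, y) {
  s <- g$cell_size
  col <- floor((x - g$origin[1]) / s) + 1
  row <- floor((g$origin[2] - y) / s) + 1
  bad <- col < 1 | col > ncol(g$values) | row < 1 | row > nrow(g$values)
  col[bad] <- NA; row[bad] <- NA
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Area of a cell mask in km^2
#' @param g a `pan_grid` or logical matrix interpreted on grid `template`.
#' @param template grid supplying cell size when `g` is a bare matrix.
#' @return area in km^2 (cell count times cell_size^2).
#' @export
mask_area_km2 <- function(g, template = NULL) {
  if (inherits(g, "pan_grid")) {
    n <- sum(g$values != 0, na.rm = TRUE); s <- g$cell_size
  } else {
    stopifnot(inherits(template, "pan_grid"))
    n <- sum(g, na.rm = TRUE); s <- template$cell_size
  }
  n * s^2 / 1e6
}

#' Read / write ESRI ASCII grid rasters
#'
#' Plain-text single-band georeferenced raster format (`ncols/nrows/
#' xllcorner/yllcorner/cellsize/NODATA_value` header followed by rows from
#' north to south). Round-trips values, nodata mask and georeferencing.
#'
#' @param path file path.
#' @param crs_id CRS identifier to attach on read (the format carries none).
#' @return `read_raster`: a `pan_grid`.
#' @export
read_raster <- function(path, crs_id = "local-projected") {
  lines <- readLines(path, n = 6L)
  hdr <- list(); nhdr <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (!grepl("^[A-Za-z]", parts[1])) break
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    nhdr <- nhdr + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("not an ESRI ASCII grid: missing header field(s) ",
         paste(setdiff(need, names(hdr)), collapse = ", "))
  if (hdr$cellsize <= 0) stop("cellsize must be positive")
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(path, skip = nhdr, quiet = TRUE)
  nr <- hdr$nrows; nc <- hdr$ncols
  if (length(vals) != nr * nc) stop("value count does not match header")
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA
  pan_grid(m, origin = c(hdr$xllcorner, hdr$yllcorner + nr * hdr$cellsize),
           cell_size = hdr$cellsize, crs_id = crs_id)
}

#' @rdname read_raster
#' @param g a `pan_grid` to write.
#' @param nodata sentinel written for `NA` cells.
#' @return `write_raster`: invisibly, `path`.
#' @export
write_raster <- function(g, path, nodata = -9999) {
  stopifnot(inherits(g, "pan_grid"))
  m <- g$values
  if (any(m == nodata, na.rm = TRUE))
    stop("grid contains the nodata sentinel as a data value; choose another")
  m[is.na(m)] <- nodata
  nr <- nrow(m); nc <- ncol(m)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %.10g", g$origin[1]),
    sprintf("yllcorner %.10g", g$origin[2] - nr * g$cell_size),
    sprintf("cellsize %.10g", g$cell_size),
    sprintf("NODATA_value %.10g", nodata)), con)
  for (r in seq_len(nr))
    writeLines(paste(formatC(m[r, ], format = "g", digits = 17), collapse = " "), con)
  invisible(path)
}

#' Euclidean distance to the nearest feature
#'
#' Rasterizes the features onto the template and returns, for every cell,
#' the centre-to-centre Euclidean distance in metres to the nearest feature
#' cell (0 on the features themselves). Exact (Felzenszwalb distance
#' transform), not a chamfer approximation.
#'
#' @param features a `pan_vector` layer (or a logical matrix mask).
#' @param template a `pan_grid` providing the georeferencing.
#' @return a `pan_grid` of distances in metres.
#' @export
distance_to <- function(features, template) {
  mask <- if (is.matrix(features)) features else
    rasterize_features(features, template)$values != 0
  mask[is.na(mask)] <- FALSE
  if (!any(mask)) stop("empty feature set: distance undefined")
  d2 <- cpp_edt_sq(mask)
  grid_like(template, sqrt(d2) * template$cell_size)
}

#' Terrain derivatives: slope and relief
#'
#' Slope by Horn's 3x3 finite differences (degrees); relief as the max-min
#' elevation range in a square moving window. Border cells (and any cell
#' whose window touches `NA`) are `NA`.
#'
#' @param dem elevation `pan_grid` in metres.
#' @param relief_window odd window edge length in cells (default 3).
#' @return list with `slope` (degrees) and `relief` (metres) grids.
#' @export
terrain <- function(dem, relief_window = 3) {
  stopifnot(inherits(dem, "pan_grid"))
  m <- dem$values; nr <- nrow(m); nc <- ncol(m); s <- dem$cell_size
  if (relief_window %% 2 != 1 || relief_window < 1)
    stop("relief_window must be odd and positive")
  if (nr < relief_window || nc < relief_window || nr < 3 || nc < 3)
    stop("grid smaller than the analysis window")
  sh <- function(dr, dc) {
    out <- matrix(NA_real_, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs - dr, cs - dc] <- m[rs, cs]
    out
  }
  z1 <- sh(-1, -1); z2 <- sh(-1, 0); z3 <- sh(-1, 1)
  z4 <- sh(0, -1);                   z6 <- sh(0, 1)
  z7 <- sh(1, -1);  z8 <- sh(1, 0);  z9 <- sh(1, 1)
  dzdx <- ((z3 + 2 * z6 + z9) - (z1 + 2 * z4 + z7)) / (8 * s)
  dzdy <- ((z7 + 2 * z8 + z9) - (z1 + 2 * z2 + z3)) / (8 * s)
  slope <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  half <- (relief_window - 1) / 2
  mx <- matrix(-Inf, nr, nc); mn <- matrix(Inf, nr, nc)
  anyna <- matrix(FALSE, nr, nc)
  for (dr in -half:half) for (dc in -half:half) {
    w <- sh(dr, dc)
    anyna <- anyna | is.na(w)
    w2 <- w; w2[is.na(w2)] <- -Inf; mx <- pmax(mx, w2)
    w2 <- w; w2[is.na(w2)] <- Inf;  mn <- pmin(mn, w2)
  }
  relief <- mx - mn
  relief[anyna] <- NA
  list(slope = grid_like(dem, slope), relief = grid_like(dem, relief))
}
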