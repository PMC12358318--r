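# Build the sparse conductance graph of a resistance grid restricted to a
# mask. Nodes are valid cells; optional patch labels collapse every cell of
# one patch into a single supernode (patches are short-circuited).
# Edge conductance = 1 / edge cost, with edge cost exactly as in
# cost_distance(), so the circuit and cost-distance analyses share one
# geometry.
build_circuit <- function(R, mask = NULL, patch_labels = NULL) {
  v <- R$values
  nr <- nrow(v); nc <- ncol(v); s <- R$cell_size
  valid <- is.finite(v)
  if (!is.null(mask)) valid <- valid & mask
  # node numbering: patch supernodes first (1..P), then free cells
  lab <- if (is.null(patch_labels)) matrix(0L, nr, nc) else patch_labels
  P <- max(lab)
  node_of <- matrix(NA_integer_, nr, nc)
  node_of[valid & lab > 0] <- lab[valid & lab > 0]
  free <- which(valid & lab == 0)
  node_of[free] <- P + seq_along(free)
  n_nodes <- P + length(free)
  edges_i <- integer(0); edges_j <- integer(0); edges_g <- numeric(0)
  shifts <- list(c(0, 1, 1), c(1, 0, 1), c(1, 1, sqrt(2)), c(1, -1, sqrt(2)))
  for (sh in shifts) {
    dr <- sh[1]; dc <- sh[2]; mult <- sh[3]
    r1 <- seq_len(nr - dr); c1 <- if (dc >= 0) seq_len(nc - dc) else seq(1 - dc, nc)
    a_rc <- as.matrix(expand.grid(row = r1, col = c1))
    b_rc <- cbind(a_rc[, 1] + dr, a_rc[, 2] + dc)
    ai <- a_rc[, 1] + (a_rc[, 2] - 1L) * nr
    bi <- b_rc[, 1] + (b_rc[, 2] - 1L) * nr
    ok <- valid[ai] & valid[bi]
    if (!any(ok)) next
    ai <- ai[ok]; bi <- bi[ok]
    g <- 1 / (0.5 * (v[ai] + v[bi]) * s * mult)
    na <- node_of[ai]; nb <- node_of[bi]
    keep <- na != nb  # drop intra-patch edges
    edges_i <- c(edges_i, na[keep]); edges_j <- c(edges_j, nb[keep])
    edges_g <- c(edges_g, g[keep])
  }
  list(n_nodes = n_nodes, P = P, node_of = node_of, free = free,
       ei = edges_i, ej = edges_j, eg = edges_g, nr = nr, nc = nc)
}

# Solve node voltages with `injections` (named by node) and `ground` nodes
# held at 0 V; sparse Cholesky on the grounded Laplacian.
solve_voltages <- function(circ, injection_nodes, injection_amps, ground_nodes) {
  n <- circ$n_nodes
  # every injecting node must reach a ground, or the system is singular
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (e in seq_along(circ$ei)) {
    ra <- find(circ$ei[e]); rb <- find(circ$ej[e])
    if (ra != rb) parent[rb] <- ra
  }
  gnd_roots <- unique(vapply(ground_nodes, find, 0L))
  inj_roots <- vapply(injection_nodes, find, 0L)
  if (!all(inj_roots %in% gnd_roots)) {
    bad <- injection_nodes[!(inj_roots %in% gnd_roots)]
    stop("singular circuit system: component containing node(s) ",
         paste(utils::head(bad, 3), collapse = ", "),
         " is disconnected from every ground")
  }
  i <- c(circ$ei, circ$ej); j <- c(circ$ej, circ$ei); g <- c(circ$eg, circ$eg)
  A <- Matrix::sparseMatrix(i = i, j = j, x = -g, dims = c(n, n))
  d <- -Matrix::rowSums(A)
  L <- A + Matrix::Diagonal(n, d)
  # solve only within grounded components; groundless pockets stay at 0 V
  roots <- vapply(seq_len(n), find, 0L)
  keep <- setdiff(which(roots %in% gnd_roots), ground_nodes)
  b <- numeric(n)
  b[injection_nodes] <- b[injection_nodes] + injection_amps
  Lk <- L[keep, keep, drop = FALSE]
  vk <- tryCatch(
    as.numeric(Matrix::solve(Lk, b[keep])),
    error = function(e) stop("singular circuit system: some component is disconnected from ground (",
                             conditionMessage(e), ")"))
  volts <- numeric(n)
  volts[keep] <- vk
  volts
}

# per-node current: half the sum of absolute edge currents plus half the
# absolute external (injected or grounded) current through the node
node_currents <- function(circ, volts, injection_nodes, injection_amps, ground_nodes) {
  ie <- abs((volts[circ$ei] - volts[circ$ej]) * circ$eg)
  cur <- numeric(circ$n_nodes)
  acc <- function(idx, val) {
    t <- tapply(val, idx, sum)
    cur[as.integer(names(t))] <<- cur[as.integer(names(t))] + t
  }
  acc(circ$ei, ie); acc(circ$ej, ie)
  ext <- numeric(circ$n_nodes)
  ext[injection_nodes] <- ext[injection_nodes] + injection_amps
  # ground absorbs the net: current into ground = sum of edge currents there
  net_out <- numeric(circ$n_nodes)
  t1 <- tapply((volts[circ$ei] - volts[circ$ej]) * circ$eg, circ$ei, sum)
  net_out[as.integer(names(t1))] <- net_out[as.integer(names(t1))] + t1
  t2 <- tapply((volts[circ$ej] - volts[circ$ei]) * circ$eg, circ$ej, sum)
  net_out[as.integer(names(t2))] <- net_out[as.integer(names(t2))] + t2
  ext[ground_nodes] <- -net_out[ground_nodes]
  (cur + abs(ext)) / 2
}

#' Solve current flow across a resistance surface
#'
#' Converts the grid to an electrical network (conductance = reciprocal of
#' the cost-distance edge cost), injects `injection` amps spread over the
#' source cells, holds the ground cells at 0 V, and solves the Laplacian
#' system by sparse Cholesky factorization. The per-cell current density is
#' half the sum of absolute currents on incident edges (plus the external
#' current at sources/grounds), the standard cumulative current of
#' circuit-theory connectivity analysis.
#'
#' @param resistance a `pan_resistance` or `pan_grid`.
#' @param source_cells,ground_cells cell indices (column-major) or logical
#'   matrices; must be disjoint.
#' @param injection total injected current in amps (default 1).
#' @param mask optional logical matrix restricting the analysis extent.
#' @return an object of class `pan_current`: `current` grid, `voltage`
#'   grid, and the net ground current `absorbed`.
#' @export
solve_current <- function(resistance, source_cells, ground_cells,
                          injection = 1, mask = NULL) {
  R <- if (inherits(resistance, "pan_resistance")) resistance$grid else resistance
  if (is.matrix(source_cells)) source_cells <- which(source_cells)
  if (is.matrix(ground_cells)) ground_cells <- which(ground_cells)
  if (length(intersect(source_cells, ground_cells)))
    stop("source and ground cells must be disjoint")
  circ <- build_circuit(R, mask = mask)
  src_nodes <- circ$node_of[source_cells]
  gnd_nodes <- unique(circ$node_of[ground_cells])
  if (anyNA(src_nodes) || anyNA(gnd_nodes))
    stop("source or ground cells fall on nodata cells")
  amps <- rep(injection / length(src_nodes), length(src_nodes))
  volts <- solve_voltages(circ, src_nodes, amps, gnd_nodes)
  cur <- node_currents(circ, volts, src_nodes, amps, gnd_nodes)
  cur_grid <- matrix(NA_real_, circ$nr, circ$nc)
  vol_grid <- matrix(NA_real_, circ$nr, circ$nc)
  idx <- which(!is.na(circ$node_of))
  cur_grid[idx] <- cur[circ$node_of[idx]]
  vol_grid[idx] <- volts[circ$node_of[idx]]
  structure(list(current = grid_like(R, cur_grid),
                 voltage = grid_like(R, vol_grid),
                 absorbed = sum(amps), mode = "pairwise"),
            class = "pan_current")
}

#' @exportS3Method base::print
print.pan_current <- function(x, ...) {
  v <- x$current$values[is.finite(x$current$values)]
  cat(sprintf("<pan_current> mode %s, max current %.4g A\n", x$mode, max(v)))
  invisible(x)
}

#' Cumulative all-to-one current across the patch network
#'
#' Iterates every patch as the ground while all other patches inject 1 A
#' each (patch cells are short-circuited into one supernode per patch), and
#' sums the per-cell current over iterations. The analysis is restricted to
#' cells whose minimum normalized corridor value is within `width` (the
#' cost-weighted-distance "corridor width" of the current mapping), when a
#' `pan_paths` object is supplied.
#'
#' @param resistance a `pan_resistance` or `pan_grid`.
#' @param patchset a `pan_patches` (>= 2 patches).
#' @param paths optional `pan_paths` used to build the corridor mask.
#' @param width corridor width in CWD units (default 10000 m-resistance,
#'   i.e. the 10 km preset; ignored without `paths`).
#' @return a `pan_current` with `mode = "all_to_one"`.
#' @export
cumulative_current <- function(resistance, patchset, paths = NULL, width = 10000) {
  R <- if (inherits(resistance, "pan_resistance")) resistance$grid else resistance
  stopifnot(inherits(patchset, "pan_patches"))
  P <- nrow(patchset$patches)
  if (P < 2) stop("all-to-one current needs at least two patches")
  lab <- patchset$labels$values
  mask <- NULL
  if (!is.null(paths)) {
    nl <- corridor_min_raster(paths)$values
    mask <- is.finite(nl) & nl <= width
    mask <- mask | lab > 0
  }
  circ <- build_circuit(R, mask = mask, patch_labels = lab)
  acc <- numeric(circ$n_nodes)
  for (g in seq_len(P)) {
    inj_nodes <- setdiff(seq_len(P), g)
    amps <- rep(1, length(inj_nodes))
    volts <- solve_voltages(circ, inj_nodes, amps, g)
    acc <- acc + node_currents(circ, volts, inj_nodes, amps, g)
  }
  cur_grid <- matrix(NA_real_, circ$nr, circ$nc)
  idx <- which(!is.na(circ$node_of))
  cur_grid[idx] <- acc[circ$node_of[idx]]
  structure(list(current = grid_like(R, cur_grid), voltage = NULL,
                 absorbed = P * (P - 1), mode = "all_to_one"),
            class = "pan_current")
}

#' Extract pinch points from a current map
#'
#' Classifies in-mask current densities into `k` Jenks classes; 8-connected
#' regions of top-class cells with area at least `min_area_km2` become
#' pinch-point regions. A current map with fewer than `k` distinct values
#' (e.g. uniform current) yields an empty set with a warning.
#'
#' @param cm a `pan_current`.
#' @param k number of Jenks classes (default 5).
#' @param min_area_km2 minimum region area (default 0.1).
#' @param exclude optional logical matrix of cells to ignore (e.g. patch
#'   interiors).
#' @return an object of class `pan_pinch`: `points` tibble (region id,
#'   n_cells, area_km2, peak_current, centroid row/col), `mask` grid of
#'   retained regions, and the break rule.
#' @export
extract_pinch_points <- function(cm, k = 5, min_area_km2 = 0.1, exclude = NULL) {
  stopifnot(inherits(cm, "pan_current"))
  g <- cm$current
  vals <- g$values
  if (!is.null(exclude)) vals[exclude] <- NA
  v <- vals[is.finite(vals)]
  empty <- tibble::tibble(region = integer(), n_cells = integer(),
                          area_km2 = numeric(), peak_current = numeric(),
                          centroid_row = numeric(), centroid_col = numeric())
  if (length(unique(v)) < k) {
    warning("current map has fewer than ", k, " distinct values; no pinch points")
    return(structure(list(points = empty, mask = grid_like(g, matrix(0, nrow(g$values), ncol(g$values))),
                          breaks = NULL, k = k, min_area_km2 = min_area_km2),
                     class = "pan_pinch"))
  }
  rule <- jenks_breaks(v, k)
  cls <- jenks_classify(grid_like(g, vals), rule)
  top <- !is.na(cls$values) & cls$values == k
  lab <- cpp_label8(top)
  s <- g$cell_size
  n_reg <- max(lab)
  rows <- list()
  keep_mask <- matrix(0, nrow(lab), ncol(lab))
  rid <- 0
  for (i in seq_len(n_reg)) {
    cells <- which(lab == i)
    area <- length(cells) * s^2 / 1e6
    if (area < min_area_km2) next
    rid <- rid + 1
    rc <- cell_rowcol(g, cells)
    keep_mask[cells] <- rid
    rows[[rid]] <- tibble::tibble(
      region = rid, n_cells = length(cells), area_km2 = area,
      peak_current = max(vals[cells]),
      centroid_row = mean(rc[, 1]), centroid_col = mean(rc[, 2]))
  }
  structure(list(points = if (rid) dplyr::bind_rows(rows) else empty,
                 mask = grid_like(g, keep_mask), breaks = rule,
                 k = k, min_area_km2 = min_area_km2),
            class = "pan_pinch")
}

#' @exportS3Method base::print
print.pan_pinch <- function(x, ...) {
  cat(sprintf("<pan_pinch> %d pinch region(s), %.3f km2 total\n",
              nrow(x$points), sum(x$points$area_km2)))
  invisible(x)
}
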