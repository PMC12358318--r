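#' Patch-corridor link graph
#'
#' Nodes are patches, edges the least-cost linkages with resistance equal
#' to the linkage cost (CWD units), mirroring the convention of current
#' centrality mapping on corridor networks.
#'
#' @param paths a `pan_paths`.
#' @return an object of class `pan_linkgraph`: `nodes` tibble (patch id),
#'   `edges` tibble (patch_a, patch_b, resistance).
#' @export
link_graph <- function(paths) {
  stopifnot(inherits(paths, "pan_paths"))
  structure(list(
    nodes = paths$patchset$patches["id"],
    edges = tibble::tibble(patch_a = paths$paths$patch_a,
                           patch_b = paths$paths$patch_b,
                           resistance = paths$paths$cost)),
    class = "pan_linkgraph")
}

#' Current-flow centrality of patches and linkages
#'
#' For each node in turn taken as ground, 1 A is injected at every other
#' node of its connected component; the resistor network (edge resistance =
#' linkage cost) is solved and the absolute current through every node and
#' edge accumulated over ground iterations. Isolated nodes get centrality 0
#' with a warning.
#'
#' @param graph a `pan_linkgraph`.
#' @return the graph with `centrality` columns added to nodes and edges.
#' @export
centrality <- function(graph) {
  stopifnot(inherits(graph, "pan_linkgraph"))
  ids <- graph$nodes$id
  n <- length(ids)
  idx <- stats::setNames(seq_len(n), ids)
  ea <- idx[as.character(graph$edges$patch_a)]
  eb <- idx[as.character(graph$edges$patch_b)]
  g <- 1 / graph$edges$resistance
  L <- matrix(0, n, n)
  for (e in seq_along(ea)) {
    L[ea[e], eb[e]] <- L[ea[e], eb[e]] - g[e]
    L[eb[e], ea[e]] <- L[eb[e], ea[e]] - g[e]
  }
  diag(L) <- -rowSums(L)
  # connected components via edge adjacency
  comp <- rep(0L, n); cid <- 0L
  adj <- lapply(seq_len(n), function(i) unique(c(eb[ea == i], ea[eb == i])))
  for (i in seq_len(n)) {
    if (comp[i] != 0L) next
    cid <- cid + 1L
    stack <- i
    while (length(stack)) {
      u <- stack[[1]]; stack <- stack[-1]
      if (comp[u] != 0L) next
      comp[u] <- cid
      stack <- c(stack, adj[[u]][comp[adj[[u]]] == 0L])
    }
  }
  if (any(lengths(adj) == 0))
    warning("isolated patch(es) receive centrality 0")
  node_cent <- numeric(n); edge_cent <- numeric(length(ea))
  for (gnd in seq_len(n)) {
    members <- which(comp == comp[gnd])
    if (length(members) < 2) next
    inj <- setdiff(members, gnd)
    keep <- setdiff(members, gnd)
    b <- rep(1, length(keep))
    v <- numeric(n)
    v[keep] <- solve(L[keep, keep, drop = FALSE], b)
    ie <- (v[ea] - v[eb]) * g
    edge_cent <- edge_cent + abs(ie)
    flow_out <- numeric(n)
    for (e in seq_along(ea)) {
      flow_out[ea[e]] <- flow_out[ea[e]] + ie[e]
      flow_out[eb[e]] <- flow_out[eb[e]] - ie[e]
    }
    ext <- numeric(n); ext[inj] <- 1; ext[gnd] <- -flow_out[gnd]
    thru <- numeric(n)
    for (e in seq_along(ea)) {
      thru[ea[e]] <- thru[ea[e]] + abs(ie[e])
      thru[eb[e]] <- thru[eb[e]] + abs(ie[e])
    }
    node_cent <- node_cent + (thru + abs(ext)) / 2
  }
  graph$nodes$centrality <- node_cent
  graph$edges$centrality <- edge_cent
  graph
}

#' Classify centrality values into three priority levels
#'
#' Jenks k = 3; class III is the highest-centrality (highest-priority)
#' class, class I the lowest. Fewer than three distinct values collapse to
#' one class with a warning.
#'
#' @param values numeric centrality values.
#' @param k number of classes (default 3).
#' @return ordered factor with levels I < II < III (first `k` roman levels).
#' @export
classify_centrality <- function(values, k = 3) {
  lev <- as.character(utils::as.roman(seq_len(k)))
  if (length(unique(values[is.finite(values)])) < k) {
    warning("fewer than ", k, " distinct values; single class")
    return(factor(rep(lev[1], length(values)), levels = lev, ordered = TRUE))
  }
  cls <- jenks_classify(values, jenks_breaks(values, k))
  factor(lev[cls], levels = lev, ordered = TRUE)
}

#' Bivariate resistance-by-centrality corridor typology
#'
#' Crosses the 3-level relative-resistance class of each linkage with its
#' 3-level centrality class into the 9-category ensemble used to stage
#' corridor construction priorities. The documented priority ordering puts
#' low resistance + class-III centrality first (cheapest, most load-bearing
#' corridors) and high resistance + class-I centrality last.
#'
#' @param ratio_class factor with levels low/medium/high.
#' @param centrality_class ordered factor with levels I/II/III.
#' @return tibble with `ensemble` (factor, 9 levels "low-III" first) and
#'   `priority_rank` (1 = build first).
#' @export
bivariate_ensemble <- function(ratio_class, centrality_class) {
  stopifnot(length(ratio_class) == length(centrality_class))
  rl <- c("low", "medium", "high"); cl <- c("III", "II", "I")
  combos <- as.vector(t(outer(rl, cl, paste, sep = "-")))  # low-III, low-II, ...
  ens <- paste(as.character(ratio_class), as.character(centrality_class), sep = "-")
  ens <- factor(ens, levels = combos)
  tibble::tibble(ensemble = ens, priority_rank = as.integer(ens))
}

#' Regions where pinch points and barrier points co-occur
#'
#' Groups pinch regions and barrier points lying within `radius_m` of each
#' other (union-merged through mutual proximity) into co-occurrence
#' regions: places that simultaneously concentrate current flow and would
#' benefit most from restoration.
#'
#' @param pinch a `pan_pinch`.
#' @param barriers a `pan_barriers`.
#' @param radius_m proximity radius in metres (default 1000).
#' @param cell_size_m cell size used to convert centroids to metres.
#' @return tibble: one row per region with member pinch/barrier ids and the
#'   bounding-box centre.
#' @export
cooccurrence_regions <- function(pinch, barriers, radius_m = 1000,
                                 cell_size_m = pinch$mask$cell_size) {
  stopifnot(inherits(pinch, "pan_pinch"), inherits(barriers, "pan_barriers"))
  np <- nrow(pinch$points); nb <- nrow(barriers$points)
  if (np == 0 || nb == 0)
    return(tibble::tibble(region = integer(), pinch_ids = list(),
                          barrier_ids = list(), center_row = numeric(),
                          center_col = numeric()))
  pd <- cbind(pinch$points$centroid_row, pinch$points$centroid_col)
  bd <- cbind(barriers$points$centroid_row, barriers$points$centroid_col)
  close <- matrix(FALSE, np, nb)
  for (i in seq_len(np)) for (j in seq_len(nb))
    close[i, j] <- sqrt(sum((pd[i, ] - bd[j, ])^2)) * cell_size_m <= radius_m
  if (!any(close))
    return(tibble::tibble(region = integer(), pinch_ids = list(),
                          barrier_ids = list(), center_row = numeric(),
                          center_col = numeric()))
  # union-find over the bipartite proximity graph
  parent <- seq_len(np + nb)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(np)) for (j in seq_len(nb))
    if (close[i, j]) parent[find(np + j)] <- find(i)
  roots <- vapply(seq_len(np + nb), find, 0L)
  touched <- unique(roots[c(which(rowSums(close) > 0),
                            np + which(colSums(close) > 0))])
  rows <- lapply(seq_along(touched), function(k) {
    mem <- which(roots == touched[k])
    pids <- mem[mem <= np]; bids <- mem[mem > np] - np
    ctr <- colMeans(rbind(pd[pids, , drop = FALSE], bd[bids, , drop = FALSE]))
    tibble::tibble(region = k, pinch_ids = list(pids), barrier_ids = list(bids),
                   center_row = ctr[1], center_col = ctr[2])
  })
  dplyr::bind_rows(rows)
}

#' Screen candidate OECM sites
#'
#' Other Effective area-based Conservation Measures (OECMs) are sites
#' outside formal protected areas that still deliver conservation outcomes.
#' Candidates here are 8-connected regions of corridor focal (pinch) cells
#' that satisfy every enabled predicate: outside PA patches; at least
#' `min_area_km2`; mean composite resistance below the landscape's
#' `resistance_pct`-th percentile; within `settlement_dist_m` of a
#' settlement (the "surrounded by human communities" condition). Predicates
#' are individually toggleable and jointly conjunctive.
#'
#' @param pinch a `pan_pinch` (focal corridor areas).
#' @param resistance a `pan_resistance` or `pan_grid`.
#' @param patchset a `pan_patches` (PA mask source).
#' @param settlements a `pan_vector` of settlement points.
#' @param min_area_km2 area threshold (default 0.1).
#' @param resistance_pct resistance percentile cap (default 20).
#' @param settlement_dist_m settlement proximity (default 2000).
#' @param require_outside_pa,require_low_resistance,require_near_settlement
#'   predicate toggles.
#' @return tibble of candidate regions with area, mean resistance, distance
#'   to the nearest settlement and centroid.
#' @export
screen_oecm <- function(pinch, resistance, patchset, settlements,
                        min_area_km2 = 0.1, resistance_pct = 20,
                        settlement_dist_m = 2000,
                        require_outside_pa = TRUE,
                        require_low_resistance = TRUE,
                        require_near_settlement = TRUE) {
  stopifnot(inherits(pinch, "pan_pinch"))
  R <- if (inherits(resistance, "pan_resistance")) resistance$grid else resistance
  focal <- pinch$mask$values > 0
  lab_pa <- patchset$labels$values
  if (require_outside_pa) focal <- focal & lab_pa == 0
  empty <- tibble::tibble(region = integer(), n_cells = integer(),
                          area_km2 = numeric(), mean_resistance = numeric(),
                          dist_settlement_m = numeric(),
                          centroid_row = numeric(), centroid_col = numeric())
  if (!any(focal)) return(empty)
  rcut <- stats::quantile(R$values[is.finite(R$values)], resistance_pct / 100)
  dsett <- if (require_near_settlement) {
    distance_to(settlements, R)$values
  } else NULL
  labm <- cpp_label8(focal)
  s <- R$cell_size
  rows <- list(); rid <- 0
  for (i in seq_len(max(labm))) {
    cells <- which(labm == i)
    area <- length(cells) * s^2 / 1e6
    if (area < min_area_km2) next
    mres <- mean(R$values[cells], na.rm = TRUE)
    if (require_low_resistance && mres > rcut) next
    dmin <- if (is.null(dsett)) NA_real_ else min(dsett[cells])
    if (require_near_settlement && dmin > settlement_dist_m) next
    rid <- rid + 1
    rc <- cell_rowcol(R, cells)
    rows[[rid]] <- tibble::tibble(
      region = rid, n_cells = length(cells), area_km2 = area,
      mean_resistance = mres, dist_settlement_m = dmin,
      centroid_row = mean(rc[, 1]), centroid_col = mean(rc[, 2]))
  }
  if (rid) dplyr::bind_rows(rows) else empty
}
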