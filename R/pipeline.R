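#' Run the full PAN construction, optimization and assessment pipeline
#'
#' Executes the seven stages in dependency order on a synthetic landscape:
#' simulate, resistance, corridors, circuit, barriers, network, assess.
#' Every stage's tabular/raster outputs can be written to `out_dir`
#' (ESRI ASCII / GeoJSON / CSV) and checksummed into a run manifest; a
#' rerun with identical config and seed reproduces identical checksums.
#'
#' @param config a [landscape_config()] (carries the seed).
#' @param params list of stage parameters; defaults hold the standard
#'   values: five resistance levels, corridor threshold `corridor_t` 10000
#'   CWD units, current width 10000, barrier radii {100, 300, 500} m, pinch
#'   min area 0.1 km2, barrier min area 0.05 km2, k = 5 / k = 3 classes,
#'   coverage target 30%.
#' @param out_dir optional output directory for stage artefacts.
#' @param quiet suppress stage logging.
#' @return an object of class `pan_run`: all stage results plus `manifest`.
#' @export
run_pipeline <- function(config, params = list(), out_dir = NULL, quiet = FALSE) {
  p <- utils::modifyList(list(
    corridor_t = 10000, current_width = 10000,
    barrier_radii = c(100, 300, 500), barrier_extent = 6000,
    pinch_k = 5, pinch_min_area = 0.1,
    barrier_k = 5, barrier_min_area = 0.05,
    ratio_k = 3, centrality_k = 3,
    cooccur_radius = 1000,
    oecm_min_area = 0.1, oecm_resistance_pct = 20, oecm_settlement_dist = 2000,
    footprint_t = "mean_lcp", target_pct = 30,
    mountain_elev = 300, pairing = "adjacent_allocation"), params)
  log_stage <- function(name) if (!quiet) message(sprintf("[panlink] stage: %s", name))
  t0 <- Sys.time(); stages <- list()
  tick <- function(name, expr) {
    log_stage(name)
    st <- Sys.time()
    val <- force(expr)
    stages[[name]] <<- as.numeric(difftime(Sys.time(), st, units = "secs"))
    val
  }

  bundle <- tick("simulate", generate_landscape(config))
  fit <- ahp_weights(expert_matrix())
  stack <- tick("resistance", build_factor_stack(bundle))
  resist <- composite_resistance(stack, fit)

  land <- bundle$land_mask$values > 0
  patches <- label_patches(bundle$pa_polygons, resist$grid, valid_mask = land)
  paths <- tick("corridors", least_cost_paths(patches, resist, pairing = p$pairing))
  paths <- classify_ratios(paths)

  current <- tick("circuit", cumulative_current(resist, patches, paths = paths,
                                                width = p$current_width))
  pinch <- extract_pinch_points(current, k = p$pinch_k,
                                min_area_km2 = p$pinch_min_area,
                                exclude = patches$labels$values > 0)

  barrier_field <- tick("barriers", scan_barriers(resist, paths,
                                                  radii_m = p$barrier_radii,
                                                  extent = p$barrier_extent))
  barrier_pts <- extract_barrier_points(barrier_field, k = p$barrier_k,
                                        min_area_km2 = p$barrier_min_area)

  net <- tick("network", {
    g <- centrality(link_graph(paths))
    g$nodes$centrality_class <- classify_centrality(g$nodes$centrality, p$centrality_k)
    g$edges$centrality_class <- classify_centrality(g$edges$centrality, p$centrality_k)
    ens <- bivariate_ensemble(paths$paths$ratio_class, g$edges$centrality_class)
    g$edges <- dplyr::bind_cols(g$edges, ens)
    g
  })
  cooccur <- cooccurrence_regions(pinch, barrier_pts, radius_m = p$cooccur_radius)
  oecm <- screen_oecm(pinch, resist, patches, bundle$settlements,
                      min_area_km2 = p$oecm_min_area,
                      resistance_pct = p$oecm_resistance_pct,
                      settlement_dist_m = p$oecm_settlement_dist)

  assess <- tick("assess", {
    fp <- pan_footprint(patches, paths, t = p$footprint_t,
                        study_mask = land, target_pct = p$target_pct)
    bcpa_mask <- rasterize_features(bundle$bcpa_polygons, resist$grid)$values != 0
    zones <- list(PA = patches$labels$values > 0,
                  PAN = fp$mask$values > 0,
                  region = land)
    ind <- sdg_indicators(zones, bundle$landcover, bundle$dem, bcpa_mask,
                          bundle$degraded$values > 0,
                          mountain_elev_m = p$mountain_elev)
    sub <- subzone_indicators(bundle$landcover, bundle$dem, bcpa_mask,
                              bundle$degraded$values > 0, valid_mask = land,
                              mountain_elev_m = p$mountain_elev)
    list(footprint = fp,
         bcpa_overlap_pa = overlap_pct(patches$labels$values > 0, bcpa_mask,
                                       template = resist$grid),
         bcpa_overlap_pan = overlap_pct(fp, bcpa_mask),
         composition = composition(fp, bundle$landcover),
         indicators = ind, subzones = sub,
         spearman = spearman_matrix(sub, cols = grep("^sdg", names(sub), value = TRUE)))
  })

  run <- structure(list(
    bundle = bundle, ahp = fit, resistance = resist, patches = patches,
    paths = paths, current = current, pinch = pinch,
    barrier_field = barrier_field, barrier_points = barrier_pts,
    network = net, cooccurrence = cooccur, oecm = oecm, assess = assess,
    params = p, config = config), class = "pan_run")

  manifest <- list(
    seed = config$seed,
    config = unclass(config)[!vapply(unclass(config), is.function, TRUE)],
    params = p,
    stages = names(stages),
    elapsed_s = stages,
    total_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- write_run_outputs(run, out_dir)
    manifest$files <- files
    manifest$checksums <- as.list(tools::md5sum(unlist(files)))
    jsonlite::write_json(manifest[setdiff(names(manifest), c("elapsed_s", "total_s"))],
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  run$manifest <- manifest
  run
}

# write the deterministic stage artefacts; returns named file list
write_run_outputs <- function(run, out_dir) {
  f <- function(...) file.path(out_dir, ...)
  write_raster(run$resistance$grid, f("resistance.asc"))
  write_raster(run$current$current, f("current.asc"))
  write_raster(run$barrier_field$score, f("barrier_score.asc"))
  write_raster(run$assess$footprint$mask, f("footprint.asc"))
  utils::write.csv(run$ahp$weights, f("ahp_weights.csv"), row.names = FALSE)
  utils::write.csv(dplyr::select(run$paths$paths, -dplyr::any_of("cells")),
                   f("paths.csv"), row.names = FALSE)
  utils::write.csv(run$network$nodes, f("patch_centrality.csv"), row.names = FALSE)
  utils::write.csv(run$assess$indicators, f("sdg_indicators.csv"), row.names = FALSE)
  write_vector(paths_as_vector(run$paths), f("paths.geojson"))
  as.list(c(resistance = f("resistance.asc"), current = f("current.asc"),
            barrier_score = f("barrier_score.asc"), footprint = f("footprint.asc"),
            ahp_weights = f("ahp_weights.csv"), paths = f("paths.csv"),
            patch_centrality = f("patch_centrality.csv"),
            sdg_indicators = f("sdg_indicators.csv"),
            paths_geojson = f("paths.geojson")))
}

#' @exportS3Method base::print
print.pan_run <- function(x, ...) {
  cat("<pan_run>\n")
  cat(sprintf("  %d patches, %d paths, %d pinch region(s), %d barrier point(s)\n",
              nrow(x$patches$patches), nrow(x$paths$paths),
              nrow(x$pinch$points), nrow(x$barrier_points$points)))
  cat(sprintf("  PAN coverage %.2f%% (target %g%%), BCPA overlap %.2f%% -> %.2f%%\n",
              x$assess$footprint$coverage_pct, x$assess$footprint$target_pct,
              x$assess$bcpa_overlap_pa, x$assess$bcpa_overlap_pan))
  invisible(x)
}

#' Summary of the headline run quantities
#' @param object a `pan_run`.
#' @param ... unused.
#' @return one-row tibble of headline metrics.
#' @export
glance.pan_run <- function(object, ...) {
  x <- object
  tibble::tibble(
    n_patches = nrow(x$patches$patches),
    n_paths = nrow(x$paths$paths),
    mean_lcp_cost = mean(x$paths$paths$cost),
    n_pinch = nrow(x$pinch$points),
    n_barriers = nrow(x$barrier_points$points),
    coverage_pct = x$assess$footprint$coverage_pct,
    pa_coverage_pct = 100 * sum(x$patches$labels$values > 0) /
      sum(x$bundle$land_mask$values > 0),
    bcpa_overlap_pa = x$assess$bcpa_overlap_pa,
    bcpa_overlap_pan = x$assess$bcpa_overlap_pan,
    ahp_cr = x$ahp$cr)
}
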