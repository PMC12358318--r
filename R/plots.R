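#' Plot a raster grid
#'
#' @param object a `pan_grid`.
#' @param name legend title.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.pan_grid <- function(object, name = "value", ...) {
  d <- grid_coords(object)
  d$value <- as.vector(object$values)
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = name, na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.pan_grid
#' @export
autoplot.pan_resistance <- function(object, ...) {
  autoplot(object$grid, name = "resistance", ...)
}

#' @rdname autoplot.pan_grid
#' @export
autoplot.pan_current <- function(object, ...) {
  g <- object$current
  g$values <- log10(pmax(g$values, 1e-12))
  autoplot(g, name = "log10 current", ...)
}

#' Plot AHP weights
#' @param object an `ahp_fit`.
#' @param ... unused.
#' @return a ggplot bar chart of factor weights.
#' @export
autoplot.ahp_fit <- function(object, ...) {
  d <- object$weights
  d$label <- stats::reorder(d$label, d$weight)
  ggplot2::ggplot(d, ggplot2::aes(.data$weight, .data$label)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "weight", y = NULL,
                  subtitle = sprintf("CR = %.4f", object$cr)) +
    ggplot2::theme_minimal()
}

#' Plot least-cost paths over the resistance surface
#'
#' @param paths a `pan_paths` (after [classify_ratios()] for colouring).
#' @param resistance optional `pan_resistance` background.
#' @return a ggplot object.
#' @export
plot_paths <- function(paths, resistance = NULL) {
  g <- paths$cwd[[1]]
  segs <- dplyr::bind_rows(lapply(seq_len(nrow(paths$paths)), function(i) {
    rc <- cell_rowcol(g, paths$paths$cells[[i]])
    tibble::tibble(
      path = i,
      x = g$origin[1] + (rc[, 2] - 0.5) * g$cell_size,
      y = g$origin[2] - (rc[, 1] - 0.5) * g$cell_size,
      ratio_class = if ("ratio_class" %in% names(paths$paths))
        paths$paths$ratio_class[i] else factor("low"))
  }))
  p <- ggplot2::ggplot()
  if (!is.null(resistance)) {
    d <- grid_coords(resistance$grid)
    d$value <- as.vector(resistance$grid$values)
    p <- p + ggplot2::geom_raster(data = d,
      ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
      ggplot2::scale_fill_viridis_c(name = "resistance", na.value = "grey90")
  }
  p + ggplot2::geom_path(data = segs,
        ggplot2::aes(.data$x, .data$y, group = .data$path,
                     colour = .data$ratio_class), linewidth = 0.7) +
    ggplot2::scale_colour_manual(values = c(low = "forestgreen",
                                            medium = "orange", high = "red"),
                                 name = "relative resistance") +
    ggplot2::coord_equal() + ggplot2::theme_minimal()
}
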