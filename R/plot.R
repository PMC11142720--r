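#' Six-panel DOA overview figure
#'
#' The standard two-array DOA display used when identifying and labelling
#' individual sources: azimuth vs. time and elevation vs. time for each
#' array, plus azimuth vs. elevation for each array, coloured by source
#' label.
#'
#' @param series1,series2 `"doa_series"` data frames for the two arrays.
#' @param path Optional output file (PNG/SVG by extension); when `NULL` the
#'   ggplot object is returned without writing.
#' @param width,height Figure size in inches.
#' @return The composed ggplot object (invisibly when written to file).
#' @export
plot_doa_panels <- function(series1, series2, path = NULL,
                            width = 10, height = 7) {
  panel <- function(df, xvar, yvar, ttl) {
    df <- as.data.frame(df)
    if (nrow(df) == 0L) {
      df <- data.frame(time = numeric(0), az = numeric(0), el = numeric(0),
                       label = character(0))
    }
    df$label[is.na(df$label)] <- "unlabeled"
    ggplot2::ggplot(df, ggplot2::aes(x = .data[[xvar]], y = .data[[yvar]],
                                     colour = .data$label)) +
      ggplot2::geom_point(size = 0.6) +
      ggplot2::labs(title = ttl, x = xvar, y = yvar) +
      ggplot2::theme_minimal(base_size = 9)
  }
  p <- patchwork::wrap_plots(list(
    panel(series1, "time", "az", "array 1: azimuth"),
    panel(series2, "time", "az", "array 2: azimuth"),
    panel(series1, "time", "el", "array 1: elevation"),
    panel(series2, "time", "el", "array 2: elevation"),
    panel(series1, "az", "el", "array 1: az vs el"),
    panel(series2, "az", "el", "array 2: az vs el")), ncol = 2)
  if (!is.null(path)) {
    ggplot2::ggsave(path, p, width = width, height = height, dpi = 150)
    return(invisible(p))
  }
  p
}

#' Map-and-depth track figure
#'
#' Map view (x vs y) and depth vs time of one or more localized tracks,
#' coloured by label, with per-axis 95% confidence ribbons on the depth
#' panel.
#'
#' @param track A `"track_estimate"` data frame.
#' @param geometry Optional [deployment_geometry()] whose instruments are
#'   drawn on the map.
#' @param path Optional output file.
#' @param width,height Figure size in inches.
#' @return The composed ggplot object (invisibly when written to file).
#' @export
plot_track <- function(track, geometry = NULL, path = NULL,
                       width = 10, height = 5) {
  df <- as.data.frame(track)
  map <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                          colour = .data$label)) +
    ggplot2::geom_path() + ggplot2::geom_point(size = 0.7) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "East (m)", y = "North (m)") +
    ggplot2::theme_minimal(base_size = 9)
  if (!is.null(geometry)) {
    ip <- do.call(rbind, lapply(geometry$instruments, function(i) {
      data.frame(x = i$position[1], y = i$position[2], id = i$id)
    }))
    map <- map + ggplot2::geom_point(data = ip,
                                     ggplot2::aes(x = .data$x, y = .data$y),
                                     inherit.aes = FALSE, shape = 15)
  }
  depth <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$z,
                                            colour = .data$label)) +
    ggplot2::geom_point(size = 0.7)
  if (all(c("ci_z_lo", "ci_z_hi") %in% names(df))) {
    depth <- depth +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_z_lo,
                                        ymax = .data$ci_z_hi,
                                        fill = .data$label),
                           alpha = 0.25, colour = NA)
  }
  depth <- depth + ggplot2::labs(x = "time (s)", y = "height above datum (m)") +
    ggplot2::theme_minimal(base_size = 9)
  p <- patchwork::wrap_plots(list(map, depth), ncol = 2)
  if (!is.null(path)) {
    ggplot2::ggsave(path, p, width = width, height = height, dpi = 150)
    return(invisible(p))
  }
  p
}
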