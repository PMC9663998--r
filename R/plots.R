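#' Plot the normalized state field
#'
#' Scatter of state points (normalized length vs normalized speed)
#' colored by state label.
#'
#' @param track Classified track (see [classify_states()]).
#' @param alpha Point transparency.
#' @return A ggplot object.
#' @export
plot_state_field <- function(track, alpha = 0.2) {
  df <- track[!is.na(track$l_norm) & !is.na(track$s_norm), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$l_norm, y = .data$s_norm,
                                   color = .data$label)) +
    ggplot2::geom_point(alpha = alpha, size = 0.5) +
    ggplot2::labs(x = "normalized length", y = "normalized speed",
                  color = "state") +
    ggplot2::theme_minimal()
}

#' Plot a gridded transition-vector field
#'
#' Quiver-style plot of the per-cell median transition vectors.
#'
#' @param grid Output of [grid_vector_field()].
#' @param scale Arrow length multiplier.
#' @return A ggplot object.
#' @export
plot_vector_field <- function(grid, scale = 10) {
  ggplot2::ggplot(grid) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$l_mid, y = .data$s_mid,
                   xend = .data$l_mid + scale * .data$dl_med,
                   yend = .data$s_mid + scale * .data$ds_med),
      arrow = ggplot2::arrow(length = ggplot2::unit(1.5, "mm"))) +
    ggplot2::labs(x = "normalized length", y = "normalized speed") +
    ggplot2::theme_minimal()
}

#' Heatmap of a spatial occupancy density map
#'
#' @param object A `density_map` from [occupancy_density()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.density_map <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y,
                                       fill = .data$density)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", fill = "density (1/mm²)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
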