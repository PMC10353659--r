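# ggplot2 autoplot methods for the package's result types.

#' Plot a green-fraction time series
#'
#' @param object A [gf_series()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gf_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$timestamp, .data$green_fraction)) +
    ggplot2::geom_line(colour = "#2E7D32") +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "Green fraction") +
    ggplot2::theme_minimal()
}

#' Plot an error-class density estimate
#'
#' @param object A [class_density()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.density_estimate <- function(object, ...) {
  lab <- attr(object, "class_label")
  ggplot2::ggplot(object, ggplot2::aes(.data$grid, .data$density)) +
    ggplot2::geom_area(fill = default_error_palette()[[lab]], alpha = 0.5) +
    ggplot2::labs(x = "feature value", y = "density", title = lab) +
    ggplot2::theme_minimal()
}

#' Plot error-class densities of a pixel feature
#'
#' Companion to [class_densities()]: one curve per error class,
#' coloured with the error-overlay palette.
#'
#' @param densities Output of [class_densities()].
#' @return A ggplot.
#' @export
plot_class_densities <- function(densities) {
  ggplot2::ggplot(densities,
                  ggplot2::aes(.data$grid, .data$density, colour = .data$class)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::scale_colour_manual(values = default_error_palette()) +
    ggplot2::labs(x = "feature value", y = "density", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a pixel error map
#'
#' @param object A [error_map()].
#' @param palette Class palette (see [render_error_overlay()]).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pixel_error_map <- function(object, palette = default_error_palette(),
                                     ...) {
  lv <- attr(object, "levels")
  df <- tibble(
    row = rep(seq_len(nrow(object)), times = ncol(object)),
    col = rep(seq_len(ncol(object)), each = nrow(object)),
    class = factor(lv[as.vector(unclass(object))], levels = lv)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = palette) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_void()
}

#' Plot a rendered sample
#'
#' Shows the RGB image, optionally with the green mask outlined.
#'
#' @param object A [render_sample()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rendered_sample <- function(object, ...) {
  rgb <- object$rgb / 255
  ras <- grDevices::rgb(rgb[, , 1], rgb[, , 2], rgb[, , 3])
  dim(ras) <- dim(object$mask)
  ggplot2::ggplot() +
    ggplot2::annotation_raster(ras, xmin = 0, xmax = ncol(object$mask),
                               ymin = 0, ymax = nrow(object$mask)) +
    ggplot2::xlim(0, ncol(object$mask)) +
    ggplot2::ylim(0, nrow(object$mask)) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}
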