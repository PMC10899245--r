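# ggplot2 visualisations for the main result types.

raster_df <- function(pixels) {
  tibble(row = rep(seq_len(nrow(pixels)), times = ncol(pixels)),
         col = rep(seq_len(ncol(pixels)), each = nrow(pixels)),
         value = as.vector(pixels))
}

#' Plot a scan image
#'
#' Grayscale raster with rows increasing downward, as displayed on a scanner.
#'
#' @param object A [scan_image].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot scan_image
#' @export
autoplot.scan_image <- function(object, ...) {
  df <- raster_df(object$pixels)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("%s view (%.2f mm/px)", object$view,
                                  object$spacing_mm_per_px)) +
    ggplot2::theme_void()
}

#' Plot measurements over a mask or image
#'
#' Draws each landmark pair as a labelled segment on top of the pixel data.
#'
#' @param pixels Numeric matrix (image) or binary mask.
#' @param measurements A `renal_measurement` or list of them.
#' @return A ggplot.
#' @export
plot_measurements <- function(pixels, measurements) {
  if (inherits(measurements, "renal_measurement")) {
    measurements <- list(measurements)
  }
  seg <- purrr::map_dfr(measurements, function(m) {
    tibble(biomarker = m$biomarker,
           row1 = m$p1[1], col1 = m$p1[2], row2 = m$p2[1], col2 = m$p2[2],
           label = sprintf("%s %.1f mm", m$biomarker, m$length_mm))
  })
  ggplot2::ggplot() +
    ggplot2::geom_raster(data = raster_df(pixels),
                         ggplot2::aes(x = .data$col, y = .data$row,
                                      alpha = .data$value), fill = "grey20") +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$col1, y = .data$row1,
                                       xend = .data$col2, yend = .data$row2,
                                       colour = .data$label),
                          linewidth = 0.8) +
    ggplot2::scale_alpha(range = c(0, 0.6), guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a training history
#'
#' Loss and validation Dice per step.
#'
#' @param object A `unet_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot unet_fit
#' @export
autoplot.unet_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history, -"step",
                            names_to = "series", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "step (epoch)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
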