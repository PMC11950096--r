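#' Plot a tile
#'
#' Renders the RGB raster with axes in micrometres.
#'
#' @param object An [ish_tile()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.ish_tile <- function(object, ...) {
  d <- dim(object$pixels)
  rast <- grDevices::rgb(object$pixels[, , 1] / 255,
                         object$pixels[, , 2] / 255,
                         object$pixels[, , 3] / 255)
  dim(rast) <- d[1:2]
  w_um <- d[2] * object$pixel_size_um
  h_um <- d[1] * object$pixel_size_um
  ggplot2::ggplot() +
    ggplot2::annotation_raster(rast, xmin = 0, xmax = w_um,
                               ymin = -h_um, ymax = 0) +
    ggplot2::coord_fixed(xlim = c(0, w_um), ylim = c(-h_um, 0), expand = FALSE) +
    ggplot2::labs(x = "x (µm)", y = "y (µm)") +
    ggplot2::theme_minimal()
}

#' Bland-Altman plot
#'
#' Differences against pair means with the mean difference (solid) and the
#' 95% limits of agreement (dashed).
#'
#' @param object A [bland_altman()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = object$mean_diff, linewidth = 0.6) +
    ggplot2::geom_hline(yintercept = c(object$lower_limit, object$upper_limit),
                        linetype = "dashed") +
    ggplot2::labs(x = "mean of the two methods",
                  y = "image analysis - visual") +
    ggplot2::theme_minimal()
}

#' Margin-of-error curve plot
#'
#' Observed (n, ME) points with the fitted power curve, on log-log axes.
#'
#' @param object A [fit_power_model()] result.
#' @param threshold Optional ME threshold drawn as a horizontal line.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.power_model_fit <- function(object, threshold = NULL, ...) {
  grid <- tibble::tibble(n = exp(seq(log(min(object$data$n)),
                                     log(max(object$data$n)), length.out = 100)))
  grid$me <- predict_me(object, grid$n)
  p <- ggplot2::ggplot(object$data, ggplot2::aes(x = .data$n, y = .data$me)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "cells analysed", y = "margin of error (95% CI)") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = "dashed")
  }
  p
}

#' Nucleus map plot
#'
#' Scatter of nucleus centroids sized by area and coloured by inclusion
#' status / exclusion reason; a quick QC view of the segmentation and
#' gating.
#'
#' @param nuclei Nucleus tibble or `ish_segmentation`.
#' @param pixel_size_um Micrometres per pixel (for the axes).
#' @return A ggplot.
#' @export
plot_nuclei <- function(nuclei, pixel_size_um = 1) {
  if (inherits(nuclei, "ish_segmentation")) {
    pixel_size_um <- nuclei$pixel_size_um
    nuclei <- nuclei$nuclei
  }
  df <- dplyr::mutate(nuclei,
                      x_um = .data$x * pixel_size_um,
                      y_um = -.data$y * pixel_size_um)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x_um, y = .data$y_um,
                                   size = .data$area_um2,
                                   colour = .data$reason)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)",
                  size = "area (µm²)", colour = "status") +
    ggplot2::theme_minimal()
}
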