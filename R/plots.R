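# ggplot2 views of the main result types.

#' Plot detected lines and crossings over an image
#'
#' @param image Grayscale image matrix.
#' @param lines Optional `clem_lines` tibble.
#' @param crossings Optional crossing tibble with `center_x`, `center_y`.
#' @return A ggplot object.
#' @export
plot_grid_detection <- function(image, lines = NULL, crossings = NULL) {
  df <- tibble::tibble(
    x = rep(seq_len(ncol(image)), each = nrow(image)),
    y = rep(seq_len(nrow(image)), times = ncol(image)),
    value = as.vector(image))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  if (!is.null(lines) && nrow(lines)) {
    ctr <- attr(lines, "center")
    dmax <- sqrt(sum(dim(image)^2))
    segs <- purrr::map_dfr(seq_len(nrow(lines)), function(i) {
      d <- line_direction(lines$angle[i]); nrm <- line_normal(lines$angle[i])
      p0 <- ctr + lines$offset[i] * nrm
      tibble::tibble(x = p0[1] - dmax * d[1], y = p0[2] - dmax * d[2],
                     xend = p0[1] + dmax * d[1], yend = p0[2] + dmax * d[2])
    })
    p <- p + ggplot2::geom_segment(
      data = segs,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend),
      colour = "red", linewidth = 0.3, alpha = 0.7)
  }
  if (!is.null(crossings) && nrow(crossings)) {
    p <- p + ggplot2::geom_point(
      data = tibble::as_tibble(crossings),
      ggplot2::aes(.data$center_x, .data$center_y),
      colour = "yellow", shape = 3, size = 2)
  }
  p
}

#' Plot a slice-monitor report
#'
#' Cumulative drift and quality metrics against slice index, with warning
#' slices marked.
#'
#' @param reports A `clem_slice_reports` tibble from [monitor_stack()].
#' @return A ggplot object.
#' @export
plot_monitor <- function(reports) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(reports)[, c("slice", "dy_cum", "focus", "astig")],
    -"slice", names_to = "metric", values_to = "value")
  warns <- reports$slice[reports$warnings != ""]
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$slice, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "slice", y = NULL)
  if (length(warns)) {
    p <- p + ggplot2::geom_vline(xintercept = warns, colour = "red",
                                 linetype = "dashed", alpha = 0.5)
  }
  p
}

#' Plot registration residuals
#'
#' Landmark positions with residual vectors of the fitted transform.
#'
#' @param object A `clem_affine` fitted with residuals.
#' @param pairs The pair tibble the transform was fitted on.
#' @param scale Residual magnification for visibility.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.clem_affine <- function(object, pairs, scale = 20, ...) {
  stopifnot(!is.null(object$residuals))
  df <- tibble::tibble(
    x = pairs$em_x_um, y = pairs$em_y_um,
    xend = pairs$em_x_um + scale * object$residuals[, 1],
    yend = pairs$em_y_um + scale * object$residuals[, 2])
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$xend, yend = .data$yend),
                          colour = "red",
                          arrow = ggplot2::arrow(length = ggplot2::unit(2, "pt"))) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "EM x (um)", y = "EM y (um)",
                  subtitle = sprintf("rmse %.2f um (residuals x%g)",
                                     object$rmse_um, scale))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
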