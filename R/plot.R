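#' Plot a spatial graph
#'
#' Draws edges as red polylines along their traced pixel paths (falling
#' back to straight endpoint segments when no path is stored) and
#' vertices as blue squares, in image coordinates (y axis pointing down).
#'
#' @param object a [spatial_graph()].
#' @param path_points maximum number of polyline points drawn per edge.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.spatial_graph <- function(object, path_points = 60, ...) {
  segs <- graph_segments(object, path_points)
  p <- ggplot2::ggplot() +
    ggplot2::geom_path(
      data = segs,
      ggplot2::aes(x = .data$x, y = .data$y, group = .data$edge,
                   linewidth = .data$width),
      colour = "red", lineend = "round") +
    ggplot2::geom_point(
      data = object$nodes,
      ggplot2::aes(x = .data$x, y = .data$y),
      colour = "blue", shape = 15, size = 2) +
    ggplot2::scale_linewidth(range = c(0.3, 2), guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  p
}

#' @rdname autoplot.spatial_graph
#' @param x a [spatial_graph()].
#' @param y unused.
#' @export
plot.spatial_graph <- function(x, y, ...) print(autoplot.spatial_graph(x, ...))

graph_segments <- function(g, path_points = 60) {
  if (!n_edges(g))
    return(tibble::tibble(edge = integer(), x = double(), y = double(),
                          width = double()))
  pieces <- lapply(seq_len(n_edges(g)), function(i) {
    p <- g$edges$path[[i]]
    if (is.null(p)) p <- edge_ctrl(g, i)
    if (nrow(p) > path_points)
      p <- p[unique(round(seq(1, nrow(p), length.out = path_points))), ,
             drop = FALSE]
    tibble::tibble(edge = i, x = p[, 1], y = p[, 2],
                   width = g$edges$width_median[i] %||% 1)
  })
  dplyr::bind_rows(pieces)
}

#' Overlay an extracted graph on its source image
#'
#' Renders the input image in gray and draws the detected graph on top --
#' blue squares for vertices, red lines for edges -- for visual
#' inspection of an extraction result.
#'
#' @param img the source [raster_image()].
#' @param g the extracted [spatial_graph()].
#' @param path_points maximum polyline points per edge.
#' @return a ggplot object.
#' @export
plot_overlay <- function(img, g, path_points = 60) {
  gr <- img_gray(img) / 255
  d <- dim(gr)
  ras <- grDevices::as.raster(gr)
  segs <- graph_segments(g, path_points)
  ggplot2::ggplot() +
    ggplot2::annotation_raster(ras, xmin = -0.5, xmax = d[2] - 0.5,
                               ymin = -(d[1] - 0.5), ymax = 0.5) +
    ggplot2::geom_path(
      data = segs,
      ggplot2::aes(x = .data$x, y = -.data$y, group = .data$edge),
      colour = "red", linewidth = 0.4) +
    ggplot2::geom_point(
      data = g$nodes,
      ggplot2::aes(x = .data$x, y = -.data$y),
      colour = "blue", shape = 15, size = 1.5) +
    ggplot2::coord_fixed(xlim = c(-0.5, d[2] - 0.5),
                         ylim = c(-(d[1] - 0.5), 0.5), expand = FALSE) +
    ggplot2::theme_void()
}

#' Plot an evaluation report
#'
#' Mean and standard deviation of the similarity score, sensitivity and
#' precision per method.
#'
#' @param object an `eval_report` from [evaluate_pipelines()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.eval_report <- function(object, ...) {
  long <- dplyr::bind_rows(
    tibble::tibble(method = object$method, metric = "similarity",
                   mean = object$s_mean, sd = object$s_sd),
    tibble::tibble(method = object$method, metric = "sensitivity",
                   mean = object$sensitivity_mean,
                   sd = object$sensitivity_sd),
    tibble::tibble(method = object$method, metric = "precision",
                   mean = object$precision_mean, sd = object$precision_sd))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$method, y = .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sd,
                                          ymax = .data$mean + .data$sd)) +
    ggplot2::facet_wrap(~metric) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
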