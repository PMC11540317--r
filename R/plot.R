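image_raster_df <- function(image) {
  px <- image$pixels
  tibble(
    x = rep(seq_len(ncol(px)) - 1, each = nrow(px)),
    y = rep(seq_len(nrow(px)) - 1, times = ncol(px)),
    intensity = as.vector(px)
  )
}

circle_paths <- function(x, y, r, id, points = 48) {
  th <- seq(0, 2 * pi, length.out = points)
  tibble(
    id = rep(id, each = points),
    x = rep(x, each = points) + rep(r, each = points) * cos(th),
    y = rep(y, each = points) + rep(r, each = points) * sin(th)
  )
}

#' Plot detected ommatidia over an eye image
#'
#' Grayscale raster of the image with one circle per detection, mirroring the
#' detection overlay of the original tool.
#'
#' @param image An [as_eye_image()] object.
#' @param detections A detection table from [detect_ommatidia()]; when `NULL`,
#'   detection is run with default parameters.
#' @param color Circle color.
#' @return A ggplot object (y axis flipped so the origin is top-left, as in
#'   image coordinates).
#' @export
plot_detections <- function(image, detections = NULL, color = "red") {
  detections <- detections %||% detect_ommatidia(image)
  circles <- circle_paths(detections$x, detections$y, detections$radius,
                          id = seq_len(nrow(detections)))
  ggplot2::ggplot() +
    ggplot2::geom_raster(
      data = image_raster_df(image),
      ggplot2::aes(x = .data$x, y = .data$y, fill = .data$intensity)
    ) +
    ggplot2::geom_path(
      data = circles,
      ggplot2::aes(x = .data$x, y = .data$y, group = .data$id),
      color = color, linewidth = 0.3
    ) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)", fill = "intensity") +
    ggplot2::theme_minimal()
}

#' Plot the neighbor-vector fans of an analysis
#'
#' Draws the 6-neighbor vectors of every (or a subset of) scored ommatidia,
#' colored by per-ommatidium disorderliness.
#'
#' @param analysis An `eye_analysis` from [analyze_eye()] or
#'   [score_centers()].
#' @param indices Optional integer vector of focal ommatidium indices.
#' @return A ggplot object.
#' @export
plot_fans <- function(analysis, indices = NULL) {
  fans <- analysis$fans
  scores <- analysis$scores
  idx <- indices %||% fans$index
  segs <- dplyr::bind_rows(lapply(idx, function(i) {
    nb <- fans$neighbors[[i]]
    tibble(x = fans$x[i], y = fans$y[i],
           xend = fans$x[nb], yend = fans$y[nb],
           odi = scores$odi[i])
  }))
  ggplot2::ggplot(segs) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, color = .data$odi),
      linewidth = 0.3
    ) +
    ggplot2::scale_color_viridis_c() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)", color = "odi") +
    ggplot2::theme_minimal()
}

#' @rdname plot_fans
#' @param object An `eye_analysis`.
#' @param ... Unused.
#' @export
autoplot.eye_analysis <- function(object, ...) {
  plot_fans(object)
}

#' Write a detection overlay PNG
#'
#' Burns one circle outline per detection into the image and writes an RGB
#' PNG (`--debug-overlay` in the CLI).
#'
#' @param image An [as_eye_image()] object.
#' @param detections Detection table from [detect_ommatidia()].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
save_detection_overlay <- function(image, detections, path) {
  px <- image$pixels
  rgb <- array(rep(px, 3), dim = c(nrow(px), ncol(px), 3))
  th <- seq(0, 2 * pi, length.out = 96)
  for (i in seq_len(nrow(detections))) {
    cx <- detections$x[i]; cy <- detections$y[i]; r <- detections$radius[i]
    jj <- pmin(pmax(round(cx + r * cos(th)) + 1, 1), ncol(px))
    ii <- pmin(pmax(round(cy + r * sin(th)) + 1, 1), nrow(px))
    rgb[cbind(ii, jj, 1)] <- 1
    rgb[cbind(ii, jj, 2)] <- 0
    rgb[cbind(ii, jj, 3)] <- 0
  }
  png::writePNG(rgb, path)
  invisible(path)
}
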