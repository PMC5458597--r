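#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Plot a radial profile
#'
#' @param object A `radial_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot radial_profile
#' @export
autoplot.radial_profile <- function(object, ...) {
  df <- object[object$valid, ]
  unit <- switch(radial_unit(object) %||% "q",
                 q = "q (1/Å)", two_theta = "2θ (deg)",
                 d = "d (Å)")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$radial, y = .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = unit, y = "intensity") +
    ggplot2::theme_minimal()
  if (!all(is.na(df$error))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$intensity - .data$error,
                   ymax = .data$intensity + .data$error),
      alpha = 0.3)
  }
  p
}

#' Plot a cake grid
#'
#' @param object A `cake_grid`.
#' @param trans Intensity transform (`"sqrt"`, `"log1p"` or `"identity"`).
#' @param ... Unused.
#' @return A ggplot raster of azimuth versus the radial unit.
#' @method autoplot cake_grid
#' @export
autoplot.cake_grid <- function(object, trans = "sqrt", ...) {
  df <- expand.grid(chi = object$azimuth_centres,
                    radial = object$radial_centres)
  df$intensity <- as.vector(object$intensity)
  f <- switch(trans, sqrt = sqrt, log1p = log1p, identity)
  df$intensity <- f(pmax(df$intensity, 0))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$radial, y = .data$chi,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::labs(x = object$radial_unit, y = "χ (deg)",
                  fill = paste0(trans, "(I)")) +
    ggplot2::theme_minimal()
}

#' Plot a peak track
#'
#' Peak centre and FWHM trajectories over the frame series.
#'
#' @param object A tibble from [track_peak()].
#' @param ... Unused.
#' @return A faceted ggplot.
#' @method autoplot peak_track
#' @export
autoplot.peak_track <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("frame", "centre", "fwhm")],
    c("centre", "fwhm"), names_to = "quantity", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frame, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~quantity, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "frame", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an orientation map
#'
#' Degree-of-orientation raster over the stage axes, with line segments
#' showing the local fibre direction where it is defined.
#'
#' @param object An [orientation_map()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot orientation_map
#' @export
autoplot.orientation_map <- function(object, ...) {
  d <- dim(object$degree)
  ax_y <- object$axes[[1]]; ax_x <- if (length(object$axes) > 1) object$axes[[2]] else NULL
  yv <- if (!is.null(ax_y)) ax_y$values else seq_len(d[1])
  xv <- if (!is.null(ax_x)) ax_x$values else seq_len(d[2])
  df <- expand.grid(y = yv, x = xv)
  df$degree <- as.vector(object$degree)
  df$direction <- as.vector(object$direction)
  sc <- min(diff(range(xv)) / max(length(xv) - 1, 1),
            diff(range(yv)) / max(length(yv) - 1, 1)) * 0.4
  seg <- df[is.finite(df$direction), ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$degree)) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = if (!is.null(ax_x)) ax_x$name else "x",
                  y = if (!is.null(ax_y)) ax_y$name else "y",
                  fill = "degree") +
    ggplot2::theme_minimal()
  if (nrow(seg)) {
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x - sc * cospi(.data$direction / 180),
                   xend = .data$x + sc * cospi(.data$direction / 180),
                   y = .data$y - sc * sinpi(.data$direction / 180),
                   yend = .data$y + sc * sinpi(.data$direction / 180)),
      colour = "white", linewidth = 0.4)
  }
  p
}
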