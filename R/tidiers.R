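#' Tidy and glance methods for segmentation results
#'
#' `tidy()` returns the final contour as a tibble of points; `glance()`
#' returns a one-row summary (iterations, convergence, final energies,
#' segmented area).
#'
#' @param x a `foot_segmentation`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.foot_segmentation <- function(x, ...) {
  dplyr::mutate(x$contour, point = dplyr::row_number(), .before = 1)
}

#' @rdname tidy.foot_segmentation
#' @export
glance.foot_segmentation <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    iterations = x$iterations,
    converged = x$converged,
    e_total = if (nrow(x$energy) && "e_total" %in% names(x$energy)) {
      utils::tail(x$energy$e_total, 1)
    } else {
      NA_real_
    },
    area_px = sum(x$mask),
    perimeter_px = contour_perimeter(x$contour)
  )
}

#' @rdname tidy.foot_segmentation
#' @export
tidy.delta_t_map <- function(x, ...) {
  idx <- which(!is.na(x$delta), arr.ind = TRUE)
  tibble::tibble(
    x = idx[, 2] - 1, y = idx[, 1] - 1,
    delta_t = x$delta[idx]
  )
}

#' @rdname tidy.foot_segmentation
#' @export
glance.delta_t_map <- function(x, ...) {
  tibble::tibble(
    area_px = sum(x$mask), mean_dt = x$mean_dt, max_dt = x$max_dt
  )
}

.image_tibble <- function(grid) {
  tibble::tibble(
    x = rep(0:(ncol(grid) - 1), each = nrow(grid)),
    y = rep(0:(nrow(grid) - 1), times = ncol(grid)),
    value = as.vector(grid)
  )
}

#' Plot a thermal image
#'
#' @param object a [thermal_image()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.thermal_image <- function(object, ...) {
  df <- .image_tibble(object$grid)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(option = "inferno", name = "degC") +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}

#' Plot a segmentation result over its image
#'
#' @param object a `foot_segmentation`.
#' @param image optional [thermal_image()] backdrop.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.foot_segmentation <- function(object, image = NULL, ...) {
  p <- if (!is.null(image)) {
    autoplot(as_thermal_image(image))
  } else {
    ggplot2::ggplot() +
      ggplot2::scale_y_reverse() +
      ggplot2::coord_fixed() +
      ggplot2::theme_minimal()
  }
  closed <- dplyr::bind_rows(object$contour, object$contour[1, ])
  p + ggplot2::geom_path(
    data = closed, ggplot2::aes(.data$x, .data$y),
    inherit.aes = FALSE, color = "cyan", linewidth = 0.6
  )
}

#' Plot a temperature-difference map
#'
#' Uses a fixed color scale (default 0-4 degC) so that maps of different
#' subjects are visually comparable.
#'
#' @param object a [delta_t_map()].
#' @param limits color-scale limits, degC.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.delta_t_map <- function(object, limits = c(0, 4), ...) {
  df <- tidy.delta_t_map(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$delta_t)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(
      option = "magma", name = "|dT| degC",
      limits = limits, oob = scales_squish
    ) +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}

# minimal squish (avoids a scales dependency for one helper)
scales_squish <- function(x, range = c(0, 1), ...) {
  pmin(pmax(x, range[1]), range[2])
}

#' Plot a phantom sample with its ground truth
#'
#' @param object a `phantom_sample`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.phantom_sample <- function(object, ...) {
  closed <- dplyr::bind_rows(object$contour, object$contour[1, ])
  autoplot(object$image) +
    ggplot2::geom_path(
      data = closed, ggplot2::aes(.data$x, .data$y),
      inherit.aes = FALSE, color = "green", linewidth = 0.5
    )
}
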