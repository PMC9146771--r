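#' Contours as tibbles
#'
#' A contour is an ordered, implicitly closed polyline stored as a tibble
#' with numeric columns `x` and `y` (pixel coordinates, sub-pixel precision,
#' first point not duplicated at the end). The canonical orientation is
#' counterclockwise in image coordinates (y down, positive shoelace area),
#' and the canonical start point is the lowest point of the heel (maximal y,
#' ties broken by smallest x).
#'
#' @param points a data frame or matrix with columns/values `x`, `y`.
#' @return a tibble with columns `x`, `y`.
#' @export
as_contour <- function(points) {
  if (is.matrix(points)) {
    points <- tibble::tibble(x = points[, 1], y = points[, 2])
  }
  stopifnot(all(c("x", "y") %in% names(points)))
  pts <- tibble::tibble(x = as.numeric(points$x), y = as.numeric(points$y))
  if (nrow(pts) < 3 || !all(is.finite(pts$x)) || !all(is.finite(pts$y))) {
    stop("a contour needs at least 3 finite points", call. = FALSE)
  }
  pts
}

contour_matrix <- function(points) {
  cbind(points$x, points$y)
}

#' Perimeter and signed area of a closed contour
#'
#' The shoelace signed area is positive for the package's canonical
#' counterclockwise orientation (image coordinates, y down).
#'
#' @param points a contour (tibble with `x`, `y`).
#' @return a scalar.
#' @export
contour_perimeter <- function(points) {
  p <- contour_matrix(as_contour(points))
  sum(rownorm(cyc(p, 1) - p))
}

#' @rdname contour_perimeter
#' @export
contour_area <- function(points) {
  p <- contour_matrix(as_contour(points))
  q <- cyc(p, 1)
  sum(p[, 1] * q[, 2] - q[, 1] * p[, 2]) / 2
}

#' Resample a closed contour uniformly by arclength
#'
#' Produces `n` points equally spaced along the closed polyline, preserving
#' the total perimeter and normalizing the orientation to counterclockwise.
#' The first input vertex stays the starting point of the parameterization.
#'
#' @param points a contour.
#' @param n number of output points (>= 8).
#' @return a tibble contour with `n` rows.
#' @examples
#' sq <- as_contour(data.frame(x = c(0, 10, 10, 0), y = c(0, 0, 10, 10)))
#' resample_contour(sq, 8)
#' @export
resample_contour <- function(points, n = 200) {
  stopifnot(n >= 8)
  pts <- as_contour(points)
  p <- contour_matrix(pts)
  p <- p[!duplicated(p), , drop = FALSE] # drop exact repeats
  if (nrow(p) < 3) stop("degenerate contour: fewer than 3 distinct points",
      call. = FALSE
    )
  if (contour_area(tibble::tibble(x = p[, 1], y = p[, 2])) < 0) {
    p <- p[c(1, nrow(p):2), , drop = FALSE] # reverse, keep start
  }
  seg <- rownorm(cyc(p, 1) - p)
  per <- sum(seg)
  if (per <= 0) stop("degenerate contour: zero perimeter", call. = FALSE)
  # already uniform at the requested n: resampling is the identity
  # (makes resample o resample exactly idempotent)
  if (nrow(p) == n && max(abs(seg - mean(seg))) < 1e-4 * mean(seg)) {
    return(tibble::tibble(x = p[, 1], y = p[, 2]))
  }
  cum <- c(0, cumsum(seg))
  target <- per * (seq_len(n) - 1) / n
  idx <- findInterval(target, cum, rightmost.closed = FALSE)
  idx <- pmin(idx, nrow(p))
  frac <- (target - cum[idx]) / pmax(seg[idx], 1e-300)
  nxt <- cyc(p, 1)
  out <- p[idx, , drop = FALSE] + frac * (nxt[idx, , drop = FALSE] -
    p[idx, , drop = FALSE])
  res <- tibble::tibble(x = out[, 1], y = out[, 2])
  if (abs(contour_area(res)) < 1e-9 * per^2) {
    stop("degenerate contour: collinear points", call. = FALSE)
  }
  res
}

#' Rotate the contour start point to the heel
#'
#' Cyclically rotates the points so that index 1 is the lowest point of the
#' contour (maximal y in image coordinates, ties broken by smallest x). The
#' geometry is unchanged; only the starting index moves. Both the snake and
#' the prior shape are examined from this common start point, which makes
#' point-wise shape comparisons rotation invariant.
#'
#' @param points a contour.
#' @return the same contour with a rotated point order.
#' @export
align_start <- function(points) {
  pts <- as_contour(points)
  i0 <- which(pts$y == max(pts$y))
  if (length(i0) > 1) i0 <- i0[which.min(pts$x[i0])]
  if (i0 == 1) {
    return(pts)
  }
  idx <- c(i0:nrow(pts), seq_len(i0 - 1))
  pts[idx, ]
}

#' Differential profile of a uniformly sampled closed contour
#'
#' Central finite differences with periodic wrap on the arclength
#' parameterization s in [0, 1), step h = 1/n, so derivative magnitudes are
#' resolution independent (a circle of radius r has |Css| = (2 pi)^2 r for
#' any n). The outward unit normal for the counterclockwise orientation is
#' (dy/ds, -dx/ds)/|Cs|.
#'
#' @param points a contour with (near-)uniform point spacing; more than 5%
#'   relative spacing deviation is an error (resample first).
#' @return a tibble with columns `x`, `y`, first/second/fourth derivative
#'   components `d1x`, `d1y`, `d2x`, `d2y`, `d4x`, `d4y`, and outward unit
#'   normal components `normal_x`, `normal_y`.
#' @export
curvature_profile <- function(points) {
  pts <- as_contour(points)
  n <- nrow(pts)
  if (n < 8) stop("curvature profile needs n >= 8 points", call. = FALSE)
  p <- contour_matrix(pts)
  seg <- rownorm(cyc(p, 1) - p)
  if (max(abs(seg - mean(seg))) > 0.05 * mean(seg)) {
    stop("non-uniform point spacing (> 5%); resample the contour first",
      call. = FALSE
    )
  }
  d1 <- (cyc(p, 1) - cyc(p, -1)) * n / 2
  d2 <- (cyc(p, 1) - 2 * p + cyc(p, -1)) * n^2
  d4 <- (cyc(p, -2) - 4 * cyc(p, -1) + 6 * p - 4 * cyc(p, 1) + cyc(p, 2)) * n^4
  nrm <- cbind(d1[, 2], -d1[, 1])
  nrm <- nrm / pmax(rownorm(nrm), 1e-300)
  tibble::tibble(
    x = p[, 1], y = p[, 2],
    d1x = d1[, 1], d1y = d1[, 2],
    d2x = d2[, 1], d2y = d2[, 2],
    d4x = d4[, 1], d4y = d4[, 2],
    normal_x = nrm[, 1], normal_y = nrm[, 2]
  )
}

#' Rasterize a closed contour into a binary mask
#'
#' Pixel centers strictly inside the closed polygon (even-odd fill rule)
#' become foreground; the pixel `[r, c]` has its center at
#' `(x = c - 1, y = r - 1)`. Contours extending beyond the grid are clipped.
#'
#' @param points a contour.
#' @param nrow,ncol mask dimensions.
#' @return an integer 0/1 matrix of size `nrow` x `ncol`.
#' @export
rasterize_mask <- function(points, nrow, ncol) {
  pts <- as_contour(points)
  m <- .cpp_rasterize(contour_matrix(pts), as.integer(nrow), as.integer(ncol))
  if (!any(m == 1L)) {
    warning("contour has an empty pixel interior; returning an all-zero mask",
      call. = FALSE
    )
  }
  m
}

#' Read and write contour CSV files
#'
#' Two columns `x,y` with a header, one row per point, closing point not
#' duplicated.
#'
#' @param path file path.
#' @param points a contour.
#' @return `read_contour_csv()` returns a contour tibble;
#'   `write_contour_csv()` returns `path` invisibly.
#' @export
read_contour_csv <- function(path) {
  as_contour(read.csv(path))
}

#' @rdname read_contour_csv
#' @export
write_contour_csv <- function(points, path) {
  write.csv(as_contour(points)[, c("x", "y")], path, row.names = FALSE)
  invisible(path)
}

#' Write a binary mask as a 0/255 PNG
#'
#' @param mask binary matrix.
#' @param path output path ending in `.png`.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(ifelse(mask > 0, 1, 0), path)
  invisible(path)
}
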