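# Shared numeric helpers. Coordinate convention: the grid entry [r, c]
# (1-based in R) is the sample at point (x = c - 1, y = r - 1); y grows
# downward so "lowest" image points have maximal y.

#' Sample a matrix at sub-pixel positions by bilinear interpolation
#'
#' @param grid numeric matrix, entry `[r, c]` located at `(x = c - 1, y = r - 1)`.
#' @param x,y numeric vectors of equal length; positions are clamped to the
#'   grid extent.
#' @return numeric vector of interpolated values.
#' @keywords internal
bilinear_sample <- function(grid, x, y) {
  nr <- nrow(grid)
  nc <- ncol(grid)
  x <- pmin(pmax(x, 0), nc - 1)
  y <- pmin(pmax(y, 0), nr - 1)
  c0 <- pmin(floor(x), nc - 2)
  r0 <- pmin(floor(y), nr - 2)
  fx <- x - c0
  fy <- y - r0
  i00 <- cbind(r0 + 1, c0 + 1)
  i01 <- cbind(r0 + 1, c0 + 2)
  i10 <- cbind(r0 + 2, c0 + 1)
  i11 <- cbind(r0 + 2, c0 + 2)
  grid[i00] * (1 - fx) * (1 - fy) + grid[i01] * fx * (1 - fy) +
    grid[i10] * (1 - fx) * fy + grid[i11] * fx * fy
}

#' Gaussian smoothing with replicated borders
#'
#' Thin wrapper around [EBImage::filter2()] with a normalized Gaussian brush
#' and replicate boundary handling (appropriate for force fields, where
#' circular wrap-around would leak the warm feet into the opposite border).
#'
#' @param grid numeric matrix.
#' @param sigma standard deviation in pixels; `sigma <= 0` returns the input.
#' @return smoothed matrix of the same shape.
#' @keywords internal
gaussian_smooth <- function(grid, sigma) {
  if (sigma <= 0) {
    return(grid)
  }
  size <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  brush <- EBImage::makeBrush(size, shape = "Gaussian", sigma = sigma)
  as.matrix(EBImage::filter2(grid, brush, boundary = "replicate"))
}

#' Image gradient by central differences
#'
#' One-sided differences at the borders. `gx` differentiates along x
#' (columns), `gy` along y (rows).
#'
#' @param grid numeric matrix.
#' @return list with matrices `gx`, `gy`.
#' @keywords internal
image_gradient <- function(grid) {
  nr <- nrow(grid)
  nc <- ncol(grid)
  gx <- matrix(0, nr, nc)
  gy <- matrix(0, nr, nc)
  gx[, 2:(nc - 1)] <- (grid[, 3:nc] - grid[, 1:(nc - 2)]) / 2
  gx[, 1] <- grid[, 2] - grid[, 1]
  gx[, nc] <- grid[, nc] - grid[, nc - 1]
  gy[2:(nr - 1), ] <- (grid[3:nr, ] - grid[1:(nr - 2), ]) / 2
  gy[1, ] <- grid[2, ] - grid[1, ]
  gy[nr, ] <- grid[nr, ] - grid[nr - 1, ]
  list(gx = gx, gy = gy)
}

# Periodic cyclic shift of rows: shift = 1 gives the next point.
cyc <- function(m, shift) {
  n <- nrow(m)
  idx <- ((seq_len(n) - 1 + shift) %% n) + 1
  m[idx, , drop = FALSE]
}

rownorm <- function(m) sqrt(rowSums(m^2))

# Accept either a thermal_image or a bare numeric matrix (useful for
# synthetic test fields that are not plausible temperatures).
.as_grid <- function(x) {
  if (inherits(x, "thermal_image")) x$grid else as.matrix(x)
}
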