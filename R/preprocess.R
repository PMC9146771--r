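#' Morphological cleanup configuration
#'
#' Sizes of the structuring elements used to clean the Otsu foreground: a
#' line erosion (severing thin bridges between the foot and clutter)
#' followed by a square dilation (restoring the foot area). Element sizes
#' must be odd and at least 3.
#'
#' @param line_len line structuring-element length, px.
#' @param line_angle line angle in degrees (0 = horizontal).
#' @param square square structuring-element side, px.
#' @return an object of class `morph_config`.
#' @export
morph_config <- function(line_len = 7L, line_angle = 0, square = 5L) {
  stopifnot(
    line_len >= 3, line_len %% 2 == 1,
    square >= 3, square %% 2 == 1
  )
  structure(
    list(
      line_len = as.integer(line_len), line_angle = line_angle,
      square = as.integer(square)
    ),
    class = "morph_config"
  )
}

#' Split a two-feet frame and flip the left foot
#'
#' The acquired frame contains both feet; it is split into two equal
#' halves by column (for an odd width the middle column goes to the right
#' half) and the left half is mirrored about its vertical axis so that
#' both feet share the same orientation. Temperatures are unchanged.
#'
#' @param image a [thermal_image()] (or matrix).
#' @return a list with [thermal_image()] fields `right` and `left_flipped`.
#' @export
split_and_flip <- function(image) {
  image <- as_thermal_image(image)
  nc <- ncol(image$grid)
  stopifnot(nc >= 2)
  half <- nc %/% 2
  left <- image$grid[, seq_len(half), drop = FALSE]
  right <- image$grid[, (half + 1):nc, drop = FALSE]
  list(
    right = thermal_image(right, image$pixel_size),
    left_flipped = thermal_image(
      left[, rev(seq_len(half)), drop = FALSE],
      image$pixel_size
    )
  )
}

#' Otsu threshold of a thermal image
#'
#' The threshold maximizes the between-class variance over a 256-bin
#' histogram of the temperature range; the warmer class is foreground.
#'
#' @param image a [thermal_image()] or matrix.
#' @return an integer 0/1 mask.
#' @export
otsu_mask <- function(image) {
  image <- as_thermal_image(image)
  g <- image$grid
  rng <- range(g)
  if (diff(rng) <= 0) stop("constant image: Otsu threshold is undefined",
      call. = FALSE
    )
  norm <- (g - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1), levels = 256)
  (norm > th) * 1L
}

#' Morphological cleanup of a binary mask
#'
#' Erosion by a line structuring element followed by dilation by a square
#' one, then retention of the largest 4-connected component (the plantar
#' surface).
#'
#' @param mask integer 0/1 matrix.
#' @param config a [morph_config()].
#' @return an integer 0/1 mask.
#' @export
morphological_cleanup <- function(mask, config = morph_config()) {
  stopifnot(any(mask > 0))
  # EBImage stores images x-first; transpose so angle 0 is a horizontal line
  img <- EBImage::Image(t(mask * 1))
  line <- EBImage::makeBrush(config$line_len,
    shape = "line",
    angle = config$line_angle
  )
  er <- EBImage::erode(img, line)
  if (!any(er > 0)) {
    stop("mask vanished under line erosion; use smaller structuring elements",
      call. = FALSE
    )
  }
  di <- EBImage::dilate(er, EBImage::makeBrush(config$square, shape = "box"))
  out <- t(as.matrix(di)) > 0
  lab <- .cpp_label(out * 1L, 4L)
  if (max(lab) > 1) {
    areas <- tabulate(lab[lab > 0])
    out <- lab == which.max(areas)
  }
  out * 1L
}

#' Gravity center of a binary mask
#'
#' Centroid of the foreground pixel centers, sub-pixel, in `(x, y)`
#' coordinates (pixel `[r, c]` has center `(c - 1, r - 1)`).
#'
#' @param mask integer 0/1 matrix.
#' @return numeric `c(x, y)`.
#' @export
gravity_center <- function(mask) {
  idx <- which(mask > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty mask has no gravity center", call. = FALSE)
  c(x = mean(idx[, 2] - 1), y = mean(idx[, 1] - 1))
}

#' Locate the foot in a single-foot thermal image
#'
#' Otsu thresholding, morphological cleanup and gravity-center extraction
#' in one call — the standard initialization pipeline.
#'
#' @param image a [thermal_image()].
#' @param config a [morph_config()].
#' @return list with `mask` (cleaned 0/1 mask) and `center` (`c(x, y)`).
#' @export
locate_foot <- function(image, config = morph_config()) {
  mask <- morphological_cleanup(otsu_mask(image), config)
  list(mask = mask, center = gravity_center(mask))
}
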