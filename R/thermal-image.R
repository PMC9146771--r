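#' Thermal image container
#'
#' A single-channel 2-D raster of temperatures in degrees Celsius with a
#' physical pixel size. The grid entry `[r, c]` is the sample at point
#' `(x = c - 1, y = r - 1)`; y grows downward.
#'
#' @param grid numeric matrix of temperatures (degrees C), at least 32 x 32,
#'   finite, within a plausible skin/room range of -20 to 60 degrees C.
#' @param pixel_size physical pixel size in mm/pixel (scalar, default 1).
#' @return an object of class `thermal_image` with fields `grid` and
#'   `pixel_size`.
#' @examples
#' img <- thermal_image(matrix(20, 64, 64) + diag(64))
#' dim(img)
#' @export
thermal_image <- function(grid, pixel_size = 1.0) {
  grid <- as.matrix(grid)
  stopifnot(is.numeric(grid), length(pixel_size) == 1, pixel_size > 0)
  if (nrow(grid) < 32 || ncol(grid) < 32) {
    stop("thermal images must be at least 32 x 32 pixels", call. = FALSE)
  }
  if (!all(is.finite(grid))) {
    stop("thermal image contains non-finite temperatures", call. = FALSE)
  }
  if (min(grid) < -20 || max(grid) > 60) {
    stop("temperatures outside the plausible [-20, 60] degrees C range",
      call. = FALSE
    )
  }
  structure(list(grid = grid, pixel_size = pixel_size),
    class = "thermal_image"
  )
}

#' @export
dim.thermal_image <- function(x) dim(x$grid)

#' @export
print.thermal_image <- function(x, ...) {
  cat(sprintf(
    "<thermal_image> %d x %d px, %.2f mm/px, %.1f..%.1f degC\n",
    nrow(x$grid), ncol(x$grid), x$pixel_size, min(x$grid), max(x$grid)
  ))
  invisible(x)
}

as_thermal_image <- function(x, pixel_size = 1.0) {
  if (inherits(x, "thermal_image")) x else thermal_image(x, pixel_size)
}

#' Read and write thermal images
#'
#' Three plain interchange formats are supported, selected by file
#' extension: a bare CSV grid of temperatures; a 32-bit floating point
#' TIFF; or a grayscale PNG (8- or 16-bit, read at its native depth). TIFF
#' and PNG are written as normalized values with a JSON sidecar
#' `{"scale": a, "offset": b}` (same path, extension `.json`) so that
#' `degC = a * value + b` with `value` in `[0, 1]`; a TIFF without a
#' sidecar is read as plain degrees C.
#'
#' @param path file path ending in `.csv`, `.tif`/`.tiff` or `.png`.
#' @param image a [thermal_image()].
#' @param pixel_size pixel size recorded on read (mm/px).
#' @return `read_thermal()` returns a [thermal_image()];
#'   `write_thermal()` returns `path` invisibly.
#' @export
read_thermal <- function(path, pixel_size = 1.0) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    grid <- as.matrix(read.csv(path, header = FALSE))
    dimnames(grid) <- NULL
  } else if (ext %in% c("tif", "tiff")) {
    grid <- tiff::readTIFF(path, as.is = FALSE)
    if (length(dim(grid)) == 3) grid <- grid[, , 1]
    sidecar <- sub("\\.tiff?$", ".json", path, ignore.case = TRUE)
    if (file.exists(sidecar)) {
      side <- jsonlite::read_json(sidecar)
      grid <- side$scale * grid + side$offset
    }
  } else if (ext == "png") {
    v <- png::readPNG(path) # [0, 1] at the file's bit depth (8 or 16)
    if (length(dim(v)) == 3) v <- v[, , 1]
    side <- jsonlite::read_json(sub("\\.png$", ".json", path,
      ignore.case = TRUE
    ))
    grid <- side$scale * v + side$offset
  } else {
    stop("unsupported thermal image format: ", ext, call. = FALSE)
  }
  thermal_image(grid, pixel_size)
}

#' @rdname read_thermal
#' @export
write_thermal <- function(image, path) {
  image <- as_thermal_image(image)
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    utils::write.table(image$grid, path,
      sep = ",", row.names = FALSE,
      col.names = FALSE
    )
  } else if (ext %in% c("tif", "tiff")) {
    rng <- range(image$grid)
    scale <- max(diff(rng), 1e-9)
    tiff::writeTIFF((image$grid - rng[1]) / scale, path,
      bits.per.sample = 32
    )
    jsonlite::write_json(
      list(scale = scale, offset = rng[1]),
      sub("\\.tiff?$", ".json", path, ignore.case = TRUE),
      auto_unbox = TRUE, digits = NA
    )
  } else if (ext == "png") {
    rng <- range(image$grid)
    scale <- max(diff(rng), 1e-9)
    png::writePNG((image$grid - rng[1]) / scale, path)
    jsonlite::write_json(
      list(scale = scale, offset = rng[1]),
      sub("\\.png$", ".json", path, ignore.case = TRUE),
      auto_unbox = TRUE, digits = NA
    )
  } else {
    stop("unsupported thermal image format: ", ext, call. = FALSE)
  }
  invisible(path)
}
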