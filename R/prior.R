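#' Build the average prior shape from a set of foot contours
#'
#' Each training contour is resampled to `n` points, oriented
#' counterclockwise, start-aligned at the heel and translated so its
#' gravity center sits at the origin; the prior is the pointwise mean of
#' the registered curves. The result is rotated to a canonical vertical
#' orientation (principal axis along y, toes — the narrower end — pointing
#' up) and its curvature and fourth-derivative profiles are precomputed
#' for the snake energies.
#'
#' @param contours a list of contours (tibbles/data frames with `x`, `y`).
#' @param n number of prior points.
#' @return an object of class `prior_shape` with fields `points` (centered
#'   tibble), `n`, and the profile tibble of [curvature_profile()].
#' @export
build_prior_shape <- function(contours, n = 200) {
  if (length(contours) < 2) {
    stop("at least 2 training contours are required", call. = FALSE)
  }
  pers <- vapply(contours, contour_perimeter, 0)
  if (max(pers) / min(pers) > 3) {
    warning("training contours have widely inconsistent scales ",
      "(perimeter ratio > 3)",
      call. = FALSE
    )
  }
  reg <- lapply(contours, function(ct) {
    p <- align_start(resample_contour(ct, n))
    p$x <- p$x - mean(p$x)
    p$y <- p$y - mean(p$y)
    p
  })
  avg <- tibble::tibble(
    x = rowMeans(do.call(cbind, lapply(reg, `[[`, "x"))),
    y = rowMeans(do.call(cbind, lapply(reg, `[[`, "y")))
  )
  new_prior_shape(.canonicalize_vertical(avg), n)
}

new_prior_shape <- function(points, n) {
  points <- align_start(resample_contour(points, n))
  points$x <- points$x - mean(points$x)
  points$y <- points$y - mean(points$y)
  structure(
    list(points = points, n = n, profile = curvature_profile(points)),
    class = "prior_shape"
  )
}

# Rotate so the principal axis is vertical with the narrow (toe) end up.
.canonicalize_vertical <- function(points) {
  p <- contour_matrix(points)
  p <- sweep(p, 2, colMeans(p))
  ev <- eigen(stats::cov(p))
  axis <- ev$vectors[, 1] # principal direction
  ang <- atan2(axis[1], axis[2]) # rotate axis onto +y
  rot <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
  q <- p %*% t(rot)
  up <- q[, 2] < 0
  if (mean(abs(q[up, 1])) > mean(abs(q[!up, 1]))) {
    q <- -q # narrow end (smaller lateral spread) goes up
  }
  tibble::tibble(x = q[, 1], y = q[, 2])
}

#' @export
print.prior_shape <- function(x, ...) {
  cat(sprintf(
    "<prior_shape> %d points, perimeter %.1f px\n",
    x$n, contour_perimeter(x$points)
  ))
  invisible(x)
}

#' Initial snake contour from the prior shape
#'
#' The prior contour is downsized by `scale` about its centroid (the
#' reference pipeline uses a factor of 2), kept in its canonical vertical
#' orientation, and translated so its centroid lies at `center` — normally
#' the Otsu/morphology gravity center of the foot, which places the
#' initialization inside the plantar surface.
#'
#' @param prior a [build_prior_shape()] result.
#' @param center target centroid `c(x, y)`, px.
#' @param scale downsizing factor (>= 1).
#' @param dim optional `c(rows, cols)`; when given, an initialization
#'   extending outside the image is an error.
#' @return a contour tibble.
#' @export
make_initial_contour <- function(prior, center, scale = 2, dim = NULL) {
  stopifnot(inherits(prior, "prior_shape"), scale >= 1)
  out <- tibble::tibble(
    x = prior$points$x / scale + center[1],
    y = prior$points$y / scale + center[2]
  )
  if (!is.null(dim)) {
    if (min(out$x) < 0 || min(out$y) < 0 || max(out$x) > dim[2] - 1 ||
      max(out$y) > dim[1] - 1) {
      stop("initial contour would be clipped by the image bounds",
        call. = FALSE
      )
    }
  }
  out
}

#' Default prior shape from held-out phantom ground truth
#'
#' Averages the ground-truth contours of `n_contours` phantoms generated
#' from a dedicated seed stream, emulating the expert-contour averaging
#' step on images held out from any evaluation suite.
#'
#' @param n number of prior points.
#' @param seed seed of the held-out training stream.
#' @param n_contours number of training contours (default 10).
#' @param spec a [phantom_spec()].
#' @return a `prior_shape`.
#' @export
default_prior <- function(n = 200, seed = 990L, n_contours = 10,
                          spec = phantom_spec()) {
  seeds <- withr::with_seed(seed, sample.int(1e9, n_contours))
  build_prior_shape(lapply(seeds, function(s) {
    generate_foot_contour(spec, s)
  }), n)
}

#' Read and write prior shapes
#'
#' The prior is stored as a contour CSV; profiles are recomputed on read.
#'
#' @param path CSV path.
#' @param prior a `prior_shape`.
#' @return `read_prior()` returns a `prior_shape`; `write_prior()` returns
#'   `path` invisibly.
#' @export
read_prior <- function(path) {
  pts <- read_contour_csv(path)
  new_prior_shape(pts, nrow(pts))
}

#' @rdname read_prior
#' @export
write_prior <- function(prior, path) {
  write_contour_csv(prior$points, path)
}
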