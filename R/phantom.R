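#' Specification of the synthetic thermal foot phantom
#'
#' The phantom emulates freehand plantar-foot thermograms: a vertically
#' oriented foot on a ~20 degC background, a butterfly temperature pattern
#' (warmest at the arch, coolest at the toes), and strong false boundaries
#' from other body parts (legs, ankles) outside the plantar surface. The
#' default working frame is 385 x 257 pixels per foot at ~1 mm/px.
#'
#' @param shape integer vector `c(rows, cols)` of the per-foot frame.
#' @param ambient background (room) temperature, degC.
#' @param base foot base temperature, degC.
#' @param arch arch peak temperature, degC (warmest point of the butterfly).
#' @param toes toe temperature, degC (coolest foot region).
#' @param clutter_n number of non-foot warm clutter sources.
#' @param clutter_temp temperature range of the clutter sources, degC.
#' @param foot_scale multiplicative scale of the foot size.
#' @param scale_jitter relative size jitter across seeds.
#' @param position_jitter maximal center displacement, px.
#' @param orientation_jitter maximal deviation from vertical, degrees
#'   (at most 15).
#' @param harmonic_amp relative amplitude budget of the low-order radial
#'   harmonics deforming the base ellipse into a foot-like outline (<= 8%
#'   total effect; 0 gives an exact ellipse).
#' @param pixel_size mm per pixel (~1 for a 40 cm field over ~400 px).
#' @param blur_sigma optics blur, px.
#' @param n_points number of ground-truth contour points.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(385L, 257L), ambient = 20, base = 30,
                         arch = 32, toes = 27.5, clutter_n = 3L,
                         clutter_temp = c(28, 34), foot_scale = 1,
                         scale_jitter = 0.05, position_jitter = 8,
                         orientation_jitter = 5, harmonic_amp = 0.06,
                         pixel_size = 1.0, blur_sigma = 1.5,
                         n_points = 200L) {
  stopifnot(
    length(shape) == 2, all(shape >= 64),
    arch > base, base > toes, toes > ambient,
    abs(orientation_jitter) <= 15, harmonic_amp >= 0, harmonic_amp <= 0.0616,
    clutter_temp[2] >= clutter_temp[1]
  )
  structure(
    list(
      shape = as.integer(shape), ambient = ambient, base = base, arch = arch,
      toes = toes, clutter_n = as.integer(clutter_n),
      clutter_temp = clutter_temp, foot_scale = foot_scale,
      scale_jitter = scale_jitter, position_jitter = position_jitter,
      orientation_jitter = orientation_jitter, harmonic_amp = harmonic_amp,
      pixel_size = pixel_size, blur_sigma = blur_sigma,
      n_points = as.integer(n_points)
    ),
    class = "phantom_spec"
  )
}

# Foot outline sampled from the current RNG state: a vertical ellipse with
# length ~3x width, deformed by a fixed foot-like harmonic pair (broadened
# forefoot, rounded heel) plus seeded low-order harmonics, then rotated and
# translated. Total relative radial deformation stays below 8%.
.gen_foot_contour <- function(spec, center = NULL) {
  a <- 138 * spec$foot_scale *
    (1 + runif(1, -spec$scale_jitter, spec$scale_jitter))
  b <- a / 3 * (1 + runif(1, -0.08, 0.08))
  phi <- seq(0, 2 * pi, length.out = 721)[-721]
  r_ell <- 1 / sqrt(cos(phi)^2 / b^2 + sin(phi)^2 / a^2)
  amp <- spec$harmonic_amp
  f <- 1 + amp * (0.6 * (-sin(phi)) - 0.3 * cos(2 * phi))
  for (k in 2:5) {
    f <- f + runif(1, -1, 1) * 0.05 * amp * cos(k * phi) +
      runif(1, -1, 1) * 0.05 * amp * sin(k * phi)
  }
  r <- r_ell * f
  x <- r * cos(phi)
  y <- r * sin(phi)
  ang <- runif(1, -1, 1) * spec$orientation_jitter * pi / 180
  xr <- x * cos(ang) - y * sin(ang)
  yr <- x * sin(ang) + y * cos(ang)
  if (is.null(center)) {
    center <- c(
      (spec$shape[2] - 1) / 2 + runif(1, -1, 1) * spec$position_jitter,
      (spec$shape[1] - 1) / 2 + runif(1, -1, 1) * spec$position_jitter
    )
  }
  pts <- tibble::tibble(x = xr + center[1], y = yr + center[2])
  align_start(resample_contour(pts, spec$n_points))
}

#' Generate a seeded ground-truth foot contour
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed; the same seed gives a bitwise-identical contour.
#' @return a contour tibble with `spec$n_points` points, counterclockwise,
#'   start point at the heel.
#' @export
generate_foot_contour <- function(spec = phantom_spec(), seed = 1L) {
  withr::with_seed(seed, .gen_foot_contour(spec))
}

# Smooth butterfly interior temperature field evaluated on the full grid.
.butterfly_field <- function(spec, contour, nr, nc) {
  cx <- mean(contour$x)
  cy <- mean(contour$y)
  ylim <- range(contour$y)
  len <- diff(ylim)
  xg <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
  yg <- matrix(0:(nr - 1), nr, nc)
  gauss2 <- function(x0, y0, sx, sy) {
    exp(-((xg - x0)^2 / (2 * sx^2) + (yg - y0)^2 / (2 * sy^2)))
  }
  spec$base +
    (spec$arch - spec$base) * gauss2(cx, cy, 0.22 * len, 0.22 * len) +
    (spec$toes - spec$base - 0.5) *
      gauss2(cx, ylim[1] + 0.10 * len, 0.25 * len, 0.10 * len) +
    (-1.5) * gauss2(cx, ylim[2] - 0.08 * len, 0.12 * len, 0.10 * len)
}

# Place warm elliptical clutter blobs outside the (dilated) union of foot
# masks: the first blob is a "leg" above the foot and is guaranteed warm;
# the rest go above or laterally. Returns the updated grid.
.add_clutter <- function(grid, forbid, spec, contours) {
  nr <- nrow(grid)
  nc <- ncol(grid)
  cmask <- matrix(FALSE, nr, nc)
  xg <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
  yg <- matrix(0:(nr - 1), nr, nc)
  ymin_feet <- min(vapply(contours, function(ct) min(ct$y), 0))
  for (i in seq_len(spec$clutter_n)) {
    temp <- if (i == 1) {
      runif(1, max(spec$clutter_temp[1], 32), spec$clutter_temp[2])
    } else {
      runif(1, spec$clutter_temp[1], spec$clutter_temp[2])
    }
    placed <- FALSE
    for (attempt in 1:100) {
      ra <- runif(1, 25, 55)
      rb <- runif(1, 12, 28)
      if (i <= 2) { # legs: tall blobs above the feet, clipped by the border
        x0 <- runif(1, 0.2, 0.8) * (nc - 1)
        y0 <- runif(1, -0.5, 0.6) * max(ymin_feet - 20, 10)
        tmp <- ra
        ra <- rb
        rb <- tmp # vertical elongation
      } else { # lateral sources
        x0 <- if (runif(1) < 0.5) runif(1, 0, 25) else runif(1, nc - 26, nc - 1)
        y0 <- runif(1, 0.15, 0.85) * (nr - 1)
      }
      blob <- ((xg - x0)^2 / ra^2 + (yg - y0)^2 / rb^2) <= 1
      if (!any(blob)) next
      if (!any(blob & forbid)) {
        grid[blob] <- temp
        cmask <- cmask | blob
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("could not place clutter outside the foot after 100 attempts",
        call. = FALSE
      )
    }
  }
  list(grid = grid, clutter = cmask)
}

.render_scene <- function(spec, contours, nr, nc) {
  xg <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
  yg <- matrix(0:(nr - 1), nr, nc)
  psi <- runif(1, 0, 2 * pi)
  ramp <- xg * cos(psi) + yg * sin(psi)
  ramp <- (ramp - min(ramp)) / max(diff(range(ramp)), 1) * 0.8
  grid <- spec$ambient + ramp
  masks <- lapply(contours, rasterize_mask, nrow = nr, ncol = nc)
  for (i in seq_along(contours)) {
    interior <- .butterfly_field(spec, contours[[i]], nr, nc)
    grid[masks[[i]] == 1L] <- interior[masks[[i]] == 1L]
  }
  forbid <- Reduce(`|`, lapply(masks, function(m) m == 1L))
  forbid <- as.matrix(EBImage::dilate(
    forbid * 1, EBImage::makeBrush(21, "disc")
  )) > 0
  clutter <- matrix(FALSE, nr, nc)
  if (spec$clutter_n > 0) {
    cl <- .add_clutter(grid, forbid, spec, contours)
    grid <- cl$grid
    clutter <- cl$clutter
  }
  grid <- gaussian_smooth(grid, spec$blur_sigma)
  list(grid = grid, masks = masks, clutter = clutter * 1L)
}

#' Render a seeded synthetic plantar-foot thermal image
#'
#' Produces a single-foot phantom with ground truth: smooth background at
#' ambient temperature with a mild (< 1 degC) gradient, butterfly interior
#' field, warm clutter blobs strictly outside the foot (emulating legs and
#' lateral thermal sources, creating false boundaries at least as strong as
#' the true one), and a global optics blur. Bitwise reproducible for a
#' fixed seed.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed.
#' @return an object of class `phantom_sample`: list with `image`
#'   ([thermal_image()]), `contour` (ground-truth tibble), `mask`
#'   (rasterized ground truth) and `meta`.
#' @export
render_phantom <- function(spec = phantom_spec(), seed = 1L) {
  withr::with_seed(seed, {
    contour <- .gen_foot_contour(spec)
    sc <- .render_scene(spec, list(contour), spec$shape[1], spec$shape[2])
    structure(
      list(
        image = thermal_image(sc$grid, spec$pixel_size),
        contour = contour,
        mask = sc$masks[[1]],
        clutter = sc$clutter,
        meta = list(seed = seed, spec = spec, lesions = list())
      ),
      class = "phantom_sample"
    )
  })
}

#' Render a two-feet phantom frame
#'
#' A 480 x 640 frame with both feet vertically oriented and separated by
#' roughly 10 cm (~100 px at 1 mm/px), as acquired before the
#' split-and-flip preprocessing step. The left foot is the mirrored
#' sibling of an independently seeded outline.
#'
#' @param spec a [phantom_spec()]; `shape` is ignored (the frame is
#'   480 x 640).
#' @param seed integer seed.
#' @return a list of class `phantom_pair` with `image`, `contours`
#'   (list `left`, `right`) and `masks`.
#' @export
render_phantom_pair <- function(spec = phantom_spec(), seed = 1L) {
  nr <- 480L
  nc <- 640L
  withr::with_seed(seed, {
    gap <- 100 # px between the two feet surfaces
    half_w <- 138 * spec$foot_scale / 3
    off <- (gap + 2 * half_w) / 2
    right <- .gen_foot_contour(spec, center = c(nc / 2 + off, nr / 2))
    # the left foot of a healthy subject is close to the mirrored right
    # foot: mirror the same outline and add small within-subject pose
    # jitter (the feet are never posed perfectly symmetrically)
    ang <- runif(1, -1, 1) * 2 * pi / 180
    jit <- runif(2, -3, 3)
    cx <- mean(right$x)
    cy <- mean(right$y)
    lx <- -(right$x - cx)
    ly <- right$y - cy
    left <- tibble::tibble(
      x = lx * cos(ang) - ly * sin(ang) + (nc / 2 - off) + jit[1],
      y = lx * sin(ang) + ly * cos(ang) + nr / 2 + jit[2]
    )
    left <- align_start(resample_contour(left, spec$n_points))
    sc <- .render_scene(spec, list(left, right), nr, nc)
    structure(
      list(
        image = thermal_image(sc$grid, spec$pixel_size),
        contours = list(left = left, right = right),
        masks = list(left = sc$masks[[1]], right = sc$masks[[2]]),
        meta = list(seed = seed, spec = spec)
      ),
      class = "phantom_pair"
    )
  })
}

#' Add zero-mean Gaussian white noise at a prescribed SNR
#'
#' The noise variance is `var(image) / 10^(snr_db / 10)`, i.i.d. per pixel,
#' matching the usual definition of the signal-to-noise ratio in decibels.
#'
#' @param image a [thermal_image()].
#' @param snr_db signal-to-noise ratio, dB; `Inf` returns the input
#'   unchanged.
#' @param seed integer seed.
#' @return a noisy [thermal_image()].
#' @export
add_gaussian_noise <- function(image, snr_db, seed = 1L) {
  image <- as_thermal_image(image)
  if (is.infinite(snr_db) && snr_db > 0) {
    return(image)
  }
  stopifnot(is.finite(snr_db))
  v <- var(as.vector(image$grid))
  if (v <= 0) stop("flat image: SNR is undefined", call. = FALSE)
  sigma <- sqrt(v / 10^(snr_db / 10))
  withr::with_seed(seed, {
    g <- image$grid + rnorm(length(image$grid), 0, sigma)
  })
  structure(list(grid = matrix(g, nrow(image$grid)), pixel_size =
    image$pixel_size), class = "thermal_image")
}

#' Inject a focal hyperthermic lesion into a phantom
#'
#' Adds a plateau of amplitude `delta_t` on a disk of radius `radius_px`
#' with a smooth cosine-tapered skirt decaying to zero over one further
#' radius, all fully inside the foot. The nominal radius is thus the
#' extent of the full temperature elevation (a "1 cm lesion" is elevated
#' by the full `delta_t` over a 1 cm disk, as a clinical hot spot would
#' read on a thermogram). The lesion geometry is recorded in the sample
#' metadata.
#'
#' @param sample a `phantom_sample`.
#' @param center lesion center `c(x, y)`, px.
#' @param radius_px plateau radius, px (~5 px for a 1 cm diameter spot at
#'   1 mm/px; the taper extends to `2 * radius_px`).
#' @param delta_t peak temperature elevation, degC.
#' @return the modified `phantom_sample`.
#' @export
inject_hyperthermia <- function(sample, center, radius_px, delta_t) {
  stopifnot(inherits(sample, "phantom_sample"))
  grid <- sample$image$grid
  nr <- nrow(grid)
  nc <- ncol(grid)
  xg <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
  yg <- matrix(0:(nr - 1), nr, nc)
  r <- sqrt((xg - center[1])^2 + (yg - center[2])^2)
  support <- r <= 2 * radius_px
  if (!all(sample$mask[support] == 1L)) {
    stop("lesion disk extends outside the foot mask", call. = FALSE)
  }
  bump <- matrix(0, nr, nc)
  bump[r <= radius_px] <- delta_t
  skirt <- r > radius_px & support
  bump[skirt] <- delta_t * 0.5 *
    (1 + cos(pi * (r[skirt] - radius_px) / radius_px))
  sample$image$grid <- grid + bump
  sample$meta$lesions <- c(
    sample$meta$lesions,
    list(list(center = center, radius_px = radius_px, delta_t = delta_t))
  )
  sample
}

#' Generate a seeded suite of phantoms
#'
#' @param n number of phantoms.
#' @param seed master seed; per-image seeds are drawn from it.
#' @param spec a [phantom_spec()].
#' @return a list of `phantom_sample` objects.
#' @export
phantom_suite <- function(n = 50, seed = 0L, spec = phantom_spec()) {
  seeds <- withr::with_seed(seed, sample.int(1e9, n))
  lapply(seeds, function(s) render_phantom(spec, s))
}
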