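# Shared fixtures, generated in code. Heavier shared objects are memoized
# so independent test files do not recompute them.

circle_contour <- function(center = c(0, 0), r = 50, n = 256, phase = 0) {
  t <- phase + 2 * pi * (seq_len(n) - 1) / n
  tibble::tibble(x = center[1] + r * cos(t), y = center[2] + r * sin(t))
}

# smooth closed curve from a handful of Fourier harmonics (complex form);
# returns the points and the coefficient list for analytic derivatives
harmonic_contour <- function(n = 256, seed = 4L, n_harm = 5) {
  withr::with_seed(seed, {
    coef <- list(
      k = c(1, sample(2:3, n_harm - 1, replace = TRUE)),
      a = complex(
        real = c(60, runif(n_harm - 1, -0.2, 0.2)),
        imaginary = c(0, runif(n_harm - 1, -0.2, 0.2))
      )
    )
  })
  s <- (seq_len(n) - 1) / n
  z <- rep(150 + 150i, n)
  for (j in seq_along(coef$k)) {
    z <- z + coef$a[j] * exp(2i * pi * coef$k[j] * s)
  }
  list(points = tibble::tibble(x = Re(z), y = Im(z)), coef = coef, s = s)
}

local_prior <- local({
  value <- NULL
  function() {
    if (is.null(value)) value <<- default_prior(200)
    value
  }
})

local_easy_sample <- local({
  value <- NULL
  function() {
    if (is.null(value)) {
      value <<- render_phantom(phantom_spec(clutter_n = 0), seed = 5)
    }
    value
  }
})

local_default_sample <- local({
  value <- NULL
  function() {
    if (is.null(value)) value <<- render_phantom(phantom_spec(), seed = 6)
    value
  }
})

# brute-force even-odd point-in-polygon with the same half-open crossing
# rule documented for the rasterizer
point_in_polygon <- function(px, py, xs, ys) {
  n <- length(xs)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((ys[i] <= py && py < ys[j]) || (ys[j] <= py && py < ys[i])) {
      xc <- xs[i] + (py - ys[i]) * (xs[j] - xs[i]) / (ys[j] - ys[i])
      if (xc > px) inside <- !inside
    }
    j <- i
  }
  inside
}

# exact distance from a point to a closed polygon (point-to-segment)
polygon_distance <- function(px, py, xs, ys) {
  n <- length(xs)
  j <- c(2:n, 1)
  vx <- xs[j] - xs
  vy <- ys[j] - ys
  len2 <- pmax(vx^2 + vy^2, 1e-300)
  t <- pmin(pmax(((px - xs) * vx + (py - ys) * vy) / len2, 0), 1)
  min(sqrt((px - (xs + t * vx))^2 + (py - (ys + t * vy))^2))
}
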