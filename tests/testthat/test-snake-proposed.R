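test_that("the external force field behaves as the literal operator", {
  expect_warning(
    ff <- external_force_field(matrix(1, 64, 64)),
    "constant"
  )
  expect_true(all(ff$fx == 0) && all(ff$fy == 0))

  # 1-D step edge: force points toward the edge from both sides
  step <- matrix(0, 64, 64)
  step[, 33:64] <- 10
  f <- external_force_field(step, w_edge = 1, sigma_img = 1, cap_quantile = 1)
  expect_gt(f$fx[32, 31], 0) # left of the edge: pulled right
  expect_lt(f$fx[32, 35], 0) # right of the edge: pulled left

  # symbolic oracle: I = x^2 gives |grad I|^2 = 4 x^2, force_x = w * 8 x
  nc <- 65
  xg <- matrix(0:(nc - 1), 64, nc, byrow = TRUE)
  f2 <- external_force_field(xg^2,
    w_edge = 3, sigma_img = 0.5,
    cap_quantile = 1
  )
  interior <- 10:50
  expect_equal(
    f2$fx[32, interior], 3 * 8 * (interior - 1),
    tolerance = 0.05
  )
  expect_lt(max(abs(f2$fy[10:50, interior])), 1e-6)
})

test_that("the prior curvature energy is zero exactly on similarity transforms", {
  pr <- local_prior()
  e0 <- prior_shape_energy(pr$points, pr, gamma = 35)
  expect_equal(e0$total, 0, tolerance = 1e-12)
  expect_equal(e0$zeta, rep(1, 200), tolerance = 1e-9)

  scaled <- tibble::tibble(x = pr$points$x * 3, y = pr$points$y * 3)
  es <- prior_shape_energy(scaled, pr, gamma = 35)
  expect_equal(es$total, 0, tolerance = 1e-9)
  expect_equal(es$zeta, rep(3, 200), tolerance = 1e-9)

  # reference magnitude: a genuinely different (anisotropically
  # stretched) shape, resampled back to uniform spacing
  base <- prior_shape_energy(
    align_start(resample_contour(
      tibble::tibble(x = pr$points$x * 2, y = pr$points$y), 200
    )), pr, 35
  )$total
  withr::with_seed(3, {
    for (i in 1:5) {
      ang <- runif(1, 0, 2 * pi)
      sc <- runif(1, 0.3, 3)
      tr <- runif(2, -50, 50)
      p <- as.matrix(pr$points) %*%
        (sc * matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)) # C R^T
      # the transform preserves the point order, so index 1 of both curves
      # is the same material (heel) point
      moved <- tibble::tibble(x = p[, 1] + tr[1], y = p[, 2] + tr[2])
      et <- prior_shape_energy(moved, pr, gamma = 35)
      expect_lt(et$total, 1e-6 * max(base, 1))
    }
  })
})

test_that("the prior energy matches a straight-from-formula recomputation", {
  pr <- local_prior()
  bumped <- pr$points
  bumped$x[50] <- bumped$x[50] + 0.1 # keeps the spacing near-uniform
  e <- prior_shape_energy(bumped, pr, gamma = 35)
  expect_gt(e$total, 0)
  # independent recomputation from the definition (local-frame reading)
  n <- 200
  local_css <- function(m) {
    d1 <- (m[c(2:n, 1), ] - m[c(n, 1:(n - 1)), ]) * n / 2
    d2 <- (m[c(2:n, 1), ] - 2 * m + m[c(n, 1:(n - 1)), ]) * n^2
    tang <- d1 / sqrt(rowSums(d1^2))
    nrml <- cbind(tang[, 2], -tang[, 1])
    cbind(rowSums(d2 * tang), rowSums(d2 * nrml))
  }
  css <- local_css(as.matrix(bumped))
  css_s <- local_css(as.matrix(pr$points))
  zeta <- sqrt(rowSums(css^2)) / sqrt(rowSums(css_s^2))
  ref <- mean(35 * rowSums((css - zeta * css_s)^2))
  expect_equal(e$total, ref, tolerance = 1e-12)
  expect_error(
    prior_shape_energy(circle_contour(n = 64), pr),
    "same number"
  )
})

test_that("single evolution steps reproduce the textbook limits", {
  pr <- local_prior()
  zero_field <- structure(
    list(
      fx = matrix(0, 400, 400), fy = matrix(0, 400, 400),
      emag2 = matrix(0, 400, 400), w_edge = 0
    ),
    class = "force_field"
  )
  circ <- align_start(circle_contour(c(200, 200), 80, 200))

  # curvature flow: with no external force the circle shrinks
  p_shrink <- snake_params(
    alpha = 0.5, beta = 0, gamma = 0, delta = 1e-9, tau = 0.5
  )
  shrunk <- evolve_step(circ, local_prior(), zero_field, p_shrink)
  r_new <- sqrt((shrunk$x - 200)^2 + (shrunk$y - 200)^2)
  expect_true(all(r_new < 80))

  # pure balloon: every point moves exactly tau * delta along its normal
  p_ball <- snake_params(
    alpha = 0, beta = 0, gamma = 0, delta = 0.3, tau = 0.5
  )
  grown <- evolve_step(circ, local_prior(), zero_field, p_ball)
  r_g <- sqrt((grown$x - 200)^2 + (grown$y - 200)^2)
  expect_equal(r_g, rep(80 + 0.5 * 0.3, 200), tolerance = 1e-6)
})

test_that("the semi-implicit step agrees with a small-step explicit oracle", {
  pr <- local_prior()
  s <- local_easy_sample()
  loc <- locate_foot(s$image)
  init <- align_start(resample_contour(
    make_initial_contour(pr, loc$center, 2), 200
  ))
  params <- snake_params(
    alpha = 0.1, beta = 0.5, gamma = 0.5, delta = 0.2,
    tau = 0.05, sigma_img = 2
  )
  field <- external_force_field(s$image, 20, 2, 0.99, normalize = TRUE)
  implicit <- evolve_step(init, pr, field, params)

  # independent explicit Euler at tau/100, with its own difference code
  n <- 200
  C <- as.matrix(init)
  ps <- as.matrix(pr$points)
  d2 <- function(m) m[c(2:n, 1), ] - 2 * m + m[c(n, 1:(n - 1)), ]
  d4 <- function(m) d2(d2(m))
  sub <- params$tau / 100
  for (k in 1:100) {
    der1 <- (C[c(2:n, 1), ] - C[c(n, 1:(n - 1)), ]) / 2
    nrm <- cbind(der1[, 2], -der1[, 1])
    nrm <- nrm / sqrt(rowSums(nrm^2))
    fx <- thermofoot:::bilinear_sample(field$fx, C[, 1], C[, 2])
    fy <- thermofoot:::bilinear_sample(field$fy, C[, 1], C[, 2])
    zeta <- pmin(
      sqrt(rowSums(d2(C)^2)) / sqrt(rowSums(d2(ps)^2)), 10
    )
    force <- cbind(fx, fy) + params$delta * nrm +
      params$gamma * zeta * d4(ps)
    internal <- params$alpha * d2(C) -
      (params$beta + params$gamma) * d4(C)
    C <- C + sub * (internal + force)
  }
  expect_lt(max(sqrt(rowSums((as.matrix(implicit) - C)^2))), 0.1)
})

test_that("the snake segments an easy phantom almost perfectly", {
  pr <- local_prior()
  s <- local_easy_sample()
  loc <- locate_foot(s$image)
  fit <- segment_snake(
    s$image, make_initial_contour(pr, loc$center, 2), pr
  )
  expect_gte(dice_coefficient(fit$mask, s$mask), 0.97)
  expect_true(fit$converged)
  expect_lte(fit$iterations, snake_params()$max_iter)
  expect_true(all(is.finite(fit$energy$e_total)))
  # tidy/glance interface
  td <- tidy(fit)
  expect_equal(nrow(td), 200)
  gl <- glance(fit)
  expect_equal(gl$method, "proposed")
  expect_true(gl$converged)
})

test_that("growing gamma draws the final curvature profile toward the prior", {
  pr <- local_prior()
  s0 <- local_default_sample()
  # under heavy noise the prior term visibly shapes the result
  noisy <- add_gaussian_noise(s0$image, 5, 99)
  loc <- locate_foot(noisy)
  init <- make_initial_contour(pr, loc$center, 2)
  norm_profile <- function(points) {
    prof <- curvature_profile(align_start(resample_contour(points, 200)))
    css <- sqrt(prof$d2x^2 + prof$d2y^2)
    css / sqrt(mean(css^2))
  }
  target <- norm_profile(pr$points)
  dist <- sapply(c(0, 35, 350), function(g) {
    fit <- suppressWarnings(segment_snake(
      noisy, init, pr,
      snake_params(gamma = if (g == 0) 1e-9 else g)
    ))
    sqrt(mean((norm_profile(fit$contour) - target)^2))
  })
  expect_true(all(diff(dist) <= 1e-6))
})

test_that("the segmented foot avoids clutter regions", {
  pr <- local_prior()
  hits <- 0
  n <- 10
  for (seed in seq(601, 600 + n)) {
    s <- render_phantom(phantom_spec(), seed)
    loc <- locate_foot(s$image)
    fit <- suppressWarnings(segment_snake(
      s$image, make_initial_contour(pr, loc$center, 2), pr
    ))
    hits <- hits + (sum(fit$mask & s$clutter) > 0)
  }
  expect_lte(hits / n, 0.1)
})
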