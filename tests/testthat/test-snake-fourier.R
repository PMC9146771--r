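test_that("Fourier descriptors follow the DFT conventions", {
  circ <- circle_contour(c(30, 40), 12, 64)
  fd <- fourier_descriptors(circ)
  expect_equal(fd$z[1], complex(real = 64 * 30, imaginary = 64 * 40),
    tolerance = 1e-9
  )
  expect_equal(Mod(fd$z[2]), 64 * 12, tolerance = 1e-6)
  expect_lt(max(Mod(fd$z[-c(1, 2)])), 1e-9 * 12)

  shifted <- circ
  shifted$x <- shifted$x + 7
  shifted$y <- shifted$y - 3
  fd2 <- fourier_descriptors(shifted)
  expect_lt(max(Mod(fd2$z[-1] - fd$z[-1])), 1e-9)
  expect_false(isTRUE(all.equal(fd2$z[1], fd$z[1])))

  expect_error(fourier_descriptors(circle_contour(n = 15)), "even")

  # brute-force O(n^2) DFT sum oracle
  withr::with_seed(5, {
    pts <- tibble::tibble(x = runif(16, 0, 30), y = runif(16, 0, 30))
  })
  fd3 <- fourier_descriptors(pts)
  z <- complex(real = pts$x, imaginary = pts$y)
  ref <- sapply(0:15, function(k) {
    sum(z * exp(-2i * pi * k * (0:15) / 16))
  })
  expect_lt(max(Mod(fd3$z - ref)), 1e-10 * max(Mod(ref)))
})

test_that("normalized descriptors are similarity invariant", {
  a <- normalize_descriptors(fourier_descriptors(
    circle_contour(c(0, 0), 10, 64)
  ))
  b <- normalize_descriptors(fourier_descriptors(
    circle_contour(c(55, -20), 50, 64)
  ))
  expect_lt(max(Mod(a$z - b$z)), 1e-9)
  expect_equal(Mod(a$z[2]), 1, tolerance = 1e-12)
  expect_equal(Arg(a$z[2]), 0, tolerance = 1e-12)
  expect_equal(a$z[1], 0 + 0i)

  h <- harmonic_contour(128, seed = 8)$points
  rot <- pi / 6
  hr <- tibble::tibble(
    x = (h$x - mean(h$x)) * cos(rot) - (h$y - mean(h$y)) * sin(rot),
    y = (h$x - mean(h$x)) * sin(rot) + (h$y - mean(h$y)) * cos(rot)
  )
  za <- normalize_descriptors(fourier_descriptors(h))
  zb <- normalize_descriptors(fourier_descriptors(hr))
  expect_lt(max(Mod(za$z - zb$z)), 1e-9)

  degenerate <- structure(
    list(z = complex(real = c(5, 0, 1, 2)), n = 4),
    class = "fourier_descriptors"
  )
  expect_error(normalize_descriptors(degenerate), "zero amplitude")
})

test_that("the Fourier prior energy vanishes on matched shapes", {
  pr <- local_prior()
  fd_star <- fourier_descriptors(pr$points)
  expect_equal(fourier_prior_energy(fd_star, fd_star, 0.5), 0)

  sim <- tibble::tibble(
    x = pr$points$x * 1.7 + 40, y = pr$points$y * 1.7 - 12
  )
  expect_lt(
    fourier_prior_energy(fourier_descriptors(sim), fd_star, 0.5),
    1e-9
  )

  moved <- pr$points
  moved$x[10] <- moved$x[10] + 5
  e <- fourier_prior_energy(fourier_descriptors(moved), fd_star, 0.5)
  expect_gt(e, 0)
  # direct-sum recomputation
  zh <- function(p) {
    z <- sapply(0:199, function(k) {
      sum(complex(real = p$x, imaginary = p$y) *
        exp(-2i * pi * k * (0:199) / 200))
    })
    r1 <- Mod(z[2])
    out <- (z / r1) * Conj(z[2] / r1)
    out[1] <- 0
    out
  }
  expect_equal(e, 0.5 * sum(Mod(zh(moved) - zh(pr$points))^2),
    tolerance = 1e-9
  )
  expect_error(
    fourier_prior_energy(
      fourier_descriptors(circle_contour(n = 64)), fd_star, 0.5
    ),
    "lengths differ"
  )
})

test_that("a greedy pass equals the exhaustive per-point search oracle", {
  withr::with_seed(17, {
    emag2 <- matrix(runif(16 * 16), 16, 16)
  })
  n <- 10
  C <- as.matrix(circle_contour(c(8, 8), 4.3, n))
  prior_pts <- circle_contour(c(0, 0), 5, n)
  zs <- normalize_descriptors(fourier_descriptors(prior_pts))$z
  nrm <- thermofoot:::.outward_normals(C)
  pars <- list(alpha = 1.2, beta = 0.1, wedge = 5, delta = 0.1, gamma0 = 0.5)
  res <- thermofoot:::.cpp_greedy_pass(
    C, nrm, emag2, fft(complex(real = C[, 1], imaginary = C[, 2])), zs,
    pars$alpha, pars$beta, pars$wedge, pars$delta, pars$gamma0, 1L, 0
  )
  # independent sequential oracle with full DFT recomputation per candidate
  pts <- C
  dbar <- mean(sqrt(rowSums((C[c(2:n, 1), ] - C)^2)))
  norm01 <- function(v) {
    if (diff(range(v)) > 0) (v - min(v)) / diff(range(v)) else v * 0
  }
  prior_e <- function(m) {
    z <- fft(complex(real = m[, 1], imaginary = m[, 2]))
    r1 <- Mod(z[2])
    if (r1 < 1e-12) {
      return(1e12)
    }
    zh <- (z / r1) * Conj(z[2] / r1)
    zh[1] <- 0
    sum(Mod(zh - zs)^2)
  }
  for (i in 1:n) {
    prev <- pts[if (i == 1) n else i - 1, ]
    nxt <- pts[if (i == n) 1 else i + 1, ]
    cand <- expand.grid(dx = -1:1, dy = -1:1)[, c("dx", "dy")]
    ord <- order(cand$dy, cand$dx) # dy outer, dx inner
    cand <- cand[ord, ]
    cont <- curv <- img <- ball <- pri <- numeric(9)
    px <- py <- numeric(9)
    for (j in 1:9) {
      p <- pmin(pmax(pts[i, ] + c(cand$dx[j], cand$dy[j]), 0), 15)
      px[j] <- p[1]
      py[j] <- p[2]
      cont[j] <- (dbar - sqrt(sum((p - prev)^2)))^2
      curv[j] <- sum((prev - 2 * p + nxt)^2)
      img[j] <- -thermofoot:::bilinear_sample(emag2, p[1], p[2])
      ball[j] <- -sum((p - pts[i, ]) * nrm[i, ]) / 1
      m2 <- pts
      m2[i, ] <- p
      pri[j] <- prior_e(m2)
    }
    tot <- pars$alpha * norm01(cont) + pars$beta * norm01(curv) +
      pars$wedge * norm01(img) + pars$delta * norm01(ball) +
      pars$gamma0 * norm01(pri)
    self <- which(cand$dx == 0 & cand$dy == 0)
    best <- self
    for (j in 1:9) if (tot[j] < tot[best] - 1e-12) best <- j
    pts[i, ] <- c(px[best], py[best])
  }
  expect_equal(unname(res$points), unname(pts), tolerance = 1e-12)
})

test_that("with no image and no prior the greedy contour contracts", {
  flat <- structure(
    list(
      fx = matrix(0, 96, 96), fy = matrix(0, 96, 96),
      emag2 = matrix(0, 96, 96), w_edge = 0
    ),
    class = "force_field"
  )
  pr <- build_prior_shape(
    list(circle_contour(c(0, 0), 30, 100), circle_contour(c(0, 0), 32, 100)),
    n = 20
  )
  img <- thermal_image(matrix(20, 96, 96) + 1e-9 * diag(96))
  # coarse irregular polygon: curvature minimization walks points toward
  # chord midpoints, shrinking the contour
  withr::with_seed(6, {
    ang <- sort(runif(20, 0, 2 * pi))
    init <- tibble::tibble(
      x = 48 + runif(20, 20, 35) * cos(ang),
      y = 48 + runif(20, 20, 35) * sin(ang)
    )
  })
  fit <- suppressWarnings(segment_greedy(
    img, init, pr,
    greedy_params(
      alpha = 0.1, beta = 1, gamma0 = 0, delta = 0, max_passes = 60,
      resample_every = 1000
    ),
    field = flat
  ))
  expect_lt(
    contour_perimeter(fit$contour),
    contour_perimeter(resample_contour(init, 20))
  )
})
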