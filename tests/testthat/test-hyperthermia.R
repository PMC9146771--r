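test_that("ICP recovers rigid transforms between contours", {
  # elongated, chirally asymmetric blob: pose is well determined
  s <- (0:199) / 200
  z <- 150 + 150i + 60 * exp(2i * pi * s) + 14 * exp(4i * pi * s) +
    9i * exp(-2i * pi * 3 * s)
  h <- resample_contour(tibble::tibble(x = Re(z), y = Im(z)), 720)
  tf0 <- icp_register(h, h)
  expect_lt(abs(tf0$theta), 1e-6)
  expect_lt(max(abs(tf0$t)), 1e-6)

  ang <- 10 * pi / 180
  moved <- tibble::tibble(
    x = h$x * cos(ang) - h$y * sin(ang) + 12,
    y = h$x * sin(ang) + h$y * cos(ang) - 7
  )
  tf <- icp_register(h, moved)
  expect_lt(abs(tf$theta - ang) * 180 / pi, 0.5)
  recovered <- apply_transform(h, tf)
  expect_lt(mean(sqrt((recovered$x - moved$x)^2 +
    (recovered$y - moved$y)^2)), 1)

  # rigid transforms cannot mirror: the residual stays large
  mirrored <- tibble::tibble(x = -h$x + 2 * mean(h$x), y = h$y)
  tfm <- suppressWarnings(icp_register(h, mirrored))
  expect_gt(tfm$residual, 5)
})

test_that("the |dT| map of a self-pair is numerically silent", {
  s <- local_easy_sample()
  ident <- structure(
    list(theta = 0, t = c(0, 0), R = diag(2), residual = 0),
    class = "rigid_transform"
  )
  map <- delta_t_map(s$image, s$image, s$mask, s$mask, ident)
  expect_lt(map$mean_dt, 0.05)
  expect_equal(sum(map$mask), sum(s$mask))
  gl <- glance(map)
  expect_named(gl, c("area_px", "mean_dt", "max_dt"))
})

test_that("an injected lesion appears at full amplitude in the |dT| map", {
  s <- local_easy_sample()
  center <- round(c(mean(s$contour$x), mean(s$contour$y) - 30))
  lesioned <- inject_hyperthermia(s, center, 8, 3)
  ident <- structure(
    list(theta = 0, t = c(0, 0), R = diag(2), residual = 0),
    class = "rigid_transform"
  )
  map <- delta_t_map(lesioned$image, s$image, s$mask, s$mask, ident)
  expect_equal(map$max_dt, 3, tolerance = 0.15)
  regions <- detect_hyperthermia(map, 2.2)
  expect_equal(nrow(regions), 1)
  expect_true(attr(regions, "hyperthermia"))
  # the detected region covers at least 80% of the full-amplitude disk
  xg <- matrix(0:(ncol(s$mask) - 1), nrow(s$mask), ncol(s$mask), byrow = TRUE)
  yg <- matrix(0:(nrow(s$mask) - 1), nrow(s$mask), ncol(s$mask))
  disk <- sqrt((xg - center[1])^2 + (yg - center[2])^2) <= 8
  hot <- !is.na(map$delta) & map$delta > 2.2
  expect_gte(sum(hot & disk) / sum(disk), 0.8)
})

test_that("|dT| of independently noisy pairs follows the folded normal", {
  s <- local_easy_sample()
  a <- add_gaussian_noise(s$image, 25, 101)
  b <- add_gaussian_noise(s$image, 25, 202)
  ident <- structure(
    list(theta = 0, t = c(0, 0), R = diag(2), residual = 0),
    class = "rigid_transform"
  )
  map <- delta_t_map(a, b, s$mask, s$mask, ident)
  sigma_n <- sqrt(var(as.vector(s$image$grid)) / 10^(25 / 10))
  # difference of two independent N(0, sigma_n^2): folded-normal mean,
  # mildly attenuated by the bilinear warp (identity here, so exact)
  expect_equal(map$mean_dt, sqrt(2) * sigma_n * sqrt(2 / pi),
    tolerance = 0.1
  )
})

test_that("hyperthermia detection thresholds and filters regions", {
  s <- local_easy_sample()
  ident <- structure(
    list(theta = 0, t = c(0, 0), R = diag(2), residual = 0),
    class = "rigid_transform"
  )
  quiet <- delta_t_map(s$image, s$image, s$mask, s$mask, ident)
  r0 <- detect_hyperthermia(quiet, 2.2)
  expect_equal(nrow(r0), 0)
  expect_false(attr(r0, "hyperthermia"))
  expect_equal(attr(r0, "min_area_px"), pi * 25, tolerance = 1e-9)

  lesioned <- inject_hyperthermia(
    s, round(c(mean(s$contour$x), mean(s$contour$y) - 30)), 8, 3
  )
  map <- delta_t_map(lesioned$image, s$image, s$mask, s$mask, ident)
  # monotone in the threshold: higher thresholds give nested regions
  hot_lo <- !is.na(map$delta) & map$delta > 2.2
  hot_hi <- !is.na(map$delta) & map$delta > 2.8
  expect_true(all(hot_lo[hot_hi]))
  expect_gte(
    detect_hyperthermia(map, 2.2)$area_px[1],
    detect_hyperthermia(map, 2.8)$area_px[1]
  )
})

test_that("swapping the feet changes the mean |dT| only marginally", {
  pair <- render_phantom_pair(phantom_spec(), seed = 77)
  # sensor noise gives the map a realistic nonzero baseline
  img <- add_gaussian_noise(pair$image, 25, 7)
  h <- split_and_flip(img)
  mr <- rasterize_mask(
    align_start(resample_contour(
      tibble::tibble(
        x = pair$contours$right$x - 320,
        y = pair$contours$right$y
      ), 200
    )), 480, 320
  )
  lf <- pair$contours$left
  ml <- rasterize_mask(
    align_start(resample_contour(
      tibble::tibble(x = 320 - 1 - lf$x, y = lf$y), 200
    )), 480, 320
  )
  tf <- icp_register(
    tibble::tibble(x = 320 - 1 - lf$x, y = lf$y),
    tibble::tibble(x = pair$contours$right$x - 320, y = pair$contours$right$y)
  )
  fwd <- delta_t_map(h$right, h$left_flipped, mr, ml, tf)
  inv <- structure(
    list(
      theta = -tf$theta, t = as.vector(-t(tf$R) %*% tf$t),
      R = t(tf$R), residual = tf$residual
    ),
    class = "rigid_transform"
  )
  bwd <- delta_t_map(h$left_flipped, h$right, ml, mr, inv)
  expect_lt(
    abs(fwd$mean_dt - bwd$mean_dt) / max(fwd$mean_dt, 1e-9), 0.02
  )
})

test_that("the end-to-end pipeline flags only lesioned pairs", {
  pr <- local_prior()
  pair <- render_phantom_pair(phantom_spec(), seed = 55)
  h <- split_and_flip(pair$image)
  res <- suppressWarnings(
    hyperthermia_pipeline(h$right, h$left_flipped, pr)
  )
  expect_false(attr(res$regions, "hyperthermia"))
  expect_lt(res$map$mean_dt, 1) # healthy feet: sub-degree asymmetry

  loc <- locate_foot(h$right)
  wrap <- structure(
    list(
      image = h$right, contour = NULL,
      mask = res$right_fit$mask, meta = list(lesions = list())
    ),
    class = "phantom_sample"
  )
  lesioned <- inject_hyperthermia(wrap, round(loc$center - c(0, 40)), 5, 3)
  res2 <- suppressWarnings(
    hyperthermia_pipeline(lesioned$image, h$left_flipped, pr)
  )
  expect_true(attr(res2$regions, "hyperthermia"))
  expect_equal(max(res2$regions$peak_dt), 3, tolerance = 0.3)
})
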