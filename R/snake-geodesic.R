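#' Edge-stopping map of the geodesic snake
#'
#' `g = 1 / (1 + b |grad(G_sigma * I)|^2)`, in (0, 1]; close to zero on
#' strong edges, exactly 1 where the smoothed gradient vanishes.
#'
#' @param image a [thermal_image()] or matrix.
#' @param b edge sensitivity (>= 0).
#' @param sigma Gaussian smoothing, px (> 0).
#' @return a matrix the size of the image.
#' @export
edge_stopping_map <- function(image, b = 0.1, sigma = 0.3) {
  stopifnot(b >= 0, sigma > 0)
  g <- .as_grid(image)
  sm <- gaussian_smooth(g, sigma)
  gr <- image_gradient(sm)
  1 / (1 + b * (gr$gx^2 + gr$gy^2))
}

#' Unsigned distance map to a placed prior curve
#'
#' Solves the eikonal equation `|grad d| = 1` by first-order fast marching
#' from the prior curve: pixels within a 2 px band of the polygon are
#' frozen at their exact point-to-segment distance, then the front is
#' propagated over the grid.
#'
#' @param contour the placed prior contour (px coordinates).
#' @param dim grid size `c(rows, cols)`.
#' @return a matrix of distances (px), zero on the curve.
#' @export
prior_distance_map <- function(contour, dim) {
  pts <- contour_matrix(as_contour(contour))
  nr <- as.integer(dim[1])
  nc <- as.integer(dim[2])
  if (min(pts[, 1]) < 0 || min(pts[, 2]) < 0 || max(pts[, 1]) > nc - 1 ||
    max(pts[, 2]) > nr - 1) {
    stop("prior curve extends outside the grid", call. = FALSE)
  }
  # exact band initialization
  seeds <- list()
  nxt <- cyc(pts, 1)
  band <- 2
  cand <- do.call(rbind, lapply(seq_len(nrow(pts)), function(i) {
    x0 <- pts[i, 1]
    y0 <- pts[i, 2]
    x1 <- nxt[i, 1]
    y1 <- nxt[i, 2]
    cs <- pmin(pmax(floor(min(x0, x1)) - band, 0), nc - 1)
    ce <- pmin(pmax(ceiling(max(x0, x1)) + band, 0), nc - 1)
    rs <- pmin(pmax(floor(min(y0, y1)) - band, 0), nr - 1)
    re <- pmin(pmax(ceiling(max(y0, y1)) + band, 0), nr - 1)
    px <- rep(cs:ce, each = re - rs + 1)
    py <- rep(rs:re, times = ce - cs + 1)
    # point-to-segment distance
    vx <- x1 - x0
    vy <- y1 - y0
    len2 <- max(vx^2 + vy^2, 1e-300)
    t <- pmin(pmax(((px - x0) * vx + (py - y0) * vy) / len2, 0), 1)
    d <- sqrt((px - (x0 + t * vx))^2 + (py - (y0 + t * vy))^2)
    cbind(py, px, d)[d <= band + 1, , drop = FALSE]
  }))
  # keep the smallest distance per pixel
  key <- cand[, 1] * nc + cand[, 2]
  ord <- order(key, cand[, 3])
  cand <- cand[ord, , drop = FALSE]
  cand <- cand[!duplicated(key[ord]), , drop = FALSE]
  .cpp_fast_march(cand, nr, nc)
}

#' Parameters of the geodesic prior-shape snake
#'
#' The curve and a similarity transform (scale `mu`, rotation `theta`,
#' translation `T`) are descended jointly: the curve moves under the
#' geodesic speed plus the prior-distance attraction, while the transform
#' aligns the curve with the prior through the fast-marching distance map.
#'
#' @param dt curve-evolution time step.
#' @param b,sigma edge-stopping parameters (see [edge_stopping_map()]).
#' @param lambda prior-distance weight.
#' @param mu0,theta0,t0 initial scale, rotation (rad) and translation (px).
#' @param max_iter iteration cap.
#' @param tol mean-displacement convergence threshold, px.
#' @param resample_every resampling period, iterations.
#' @param step_cap maximal per-point displacement per iteration, px
#'   (stabilizes the quadratic distance term far from the prior).
#' @param rate_transform step size of the transform-parameter descent.
#' @return an object of class `geodesic_params`.
#' @export
geodesic_params <- function(dt = 0.2, b = 0.1, sigma = 0.3, lambda = 8,
                            mu0 = 1, theta0 = 0, t0 = c(0, 0),
                            max_iter = 1000, tol = 0.05,
                            resample_every = 10, step_cap = 2,
                            rate_transform = 1e-4) {
  stopifnot(dt >= 0, b >= 0, sigma > 0, lambda >= 0, mu0 > 0)
  structure(
    list(
      dt = dt, b = b, sigma = sigma, lambda = lambda, mu0 = mu0,
      theta0 = theta0, t0 = t0, max_iter = as.integer(max_iter), tol = tol,
      resample_every = as.integer(resample_every), step_cap = step_cap,
      rate_transform = rate_transform
    ),
    class = "geodesic_params"
  )
}

#' Segment with the geodesic prior-shape snake
#'
#' Explicit descent of the geodesic energy augmented with the squared
#' fast-marching distance to the prior curve, evaluated at the transformed
#' positions `mu R(theta) C + T`; the transform parameters are descended
#' simultaneously from `mu0 = 1, theta0 = 0, T0 = 0`. The prior is placed
#' at full scale at `center` (the foot gravity center), where its distance
#' map is computed once. Local coordinates for the transform are taken
#' about `center`.
#'
#' @param image a [thermal_image()].
#' @param init initial contour.
#' @param prior a `prior_shape`.
#' @param params a [geodesic_params()].
#' @param center placement of the prior, `c(x, y)`; defaults to the
#'   centroid of `init`.
#' @param dist optional precomputed distance map (matrix) for this
#'   placement.
#' @return a `foot_segmentation` with extra field `transform`
#'   (`mu`, `theta`, `t`).
#' @export
segment_geodesic <- function(image, init, prior, params = geodesic_params(),
                             center = NULL, dist = NULL) {
  image <- as_thermal_image(image)
  nr <- nrow(image$grid)
  nc <- ncol(image$grid)
  init <- align_start(resample_contour(init, prior$n))
  if (is.null(center)) center <- c(mean(init$x), mean(init$y))
  placed <- tibble::tibble(
    x = prior$points$x + center[1],
    y = prior$points$y + center[2]
  )
  if (is.null(dist)) dist <- prior_distance_map(placed, c(nr, nc))
  gd <- image_gradient(dist)
  g <- edge_stopping_map(image, params$b, params$sigma)
  gg <- image_gradient(g)
  C <- contour_matrix(init)
  mu <- params$mu0
  theta <- params$theta0
  tt <- params$t0
  still <- 0L
  iter <- 0L
  mu_clamped <- FALSE
  while (iter < params$max_iter) {
    iter <- iter + 1L
    cc <- colMeans(C)
    loc <- sweep(C, 2, cc) # scale/rotation act about the curve centroid
    rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
    drot <- matrix(
      c(-sin(theta), cos(theta), -cos(theta), -sin(theta)), 2
    )
    w <- mu * loc %*% t(rot)
    wx <- pmin(pmax(w[, 1] + cc[1] + tt[1], 0), nc - 1)
    wy <- pmin(pmax(w[, 2] + cc[2] + tt[2], 0), nr - 1)
    dv <- bilinear_sample(dist, wx, wy)
    dgx <- bilinear_sample(gd$gx, wx, wy)
    dgy <- bilinear_sample(gd$gy, wx, wy)
    gv <- bilinear_sample(g, C[, 1], C[, 2])
    ggx <- bilinear_sample(gg$gx, C[, 1], C[, 2])
    ggy <- bilinear_sample(gg$gy, C[, 1], C[, 2])
    nrm <- .outward_normals(C)
    d1 <- (cyc(C, 1) - cyc(C, -1)) / 2
    d2 <- .d2_unit(C)
    sp <- rownorm(d1)
    kappa <- (d1[, 1] * d2[, 2] - d1[, 2] * d2[, 1]) / pmax(sp^3, 1e-300)
    kappa <- pmin(pmax(kappa, -0.5), 0.5) # curvature guard (radius >= 2 px)
    rn <- nrm %*% t(rot)
    # curve-shortening flow of the energy density g + (lambda/2) d^2:
    # the quadratic prior term contributes (lambda/2) d^2 kappa
    speed <- ggx * nrm[, 1] + ggy * nrm[, 2] + gv * kappa +
      params$lambda * mu * dv * (dgx * rn[, 1] + dgy * rn[, 2]) +
      params$lambda / 2 * dv^2 * kappa
    # global adaptive rescale: the quadratic distance term is huge far from
    # the prior, so the step is normalized to at most step_cap px while
    # preserving the shape of the velocity field
    vmax <- max(abs(speed))
    dt_eff <- if (params$dt * vmax > params$step_cap) {
      params$step_cap / vmax
    } else {
      params$dt
    }
    move <- -dt_eff * speed
    C_new <- C + move * nrm
    C_new[, 1] <- pmin(pmax(C_new[, 1], 0), nc - 1)
    C_new[, 2] <- pmin(pmax(C_new[, 2], 0), nr - 1)
    if (any(!is.finite(C_new))) stop("geodesic snake diverged",
        call. = FALSE
      )
    # transform descent (trapezoidal weights are uniform after resampling)
    wgt <- sp / sum(sp)
    msq <- max(sum(wgt * rowSums(loc^2)), 1e-300)
    rl <- loc %*% t(rot)
    dl <- loc %*% t(drot)
    grad_mu <- params$lambda *
      sum(wgt * dv * (dgx * rl[, 1] + dgy * rl[, 2])) / msq
    grad_theta <- params$lambda * mu *
      sum(wgt * dv * (dgx * dl[, 1] + dgy * dl[, 2])) / msq
    grad_t <- params$lambda * c(
      sum(wgt * dv * dgx),
      sum(wgt * dv * dgy)
    )
    mu <- mu - params$rate_transform * grad_mu
    theta <- theta - params$rate_transform * grad_theta
    tt <- tt - params$rate_transform * grad_t
    if (mu <= 1e-3) {
      mu <- 1e-3
      mu_clamped <- TRUE
    }
    # total motion includes the transform channels, so a run driven only
    # by the pose descent (e.g. dt = 0) does not stop prematurely
    scale_px <- sqrt(max(msq, 1))
    disp <- mean(rownorm(C_new - C)) +
      params$rate_transform * (abs(grad_mu) + abs(grad_theta)) * scale_px +
      params$rate_transform * sqrt(sum(grad_t^2))
    C <- C_new
    still <- if (disp < params$tol) still + 1L else 0L
    if (still >= 5L) break
    if (iter %% params$resample_every == 0L) {
      C <- contour_matrix(align_start(resample_contour(
        tibble::tibble(x = C[, 1], y = C[, 2]), prior$n
      )))
    }
  }
  if (mu_clamped) {
    warning("scale parameter hit its lower clamp (1e-3)", call. = FALSE)
  }
  contour <- align_start(resample_contour(
    tibble::tibble(x = C[, 1], y = C[, 2]), prior$n
  ))
  structure(
    list(
      contour = contour,
      mask = rasterize_mask(contour, nr, nc),
      iterations = iter,
      converged = still >= 5L,
      transform = list(mu = mu, theta = theta, t = tt),
      energy = tibble::tibble(iteration = integer(0)),
      method = "chen"
    ),
    class = "foot_segmentation"
  )
}
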