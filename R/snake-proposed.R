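#' Parameters of the curvature-prior snake
#'
#' Energy weights follow the classical parametric snake with a balloon
#' pressure and an added prior-curvature term: internal tension `alpha`
#' and rigidity `beta`, image weight `w_edge` on the squared smoothed
#' gradient magnitude, positive balloon weight `delta` (the initialization
#' is inside the foot and must grow), and prior-curvature weight `gamma`
#' on the normalized curvature difference to the prior shape. The defaults
#' are the reference parameter set for plantar thermograms.
#'
#' Numerical controls: the evolution uses the classical index-step
#' discretization of the contour derivatives with a semi-implicit update
#' (internal terms implicit, external explicit); `tau` is the time step,
#' `tol` the convergence speed threshold (px/iteration): the snake is
#' declared converged when no point drifts faster than `tol` on average
#' over a full resampling window (net displacement between consecutive
#' checkpoints; the windowed maximum separates genuine balloon creep of a
#' still-growing arc from sub-pixel dither at a pinned edge, which a mean
#' over mostly pinned points would hide), and the contour is
#' re-resampled/start-aligned every `resample_every` iterations to keep
#' uniform spacing and prior correspondence.
#'
#' @param alpha tension weight (>= 0).
#' @param beta rigidity weight (>= 0).
#' @param w_edge image-energy weight (>= 0).
#' @param delta balloon weight (> 0, outward).
#' @param gamma prior-curvature weight (>= 0).
#' @param tau time step (> 0).
#' @param max_iter iteration cap.
#' @param tol convergence displacement threshold, px.
#' @param resample_every resampling period, iterations.
#' @param sigma_img Gaussian smoothing of the image before the gradient, px.
#' @param cap_quantile force magnitudes above this quantile are rescaled
#'   down (guards against isolated gradient spikes).
#' @return an object of class `snake_params`.
#' @export
snake_params <- function(alpha = 0.1, beta = 4, w_edge = 20, delta = 0.2,
                         gamma = 35, tau = 0.4, max_iter = 1600, tol = 0.05,
                         resample_every = 10, sigma_img = 2,
                         cap_quantile = 0.99) {
  stopifnot(
    alpha >= 0, beta >= 0, w_edge >= 0, gamma >= 0, delta > 0, tau > 0
  )
  structure(
    list(
      alpha = alpha, beta = beta, w_edge = w_edge, delta = delta,
      gamma = gamma, tau = tau, max_iter = as.integer(max_iter), tol = tol,
      resample_every = as.integer(resample_every), sigma_img = sigma_img,
      cap_quantile = cap_quantile
    ),
    class = "snake_params"
  )
}

#' External image force field
#'
#' The image energy is `-w_edge * |grad I|^2` evaluated on the
#' Gaussian-smoothed image, so the force (its negative gradient along the
#' curve) is `w_edge * grad(|grad(G_sigma * I)|^2)`, attracting the snake
#' to ridges of high gradient magnitude. Magnitudes above `cap_quantile`
#' are rescaled to that quantile to avoid blow-up at isolated spikes.
#'
#' @param image a [thermal_image()] or plain matrix.
#' @param w_edge image-energy weight.
#' @param sigma_img smoothing standard deviation, px.
#' @param cap_quantile magnitude cap quantile in (0, 1].
#' @param normalize rescale the image to `[0, 1]` and the squared gradient
#'   magnitude map to unit maximum before differentiating. The reference
#'   energy weights (`w_edge = 20` against `delta = 0.2`) presume a
#'   unit-normalized edge-energy map (the usual snake convention), so the
#'   segmentation pipeline sets this; the default `FALSE` keeps the
#'   operator literal in the image's own units.
#' @return an object of class `force_field`: list with matrices `fx`, `fy`
#'   and `emag2` (the squared smoothed gradient magnitude, used for energy
#'   bookkeeping and by the greedy snake).
#' @export
external_force_field <- function(image, w_edge = 20, sigma_img = 1.5,
                                 cap_quantile = 0.99, normalize = FALSE) {
  g <- .as_grid(image)
  if (normalize && diff(range(g)) > 0) {
    g <- (g - min(g)) / diff(range(g))
  }
  if (diff(range(g)) == 0) {
    warning("constant image: external force field is zero", call. = FALSE)
    z <- matrix(0, nrow(g), ncol(g))
    return(structure(list(fx = z, fy = z, emag2 = z, w_edge = w_edge),
      class = "force_field"
    ))
  }
  sm <- gaussian_smooth(g, sigma_img)
  gr <- image_gradient(sm)
  emag2 <- gr$gx^2 + gr$gy^2
  if (normalize && max(emag2) > 0) emag2 <- emag2 / max(emag2)
  fe <- image_gradient(emag2)
  fx <- w_edge * fe$gx
  fy <- w_edge * fe$gy
  mag <- sqrt(fx^2 + fy^2)
  if (cap_quantile < 1 && any(mag > 0)) {
    # quantile among the active force pixels only: most of the field is
    # flat background, and clipping to its statistics would flatten the
    # boundary attraction itself rather than the rare spikes
    active <- mag > 0.01 * max(mag)
    cap <- quantile(mag[active], cap_quantile, names = FALSE)
    over <- mag > cap
    sc <- ifelse(over, cap / mag, 1)
    fx <- fx * sc
    fy <- fy * sc
  }
  structure(list(fx = fx, fy = fy, emag2 = emag2, w_edge = w_edge),
    class = "force_field"
  )
}

# Periodic difference operators on the index parameterization (unit step).
.snake_operator <- function(n, alpha, beta_eff, tau) {
  d2 <- matrix(0, n, n)
  idx <- seq_len(n)
  d2[cbind(idx, idx)] <- -2
  d2[cbind(idx, idx %% n + 1)] <- 1
  d2[cbind(idx, (idx - 2) %% n + 1)] <- 1
  d4 <- d2 %*% d2
  a_op <- -alpha * d2 + beta_eff * d4
  solve(diag(n) + tau * a_op)
}

# Unit-step periodic derivatives used by the evolution (see the methods
# vignette for why these differ in scaling from curvature_profile()).
.d2_unit <- function(p) cyc(p, 1) - 2 * p + cyc(p, -1)
.d4_unit <- function(p) {
  cyc(p, -2) - 4 * cyc(p, -1) + 6 * p - 4 * cyc(p, 1) + cyc(p, 2)
}
.outward_normals <- function(p) {
  d1 <- (cyc(p, 1) - cyc(p, -1)) / 2
  nrm <- cbind(d1[, 2], -d1[, 1])
  nrm / pmax(rownorm(nrm), 1e-300)
}

#' Prior-shape curvature energy
#'
#' The prior energy per point is
#' `gamma * |Css(s) - zeta(s) * Css*(s)|^2` with the normalization
#' `zeta(s) = |Css(s)| / |Css*(s)|`, where each second derivative is read
#' in its own curve's local (tangent, normal) frame. This makes the energy
#' invariant to similarity transforms of the contour once both curves are
#' examined from the same start point: translation never enters a second
#' derivative, rotation cancels in the local frame, and scaling cancels
#' through `zeta`. Where the prior curvature magnitude vanishes
#' (`|Css*| < 1e-8` relative) the normalization is undefined and the point
#' contributes zero.
#'
#' @param contour a contour with the same number of points as the prior,
#'   start-aligned.
#' @param prior a [build_prior_shape()] result.
#' @param gamma prior weight.
#' @return list with `total` (mean per-point energy), `per_point` and
#'   `zeta`.
#' @export
prior_shape_energy <- function(contour, prior, gamma = 35) {
  pts <- as_contour(contour)
  if (nrow(pts) != prior$n) {
    stop("contour and prior must have the same number of points",
      call. = FALSE
    )
  }
  a <- .local_css(curvature_profile(pts))
  b <- .local_css(prior$profile)
  zeta <- ifelse(b$norm >= 1e-8, a$norm / pmax(b$norm, 1e-300), 0)
  diff2 <- ifelse(b$norm >= 1e-8,
    (a$tang - zeta * b$tang)^2 + (a$nrml - zeta * b$nrml)^2, 0
  )
  per_point <- gamma * diff2
  list(total = mean(per_point), per_point = per_point, zeta = zeta)
}

# Decompose the second derivative of a curvature profile into the curve's
# local tangent/normal frame.
.local_css <- function(profile) {
  d1 <- cbind(profile$d1x, profile$d1y)
  tang <- d1 / pmax(rownorm(d1), 1e-300)
  nrml <- cbind(profile$normal_x, profile$normal_y)
  d2 <- cbind(profile$d2x, profile$d2y)
  list(
    tang = rowSums(d2 * tang),
    nrml = rowSums(d2 * nrml),
    norm = rownorm(d2)
  )
}

# One semi-implicit evolution step; C and the prior arrays are n x 2
# matrices, M the precomputed inverse of (I + tau * A). zeta is frozen at
# the current iterate and clamped: near-straight prior segments make the
# curvature ratio ill-conditioned, and transient curvature spikes of the
# evolving contour must not be amplified through the prior pull.
.evolve_core <- function(C, M, field, prior_d2, prior_d4, params,
                         zeta_max = 10, step_cap = 2) {
  nrm <- .outward_normals(C)
  fx <- bilinear_sample(field$fx, C[, 1], C[, 2])
  fy <- bilinear_sample(field$fy, C[, 1], C[, 2])
  css <- .d2_unit(C)
  zeta <- rownorm(css) / pmax(rownorm(prior_d2), 1e-300)
  zeta <- pmin(zeta, zeta_max)
  ok <- rownorm(prior_d2) >= 1e-10
  pull <- params$gamma * zeta * prior_d4
  pull[!ok, ] <- 0
  # cap only the image + balloon part: the prior pull is balanced by the
  # implicit (beta + gamma) rigidity operator and must not be clipped
  ext <- cbind(fx, fy) + params$delta * nrm
  fmag <- rownorm(ext)
  cap <- step_cap / params$tau
  ext <- ext * pmin(1, cap / pmax(fmag, 1e-300))
  M %*% (C + params$tau * (ext + pull))
}

#' One evolution step of the curvature-prior snake
#'
#' Solves the semi-implicit update
#' `(I + tau A) C_new = C_old + tau (F_ext + delta eta + gamma zeta Cssss*)`
#' where `A` is the periodic pentadiagonal operator of
#' `-alpha d2/ds2 + (beta + gamma) d4/ds4` on the index parameterization,
#' `F_ext` the sampled [external_force_field()], `eta` the outward normal
#' and `zeta` the frozen curvature-normalization factor.
#'
#' @param contour n-point contour, start-aligned with the prior.
#' @param prior a `prior_shape` with `n` points.
#' @param field an [external_force_field()].
#' @param params a [snake_params()].
#' @return the updated contour tibble.
#' @export
evolve_step <- function(contour, prior, field, params = snake_params()) {
  C <- contour_matrix(as_contour(contour))
  if (nrow(C) != prior$n) {
    stop("contour and prior must have the same number of points",
      call. = FALSE
    )
  }
  M <- .snake_operator(
    nrow(C), params$alpha, params$beta + params$gamma,
    params$tau
  )
  pd2 <- .d2_unit(contour_matrix(prior$points))
  pd4 <- .d4_unit(contour_matrix(prior$points))
  out <- .evolve_core(C, M, field, pd2, pd4, params)
  tibble::tibble(x = out[, 1], y = out[, 2])
}

#' Segment a thermal image with the curvature-prior snake
#'
#' Iterates [evolve_step()] from the initialization until every point's
#' net drift speed over the last resampling window falls below
#' `params$tol` px/iteration, or `params$max_iter` is reached. The contour
#' is re-resampled to uniform arclength and re-aligned at its heel point
#' every `params$resample_every` iterations; points are clamped to the
#' image.
#'
#' @param image a [thermal_image()].
#' @param init initial contour (e.g. [make_initial_contour()]), `n` points.
#' @param prior a `prior_shape` with matching `n`.
#' @param params a [snake_params()].
#' @param field optional precomputed [external_force_field()] (reused
#'   across runs of the same image in benchmarks).
#' @return an object of class `foot_segmentation`: `contour`, `mask`,
#'   `iterations`, `converged`, and per-iteration `energy` tibble.
#' @export
segment_snake <- function(image, init, prior, params = snake_params(),
                          field = NULL) {
  image <- as_thermal_image(image)
  if (is.null(field)) {
    field <- external_force_field(
      image, params$w_edge, params$sigma_img,
      params$cap_quantile,
      normalize = TRUE
    )
  }
  nr <- nrow(image$grid)
  nc <- ncol(image$grid)
  C <- contour_matrix(align_start(resample_contour(init, prior$n)))
  M <- .snake_operator(
    prior$n, params$alpha, params$beta + params$gamma,
    params$tau
  )
  pd2 <- .d2_unit(contour_matrix(prior$points))
  pd4 <- .d4_unit(contour_matrix(prior$points))
  pp <- contour_matrix(prior$points)
  pd1 <- (cyc(pp, 1) - cyc(pp, -1)) / 2
  pt <- pd1 / pmax(rownorm(pd1), 1e-300)
  p_loc <- list(
    tang = rowSums(pd2 * pt),
    nrml = rowSums(pd2 * cbind(pt[, 2], -pt[, 1]))
  )
  e_tot <- e_ps <- numeric(0)
  iter <- 0L
  clamped <- FALSE
  converged <- FALSE
  c_check <- NULL
  while (iter < params$max_iter) {
    iter <- iter + 1L
    C_new <- .evolve_core(C, M, field, pd2, pd4, params)
    if (any(!is.finite(C_new))) stop("snake diverged (non-finite energy)",
        call. = FALSE
      )
    out_of_bounds <- C_new[, 1] < 0 | C_new[, 1] > nc - 1 |
      C_new[, 2] < 0 | C_new[, 2] > nr - 1
    if (any(out_of_bounds)) {
      clamped <- TRUE
      C_new[, 1] <- pmin(pmax(C_new[, 1], 0), nc - 1)
      C_new[, 2] <- pmin(pmax(C_new[, 2], 0), nr - 1)
    }
    C <- C_new
    # energy bookkeeping (means over the curve; prior term in the local
    # tangent/normal frame, as in prior_shape_energy)
    d1 <- (cyc(C, 1) - cyc(C, -1)) / 2
    css <- .d2_unit(C)
    tc <- d1 / pmax(rownorm(d1), 1e-300)
    ncv <- cbind(tc[, 2], -tc[, 1])
    zeta <- rownorm(css) / pmax(rownorm(pd2), 1e-300)
    dps <- cbind(
      rowSums(css * tc) - zeta * p_loc$tang,
      rowSums(css * ncv) - zeta * p_loc$nrml
    )
    e_ps <- c(e_ps, params$gamma * mean(rowSums(dps^2)))
    e_img <- -field$w_edge *
      mean(bilinear_sample(field$emag2, C[, 1], C[, 2]))
    e_int <- mean(params$alpha * rowSums(d1^2) + params$beta *
      rowSums(css^2))
    e_tot <- c(e_tot, e_int + e_img + params$delta +
      e_ps[length(e_ps)])
    if (iter %% params$resample_every == 0L) {
      C <- contour_matrix(align_start(resample_contour(
        tibble::tibble(x = C[, 1], y = C[, 2]), prior$n
      )))
      if (!is.null(c_check)) {
        net <- max(rownorm(C - c_check))
        if (net < params$tol * params$resample_every) {
          converged <- TRUE
          break
        }
      }
      c_check <- C
    }
  }
  if (clamped) {
    warning("contour reached the image bounds and was clamped",
      call. = FALSE
    )
  }
  contour <- align_start(resample_contour(
    tibble::tibble(x = C[, 1], y = C[, 2]), prior$n
  ))
  structure(
    list(
      contour = contour,
      mask = rasterize_mask(contour, nr, nc),
      iterations = iter,
      converged = converged,
      energy = tibble::tibble(
        iteration = seq_along(e_tot),
        e_total = e_tot, e_prior = e_ps
      ),
      method = "proposed"
    ),
    class = "foot_segmentation"
  )
}

#' @export
print.foot_segmentation <- function(x, ...) {
  cat(sprintf(
    "<foot_segmentation> method=%s, %d points, %d iterations (%s)\n",
    x$method, nrow(x$contour), x$iterations,
    if (x$converged) "converged" else "iteration cap"
  ))
  invisible(x)
}
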