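#' Fourier descriptors of a closed contour
#'
#' The contour is read as the complex signal `x + iy` and transformed with
#' the unnormalized DFT (sum convention, as in [stats::fft()]); the
#' coefficient set covers frequencies `k = -n/2 ... n/2 - 1` stored in FFT
#' order. `n` must be even.
#'
#' @param contour an n-point contour, n even.
#' @return an object of class `fourier_descriptors`: list with complex
#'   vector `z` (FFT order) and `n`.
#' @export
fourier_descriptors <- function(contour) {
  pts <- as_contour(contour)
  n <- nrow(pts)
  if (n %% 2 != 0) {
    stop("Fourier descriptors need an even number of points; resample first",
      call. = FALSE
    )
  }
  structure(
    list(z = fft(complex(real = pts$x, imaginary = pts$y)), n = n),
    class = "fourier_descriptors"
  )
}

#' Normalize Fourier descriptors for similarity invariance
#'
#' Sets the DC coefficient to zero (translation invariance), divides all
#' amplitudes by the first-harmonic amplitude `R1` (scale invariance) and
#' subtracts the first-harmonic phase from all phases (rotation
#' invariance): `Zhat_0 = 0`, `Rhat_k = R_k / R_1`,
#' `thetahat_k = theta_k - theta_1`.
#'
#' @param fd a [fourier_descriptors()] result.
#' @return normalized `fourier_descriptors` (field `z` holds `Zhat`).
#' @export
normalize_descriptors <- function(fd) {
  stopifnot(inherits(fd, "fourier_descriptors"))
  r1 <- Mod(fd$z[2])
  if (r1 < 1e-12) {
    stop("degenerate curve: first Fourier harmonic has zero amplitude",
      call. = FALSE
    )
  }
  phase1 <- fd$z[2] / r1
  zhat <- (fd$z / r1) * Conj(phase1)
  zhat[1] <- 0 + 0i
  structure(list(z = zhat, n = fd$n, normalized = TRUE),
    class = "fourier_descriptors"
  )
}

#' Fourier-domain prior-shape energy
#'
#' `gamma0 * sum_k |Zhat_k - Zhat*_k|^2` over all frequencies, computed on
#' normalized descriptors, hence invariant to similarity transforms of
#' either curve.
#'
#' @param fd,fd_star [fourier_descriptors()] of the snake and the prior
#'   (normalized automatically if not already).
#' @param gamma0 prior weight.
#' @return scalar energy.
#' @export
fourier_prior_energy <- function(fd, fd_star, gamma0 = 0.5) {
  if (fd$n != fd_star$n) {
    stop("descriptor lengths differ", call. = FALSE)
  }
  if (is.null(fd$normalized)) fd <- normalize_descriptors(fd)
  if (is.null(fd_star$normalized)) fd_star <- normalize_descriptors(fd_star)
  gamma0 * sum(Mod(fd$z - fd_star$z)^2)
}

#' Parameters of the greedy Fourier-prior snake
#'
#' @param alpha continuity weight.
#' @param beta curvature weight.
#' @param w_edge image (gradient-magnitude) weight.
#' @param delta balloon weight (reward for outward candidate moves).
#' @param gamma0 Fourier prior weight.
#' @param radius greedy neighborhood radius, px.
#' @param max_passes pass cap.
#' @param stop_frac stop when fewer than this fraction of points moved.
#' @param sigma_img image smoothing before the gradient, px.
#' @param resample_every resampling period, passes.
#' @return an object of class `greedy_params`.
#' @export
greedy_params <- function(alpha = 1.2, beta = 0.1, w_edge = 5, delta = 0.1,
                          gamma0 = 0.5, radius = 1L, max_passes = 200,
                          stop_frac = 0.02, sigma_img = 1.5,
                          resample_every = 10) {
  stopifnot(alpha >= 0, beta >= 0, w_edge >= 0, delta >= 0, gamma0 >= 0,
    radius >= 1)
  structure(
    list(
      alpha = alpha, beta = beta, w_edge = w_edge, delta = delta,
      gamma0 = gamma0, radius = as.integer(radius),
      max_passes = as.integer(max_passes), stop_frac = stop_frac,
      sigma_img = sigma_img, resample_every = as.integer(resample_every)
    ),
    class = "greedy_params"
  )
}

#' Segment with the greedy Fourier-prior snake
#'
#' Classic greedy evolution: in each pass every point examines its
#' `(2 radius + 1)^2` neighborhood and moves to the position minimizing
#' the weighted sum of continuity, curvature, image, balloon and
#' Fourier-prior terms, each min-max normalized within the neighborhood.
#' The Fourier descriptors are maintained across candidate moves by exact
#' rank-one DFT updates. Passes stop when the fraction of moved points
#' falls below `stop_frac`; if the moved fraction fails to decrease for 50
#' passes the best-energy iterate is returned with a warning.
#'
#' @param image a [thermal_image()].
#' @param init initial contour.
#' @param prior a `prior_shape`.
#' @param params a [greedy_params()].
#' @param field optional precomputed [external_force_field()] (its `emag2`
#'   is used).
#' @return a `foot_segmentation` (see [segment_snake()]).
#' @export
segment_greedy <- function(image, init, prior, params = greedy_params(),
                           field = NULL) {
  image <- as_thermal_image(image)
  if (is.null(field)) {
    field <- external_force_field(image, 1, params$sigma_img, 1,
      normalize = TRUE
    )
  }
  n <- prior$n
  if (n %% 2 != 0) stop("greedy snake needs an even point count",
      call. = FALSE
    )
  zhat_star <- normalize_descriptors(fourier_descriptors(prior$points))$z
  C <- contour_matrix(align_start(resample_contour(init, n)))
  nr <- nrow(image$grid)
  nc <- ncol(image$grid)
  best <- list(energy = Inf, C = C)
  moved_hist <- integer(0)
  pass <- 0L
  oscillating <- FALSE
  while (pass < params$max_passes) {
    pass <- pass + 1L
    nrm <- .outward_normals(C)
    Z <- fft(complex(real = C[, 1], imaginary = C[, 2]))
    res <- .cpp_greedy_pass(
      C, nrm, field$emag2, Z, zhat_star, params$alpha,
      params$beta, params$w_edge, params$delta, params$gamma0, params$radius,
      0
    )
    C <- res$points
    moved_hist <- c(moved_hist, res$moved)
    e <- .greedy_energy(C, field, zhat_star, params)
    if (e < best$energy) best <- list(energy = e, C = C)
    if (res$moved < params$stop_frac * n) break
    if (length(moved_hist) >= 50 &&
      all(diff(utils::tail(moved_hist, 50)) >= 0)) {
      oscillating <- TRUE
      break
    }
    if (pass %% params$resample_every == 0L) {
      C <- contour_matrix(align_start(resample_contour(
        tibble::tibble(x = C[, 1], y = C[, 2]), n
      )))
    }
  }
  if (oscillating) {
    warning("greedy snake oscillated; returning the best-energy iterate",
      call. = FALSE
    )
    C <- best$C
  }
  contour <- align_start(resample_contour(
    tibble::tibble(x = C[, 1], y = C[, 2]), n
  ))
  structure(
    list(
      contour = contour,
      mask = rasterize_mask(contour, nr, nc),
      iterations = pass,
      converged = !oscillating && pass < params$max_passes,
      energy = tibble::tibble(
        iteration = seq_along(moved_hist),
        moved = moved_hist
      ),
      method = "ahmed"
    ),
    class = "foot_segmentation"
  )
}

# Raw (un-normalized) global greedy energy used only to track the best
# iterate across passes.
.greedy_energy <- function(C, field, zhat_star, params) {
  seg <- rownorm(cyc(C, 1) - C)
  curv <- .d2_unit(C)
  e_img <- -mean(bilinear_sample(field$emag2, C[, 1], C[, 2]))
  fd <- structure(list(
    z = fft(complex(real = C[, 1], imaginary = C[, 2])),
    n = nrow(C)
  ), class = "fourier_descriptors")
  e_pri <- fourier_prior_energy(
    normalize_descriptors(fd),
    structure(list(z = zhat_star, n = nrow(C), normalized = TRUE),
      class = "fourier_descriptors"
    ), 1
  )
  params$alpha * mean((seg - mean(seg))^2) +
    params$beta * mean(rowSums(curv^2)) +
    params$w_edge * e_img + params$gamma0 * e_pri
}
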