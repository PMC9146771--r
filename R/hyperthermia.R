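#' Rigid registration of two contours by iterative closest point
#'
#' Alternates nearest-neighbor correspondence (moving to fixed) with the
#' closed-form rigid fit (centroids + SVD of the cross-covariance, scale
#' fixed at 1). Stops when the mean residual changes by less than `tol`
#' or after `max_iter` iterations; if the residual increases for 10
#' consecutive iterations the best iterate is returned with a warning.
#' Rigid transforms cannot mirror: the left foot must be pre-flipped.
#'
#' @param moving,fixed contours resampled to comparable density.
#' @param max_iter iteration cap.
#' @param tol residual-change tolerance, px.
#' @return an object of class `rigid_transform`: `theta` (rad),
#'   `t` (px, length 2), rotation matrix `R`, and `residual`.
#' @export
icp_register <- function(moving, fixed, max_iter = 100, tol = 1e-4) {
  mv <- contour_matrix(as_contour(moving))
  fx <- contour_matrix(as_contour(fixed))
  theta <- 0
  tt <- c(0, 0)
  best <- NULL
  prev_res <- Inf
  worse <- 0L
  for (iter in seq_len(max_iter)) {
    rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
    cur <- mv %*% t(rot) + rep(1, nrow(mv)) %o% tt
    d2 <- outer(cur[, 1], fx[, 1], `-`)^2 + outer(cur[, 2], fx[, 2], `-`)^2
    nn <- max.col(-d2, ties.method = "first")
    # refine vertex correspondence to the projection onto the better of
    # the two polyline segments adjacent to the nearest vertex (removes
    # the tangential quantization bias of vertex-to-vertex matching)
    nfx <- nrow(fx)
    proj <- function(a, b) {
      v <- b - a
      len2 <- pmax(rowSums(v^2), 1e-300)
      t <- pmin(pmax(rowSums((cur - a) * v) / len2, 0), 1)
      a + v * t
    }
    p_prev <- proj(fx[(nn - 2) %% nfx + 1, , drop = FALSE],
      fx[nn, , drop = FALSE])
    p_next <- proj(fx[nn, , drop = FALSE],
      fx[nn %% nfx + 1, , drop = FALSE])
    d_prev <- rowSums((cur - p_prev)^2)
    d_next <- rowSums((cur - p_next)^2)
    tgt <- ifelse(cbind(d_prev <= d_next, d_prev <= d_next), p_prev, p_next)
    res <- sqrt(mean(rowSums((cur - tgt)^2)))
    if (is.null(best) || res < best$residual) {
      best <- list(theta = theta, t = tt, residual = res)
    }
    if (abs(prev_res - res) < tol) break
    worse <- if (res > prev_res) worse + 1L else 0L
    if (worse >= 10L) {
      warning("ICP residual diverging; returning the best iterate",
        call. = FALSE
      )
      theta <- best$theta
      tt <- best$t
      break
    }
    prev_res <- res
    # closed-form rigid fit of mv onto tgt
    mc <- colMeans(mv)
    tc <- colMeans(tgt)
    h <- t(sweep(mv, 2, mc)) %*% sweep(tgt, 2, tc)
    sv <- svd(h)
    r_fit <- sv$v %*% diag(c(1, det(sv$v %*% t(sv$u)))) %*% t(sv$u)
    theta <- atan2(r_fit[2, 1], r_fit[1, 1])
    tt <- tc - as.vector(r_fit %*% mc)
  }
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  structure(
    list(theta = theta, t = tt, R = rot, residual = best$residual),
    class = "rigid_transform"
  )
}

#' Apply a rigid transform to points
#'
#' @param points a contour.
#' @param transform a [icp_register()] result.
#' @return the transformed contour tibble.
#' @export
apply_transform <- function(points, transform) {
  p <- contour_matrix(as_contour(points)) %*% t(transform$R)
  tibble::tibble(x = p[, 1] + transform$t[1], y = p[, 2] + transform$t[2])
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf(
    "<rigid_transform> theta=%.3f rad, t=(%.2f, %.2f) px, residual %.3f px\n",
    x$theta, x$t[1], x$t[2], x$residual
  ))
  invisible(x)
}

#' Point-to-point absolute temperature difference map
#'
#' The flipped left foot is warped onto the right foot through the rigid
#' transform (bilinear resampling) and `|deltaT| = |T_right - T_left o W|`
#' is evaluated on the intersection of the right mask with the warped left
#' mask — the region where the difference is defined point-to-point.
#'
#' @param right,left_flipped [thermal_image()]s of the two feet (left
#'   already mirrored).
#' @param right_mask,left_mask segmentation masks of the two feet.
#' @param transform [icp_register()] result mapping left-foot coordinates
#'   onto right-foot coordinates.
#' @return an object of class `delta_t_map`: `delta` (matrix, NA outside
#'   the common region), `mask`, `mean_dt`, `max_dt`, `pixel_size`,
#'   `transform`.
#' @export
delta_t_map <- function(right, left_flipped, right_mask, left_mask,
                        transform) {
  right <- as_thermal_image(right)
  left_flipped <- as_thermal_image(left_flipped)
  nr <- nrow(right$grid)
  nc <- ncol(right$grid)
  xg <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
  yg <- matrix(0:(nr - 1), nr, nc)
  # inverse transform: left position of each right-frame pixel
  rx <- xg - transform$t[1]
  ry <- yg - transform$t[2]
  inv <- t(transform$R) # rigid: inverse = transpose
  lx <- inv[1, 1] * rx + inv[1, 2] * ry
  ly <- inv[2, 1] * rx + inv[2, 2] * ry
  inside <- lx >= 0 & lx <= ncol(left_flipped$grid) - 1 &
    ly >= 0 & ly <= nrow(left_flipped$grid) - 1
  warped <- matrix(NA_real_, nr, nc)
  warped[inside] <- bilinear_sample(
    left_flipped$grid, lx[inside], ly[inside]
  )
  wmask <- matrix(0L, nr, nc)
  wmask[inside] <- as.integer(
    bilinear_sample(left_mask * 1, lx[inside], ly[inside]) >= 0.5
  )
  common <- (right_mask > 0) & (wmask > 0)
  if (!any(common)) stop("registered foot masks do not intersect",
      call. = FALSE
    )
  delta <- matrix(NA_real_, nr, nc)
  delta[common] <- abs(right$grid[common] - warped[common])
  structure(
    list(
      delta = delta, mask = common * 1L,
      mean_dt = mean(delta[common]), max_dt = max(delta[common]),
      pixel_size = right$pixel_size, transform = transform
    ),
    class = "delta_t_map"
  )
}

#' @export
print.delta_t_map <- function(x, ...) {
  cat(sprintf(
    "<delta_t_map> %d px common region, mean |dT| %.2f degC, max %.2f degC\n",
    sum(x$mask), x$mean_dt, x$max_dt
  ))
  invisible(x)
}

#' Detect hyperthermia regions in a temperature-difference map
#'
#' Thresholds `|deltaT|` at `threshold` (the clinical 2.2 degC criterion),
#' extracts 8-connected components and discards components smaller than
#' `min_area_px` — by default the pixel area of a 1 cm diameter disk at
#' the recorded pixel size, the smallest clinically considered region.
#'
#' @param map a [delta_t_map()].
#' @param threshold temperature-difference threshold, degC.
#' @param min_area_px minimal region area, px.
#' @return a tibble of regions (`region`, `area_px`, `centroid_x`,
#'   `centroid_y`, `peak_dt`, `mean_dt`) with attribute `hyperthermia`
#'   (logical: any region present); retrieve it with
#'   `attr(x, "hyperthermia")` or [glance()].
#' @export
detect_hyperthermia <- function(map, threshold = 2.2, min_area_px = NULL) {
  stopifnot(inherits(map, "delta_t_map"))
  if (is.null(min_area_px)) {
    radius_px <- 5 / map$pixel_size # 1 cm diameter
    min_area_px <- pi * radius_px^2
  }
  hot <- !is.na(map$delta) & map$delta > threshold
  lab <- .cpp_label(hot * 1L, 8L)
  regions <- tibble::tibble(
    region = integer(0), area_px = numeric(0),
    centroid_x = numeric(0), centroid_y = numeric(0),
    peak_dt = numeric(0), mean_dt = numeric(0)
  )
  if (max(lab) > 0) {
    regions <- purrr::map_dfr(seq_len(max(lab)), function(k) {
      idx <- which(lab == k, arr.ind = TRUE)
      tibble::tibble(
        region = k, area_px = nrow(idx),
        centroid_x = mean(idx[, 2] - 1), centroid_y = mean(idx[, 1] - 1),
        peak_dt = max(map$delta[idx]), mean_dt = mean(map$delta[idx])
      )
    })
    regions <- dplyr::filter(regions, .data$area_px >= min_area_px)
    regions$region <- seq_len(nrow(regions))
  }
  attr(regions, "hyperthermia") <- nrow(regions) > 0
  attr(regions, "threshold") <- threshold
  attr(regions, "min_area_px") <- min_area_px
  regions
}

#' Full two-feet hyperthermia pipeline
#'
#' Segments both feet with the curvature-prior snake, registers the left
#' (flipped) foot contour onto the right by ICP, builds the |deltaT| map
#' and detects hyperthermia regions.
#'
#' @param right,left_flipped single-foot [thermal_image()]s.
#' @param prior a `prior_shape`.
#' @param params a [snake_params()].
#' @param threshold clinical threshold, degC.
#' @return a list with `right_fit`, `left_fit`, `transform`, `map`,
#'   `regions`.
#' @export
hyperthermia_pipeline <- function(right, left_flipped, prior = NULL,
                                  params = snake_params(),
                                  threshold = 2.2) {
  if (is.null(prior)) prior <- default_prior(n = 200)
  seg1 <- locate_foot(right)
  seg2 <- locate_foot(left_flipped)
  fit_r <- segment_snake(
    right, make_initial_contour(prior, seg1$center, 2), prior, params
  )
  fit_l <- segment_snake(
    left_flipped, make_initial_contour(prior, seg2$center, 2), prior, params
  )
  tf <- icp_register(fit_l$contour, fit_r$contour)
  map <- delta_t_map(right, left_flipped, fit_r$mask, fit_l$mask, tf)
  list(
    right_fit = fit_r, left_fit = fit_l, transform = tf, map = map,
    regions = detect_hyperthermia(map, threshold)
  )
}
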