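#' Directed contour RMSE
#'
#' For every point of the ground-truth contour the distance to the nearest
#' vertex of the predicted contour is taken; the RMSE of those distances
#' is returned. The measure is directed (ground truth to prediction). Both
#' contours are resampled to at least `resample_to` points first to remove
#' discretization bias.
#'
#' @param ground_truth,predicted contours.
#' @param resample_to minimal point count used for the metric.
#' @return RMSE in pixels.
#' @export
contour_rmse <- function(ground_truth, predicted, resample_to = 512) {
  gt <- contour_matrix(resample_contour(
    ground_truth, max(resample_to, nrow(as_contour(ground_truth)))
  ))
  pr <- contour_matrix(resample_contour(
    predicted, max(resample_to, nrow(as_contour(predicted)))
  ))
  d2 <- outer(gt[, 1], pr[, 1], `-`)^2 + outer(gt[, 2], pr[, 2], `-`)^2
  sqrt(mean(apply(d2, 1, min)))
}

#' Dice similarity coefficient of two masks
#'
#' `2 |A intersect B| / (|A| + |B|)`; two empty masks score 1 by
#' convention.
#'
#' @param a,b binary masks of equal shape.
#' @return a value in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("mask shapes differ", call. = FALSE)
  na <- sum(a > 0)
  nb <- sum(b > 0)
  if (na + nb == 0) {
    return(1)
  }
  2 * sum(a > 0 & b > 0) / (na + nb)
}

#' One-sided two-sample t statistics from summary data
#'
#' Tests H1: `mean1 > mean2` at the 5% level (critical value 1.65 for
#' large samples). Both the pooled-variance and the Welch statistic are
#' reported.
#'
#' @param mean1,sd1,n1 summary statistics of the first sample.
#' @param mean2,sd2,n2 summary statistics of the second sample.
#' @return a one-row tibble with `t_pooled`, `df_pooled`, `t_welch`,
#'   `df_welch`, `significant` (pooled statistic > 1.65).
#' @export
two_sample_ttest <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2)
  if (sd1 <= 0 && sd2 <= 0) {
    stop("both groups have zero variance", call. = FALSE)
  }
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  t_pooled <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  se1 <- sd1^2 / n1
  se2 <- sd2^2 / n2
  t_welch <- (mean1 - mean2) / sqrt(se1 + se2)
  df_welch <- (se1 + se2)^2 /
    (se1^2 / (n1 - 1) + se2^2 / (n2 - 1))
  tibble::tibble(
    t_pooled = t_pooled, df_pooled = n1 + n2 - 2,
    t_welch = t_welch, df_welch = df_welch,
    significant = t_pooled > 1.65
  )
}

#' Run a segmentation method on one prepared image
#'
#' Internal dispatcher shared by the benchmark harness and the acceptance
#' pipeline.
#'
#' @keywords internal
.run_method <- function(method, image, init, prior, center,
                        method_params = list(), field = NULL, dist = NULL) {
  switch(method,
    proposed = segment_snake(
      image, init, prior,
      do.call(snake_params, method_params$proposed %||% list()),
      field = field
    ),
    ahmed = segment_greedy(
      image, init, prior,
      do.call(greedy_params, method_params$ahmed %||% list()),
      field = field
    ),
    chen = segment_geodesic(
      image, init, prior,
      do.call(geodesic_params, method_params$chen %||% list()),
      center = center, dist = dist
    ),
    stop("unknown method: ", method, call. = FALSE)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Benchmark segmentation methods on a phantom suite
#'
#' Runs each method on each suite image under the requested conditions:
#' the baseline run, up to three initialization placements (the gravity
#' center plus diagonal offsets), and a grid of additive-noise SNR levels.
#' Per-image preprocessing (Otsu + morphology + gravity center) and the
#' force fields are shared across methods. Failures are recorded, not
#' fatal.
#'
#' @param suite a list of `phantom_sample` objects ([phantom_suite()]).
#' @param methods character subset of `c("proposed", "ahmed", "chen")`.
#' @param prior a `prior_shape`; default built from held-out phantoms.
#' @param init_offsets named list of initialization offsets (px) added to
#'   the gravity center; `NULL` runs only the centered placement.
#' @param snr_db numeric vector of SNR conditions (dB); `Inf` is the
#'   noise-free condition.
#' @param init_scale prior downsizing factor for the initialization.
#' @param method_params optional named list of parameter overrides per
#'   method, e.g. `list(proposed = list(gamma = 0))`.
#' @param noise_seed base seed of the noise conditions.
#' @return a tibble with one row per image x method x condition: `image`,
#'   `seed`, `method`, `condition`, `offset_x`, `offset_y`, `snr_db`,
#'   `dsc`, `rmse`, `iterations`, `converged`, `seconds`, `error`.
#' @export
run_benchmark <- function(suite, methods = c("proposed", "ahmed", "chen"),
                          prior = NULL,
                          init_offsets = list(centered = c(0, 0)),
                          snr_db = Inf, init_scale = 2,
                          method_params = list(), noise_seed = 7L) {
  if (is.null(prior)) prior <- default_prior(n = 200)
  rows <- list()
  for (i in seq_along(suite)) {
    sample <- suite[[i]]
    for (snr in snr_db) {
      image <- if (is.infinite(snr)) {
        sample$image
      } else {
        add_gaussian_noise(sample$image, snr, noise_seed + i)
      }
      loc <- locate_foot(image)
      sp <- do.call(snake_params, method_params$proposed %||% list())
      gp <- do.call(greedy_params, method_params$ahmed %||% list())
      fields <- list()
      if ("proposed" %in% methods) {
        fields$proposed <- external_force_field(
          image, sp$w_edge, sp$sigma_img, sp$cap_quantile,
          normalize = TRUE
        )
      }
      if ("ahmed" %in% methods) {
        fields$ahmed <- if (!is.null(fields$proposed) &&
          gp$sigma_img == sp$sigma_img) {
          fields$proposed
        } else {
          external_force_field(image, 1, gp$sigma_img, 1, normalize = TRUE)
        }
      }
      dist <- NULL
      if ("chen" %in% methods) {
        placed <- tibble::tibble(
          x = prior$points$x + loc$center[1],
          y = prior$points$y + loc$center[2]
        )
        dist <- tryCatch(
          prior_distance_map(placed, dim(image$grid)),
          error = function(e) NULL
        )
      }
      for (off_name in names(init_offsets)) {
        off <- init_offsets[[off_name]]
        init <- make_initial_contour(
          prior, loc$center + off, init_scale
        )
        for (method in methods) {
          t0 <- proc.time()[["elapsed"]]
          fit <- tryCatch(
            withCallingHandlers(
              .run_method(
                method, image, init, prior, loc$center,
                method_params,
                field = fields[[method]], dist = dist
              ),
              warning = function(w) invokeRestart("muffleWarning")
            ),
            error = function(e) e
          )
          el <- proc.time()[["elapsed"]] - t0
          if (inherits(fit, "error")) {
            rows[[length(rows) + 1]] <- tibble::tibble(
              image = i, seed = sample$meta$seed %||% NA_integer_,
              method = method, condition = off_name,
              offset_x = off[1], offset_y = off[2], snr_db = snr,
              dsc = NA_real_, rmse = NA_real_, iterations = NA_integer_,
              converged = NA, seconds = el,
              error = conditionMessage(fit)
            )
          } else {
            rows[[length(rows) + 1]] <- tibble::tibble(
              image = i, seed = sample$meta$seed %||% NA_integer_,
              method = method, condition = off_name,
              offset_x = off[1], offset_y = off[2], snr_db = snr,
              dsc = dice_coefficient(fit$mask, sample$mask),
              rmse = contour_rmse(sample$contour, fit$contour),
              iterations = fit$iterations, converged = fit$converged,
              seconds = el, error = NA_character_
            )
          }
        }
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Summarize a benchmark report
#'
#' Mean and standard deviation of DSC and RMSE per method and condition,
#' in the layout of the usual segmentation comparison tables.
#'
#' @param report a [run_benchmark()] tibble.
#' @return a tibble grouped by method, condition and SNR.
#' @export
benchmark_summary <- function(report) {
  report |>
    dplyr::filter(is.na(.data$error)) |>
    dplyr::group_by(.data$method, .data$condition, .data$snr_db) |>
    dplyr::summarise(
      n = dplyr::n(),
      dsc_mean = mean(.data$dsc), dsc_sd = sd(.data$dsc),
      rmse_mean = mean(.data$rmse), rmse_sd = sd(.data$rmse),
      seconds_mean = mean(.data$seconds),
      .groups = "drop"
    )
}
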