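# The straight-line comparison ("trig") model: perfectly straight rays from
# the two base corners, with independent Gaussian noise on each base angle.
# Having no internal length scale, this model's positional spread can only
# scale linearly with triangle side length — the property the worm-like-chain
# model's sub-linear scaling is tested against. It also serves as the
# alternative hypothesis in the Bayes-factor comparison.

#' Parameters of the straight-line noisy-angle null model
#'
#' @param angle_sd_deg Standard deviation of the Gaussian base-angle noise,
#'   in degrees (default 5, >= 0).
#' @return An object of class `tc_null_params`.
#' @export
null_params <- function(angle_sd_deg = 5) {
  check_number(angle_sd_deg, "angle_sd_deg", lower = 0, closed_lower = TRUE)
  structure(list(angle_sd_deg = angle_sd_deg), class = "tc_null_params")
}

stop_if_not_null <- function(params) {
  if (!inherits(params, "tc_null_params")) {
    abort("`params` must be created by `null_params()`.")
  }
  invisible(params)
}

#' Intersect two straight rays from the base corners
#'
#' The ray from `(-b/2, 0)` at angle `theta_left` and the ray from
#' `(b/2, 0)` at angle `pi - theta_right` intersect at
#' `y = b tan(thL) tan(thR) / (tan(thL) + tan(thR))`. Vectorized.
#'
#' @param theta_left_deg,theta_right_deg Base angles in degrees, in (0, 90).
#' @param base_length Base length (> 0).
#' @return A tibble with columns `x`, `y`.
#' @export
#' @examples
#' intersect_rays(45, 45, 2) # (0, 1)
#' intersect_rays(30, 60, 2) # (0.5, 0.866...)
intersect_rays <- function(theta_left_deg, theta_right_deg, base_length) {
  check_number(base_length, "base_length", lower = 0)
  tl <- tan(deg2rad(theta_left_deg))
  tr <- tan(deg2rad(theta_right_deg))
  denom <- tl + tr
  if (any(abs(denom) <= 1e-6)) {
    abort("Near-parallel rays: tan(theta_left) + tan(theta_right) below tolerance.")
  }
  y <- base_length * tl * tr / denom
  x <- -base_length / 2 + y / tl
  tibble::tibble(x = x, y = y)
}

#' Sample apex and missing-angle estimates under the null model
#'
#' Draws independent noisy base angles per side per sample, intersects the
#' straight rays for the apex estimate, and computes the missing angle
#' directly from the sampled base angles (`pi - thL - thR`), matching the
#' model's role as a pure trigonometric rule. Near-parallel draws
#' (`tan(thL) + tan(thR) <= 1e-6`) are resampled with a logged count.
#'
#' @param spec A [triangle_spec()].
#' @param params A [null_params()].
#' @param n_samples Number of samples.
#' @param seed Optional integer seed.
#' @return A tibble with columns `theta_left_deg`, `theta_right_deg`, `x`,
#'   `y` (apex estimates, spec orientation applied), `angle_rad`,
#'   `angle_deg`; attribute `"n_resampled"`.
#' @export
#' @examples
#' sample_vertex_null(triangle_spec(2, 45), null_params(5), 10, seed = 1)
sample_vertex_null <- function(spec, params, n_samples, seed = NULL) {
  stop_if_not_spec(spec)
  stop_if_not_null(params)
  n_samples <- check_count(n_samples, "n_samples", min = 1L)
  sd_rad <- deg2rad(params$angle_sd_deg)
  run <- function() {
    thl <- rnorm(n_samples, spec$theta0, sd_rad)
    thr <- rnorm(n_samples, spec$theta0, sd_rad)
    bad <- (tan(thl) + tan(thr)) <= 1e-6
    n_res <- 0L
    while (any(bad)) {
      n_res <- n_res + sum(bad)
      thl[bad] <- rnorm(sum(bad), spec$theta0, sd_rad)
      thr[bad] <- rnorm(sum(bad), spec$theta0, sd_rad)
      bad <- (tan(thl) + tan(thr)) <= 1e-6
    }
    list(thl = thl, thr = thr, n_res = n_res)
  }
  d <- if (is.null(seed)) run() else with_seed(seed, run())
  y <- spec$base_length * tan(d$thl) * tan(d$thr) / (tan(d$thl) + tan(d$thr))
  x <- -spec$base_length / 2 + y / tan(d$thl)
  p <- orient_xy(spec, x, y)
  if (d$n_res > 0L) {
    inform(sprintf("sample_vertex_null: %d near-parallel draws resampled.", d$n_res))
  }
  out <- tibble::tibble(
    theta_left_deg = rad2deg(d$thl), theta_right_deg = rad2deg(d$thr),
    x = p$x, y = p$y,
    angle_rad = pi - d$thl - d$thr,
    angle_deg = rad2deg(pi - d$thl - d$thr)
  )
  attr(out, "n_resampled") <- d$n_res
  out
}

#' Monte-Carlo scaling curve of the null model
#'
#' Apex-estimate bias and spread per side length under the straight-line
#' noisy-angle model. Because the model has no internal length scale, the
#' spread is exactly proportional to the side length (log-log slope 1).
#'
#' @param params A [null_params()].
#' @param theta0_deg Base angle in degrees.
#' @param L_grid Vector of at least 5 positive side lengths.
#' @param n_samples Samples per length.
#' @param seed Optional integer master seed.
#' @return A tibble of class `tc_scaling_curve`: `L`, `mean_y`, `bias`,
#'   `sigma_y`, `sigma_x`.
#' @export
null_scaling_curve <- function(params, theta0_deg = 36, L_grid,
                               n_samples = 4000, seed = NULL) {
  stop_if_not_null(params)
  if (length(L_grid) < 5L) abort("`L_grid` must contain at least 5 side lengths.")
  theta0 <- deg2rad(theta0_deg)
  rows <- purrr::imap(as.double(sort(L_grid)), function(l, i) {
    spec <- triangle_spec(2 * l * cos(theta0), theta0_deg)
    s <- sample_vertex_null(spec, params, n_samples,
      seed = if (is.null(seed)) NULL else substream_seed(seed, i)
    )
    tibble::tibble(
      L = l, mean_y = mean(s$y), bias = mean(s$y) - l * sin(theta0),
      sigma_y = sd(s$y), sigma_x = sd(s$x)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("tc_scaling_curve", class(out))
  attr(out, "theta0_deg") <- theta0_deg
  attr(out, "params") <- params
  attr(out, "model") <- "null"
  out
}
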