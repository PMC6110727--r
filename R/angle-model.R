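# Missing-angle predictions.
#
# The apex-estimate distribution implied by the statistical model is
# summarized by a Gamma law for the vertical coordinate (moment-matched to
# the analytic mean and variance) and a centered Gaussian for the horizontal
# coordinate. Each sampled apex (X, Y) defines "effective base angles" at
# the two fixed base corners; the missing angle is
#   pi - (effective base angle left + effective base angle right),
# so a downward apex bias translates into overestimation of the missing
# angle, increasingly so for longer sides.

#' Moment-match a Gamma distribution
#'
#' Shape `k = mean^2 / var` and scale `s = var / mean`, so the reconstructed
#' mean `k s` and variance `k s^2` equal the inputs exactly.
#'
#' @param mean Target mean (> 0).
#' @param var Target variance (> 0). Non-positive inputs signal an invalid
#'   model regime (e.g. bias exceeding the apex height) and are rejected.
#' @return A list with elements `shape` and `scale`.
#' @export
#' @examples
#' gamma_from_moments(2, 2) # shape 2, scale 1
gamma_from_moments <- function(mean, var) {
  check_number(mean, "mean", lower = 0)
  check_number(var, "var", lower = 0)
  list(shape = mean^2 / var, scale = var / mean)
}

#' Sample missing-angle estimates implied by the statistical model
#'
#' Draws apex estimates (`Y` from the moment-matched Gamma, `X` from a
#' centered Gaussian with the model's post-averaging horizontal spread),
#' rejects-and-resamples draws with `Y <= 0` (counted), and converts each
#' apex into a missing-angle estimate via the effective base angles.
#'
#' @param spec A [triangle_spec()].
#' @param params A [wlc_params()].
#' @param n Number of angle samples (default 400).
#' @param seed Optional integer seed.
#' @return A tibble of class `tc_angle_samples` with columns `x`, `y`,
#'   `angle_rad`, `angle_deg`; attributes `"n_resampled"` (rejected draws)
#'   and `"provenance"` (spec, params, n, seed).
#' @export
#' @examples
#' s <- missing_angle_samples(triangle_spec(2, 45), wlc_params(xi = 2, v0 = 0.4),
#'   n = 100, seed = 1
#' )
#' mean(s$angle_deg)
missing_angle_samples <- function(spec, params, n = 400, seed = NULL) {
  stop_if_not_spec(spec)
  stop_if_not_wlc(params)
  n <- check_count(n, "n", min = 1L)
  L <- side_length(spec)
  m <- vertex_moments_core(spec$theta0, params$xi, params$v0, L)
  if (m$mean_y <= 0) {
    abort("Model mean apex height is non-positive; invalid regime.")
  }
  zero_var <- m$var_y <= 0
  run <- function() {
    draw <- function(k) {
      y <- if (zero_var) rep(m$mean_y, k) else {
        g <- gamma_from_moments(m$mean_y, m$var_y)
        rgamma(k, shape = g$shape, scale = g$scale)
      }
      x <- if (m$var_x > 0) rnorm(k, 0, sqrt(m$var_x)) else rep(0, k)
      list(x = x, y = y)
    }
    d <- draw(n)
    bad <- d$y <= 0
    n_res <- 0L
    while (any(bad)) {
      n_res <- n_res + sum(bad)
      rep_d <- draw(sum(bad))
      d$x[bad] <- rep_d$x
      d$y[bad] <- rep_d$y
      bad <- d$y <= 0
    }
    list(d = d, n_res = n_res)
  }
  out <- if (is.null(seed)) run() else with_seed(seed, run())
  ang <- effective_base_angles(out$d$x, out$d$y, spec$base_length)
  res <- tibble::tibble(
    x = out$d$x, y = out$d$y,
    angle_rad = pi - ang$left - ang$right,
    angle_deg = rad2deg(pi - ang$left - ang$right)
  )
  class(res) <- c("tc_angle_samples", class(res))
  if (out$n_res > 0L) {
    inform(sprintf("missing_angle_samples: %d invalid draws resampled.", out$n_res))
  }
  attr(res, "n_resampled") <- out$n_res
  attr(res, "provenance") <- list(spec = spec, params = params, n = n, seed = seed)
  res
}

#' Missing-angle statistics across side lengths
#'
#' Repeats [missing_angle_samples()] over a grid of side lengths (holding
#' the base angle fixed) and reports the mean and standard deviation of the
#' predicted missing angle per length. Deterministic given `seed`
#' (independent substreams per length).
#'
#' @param params A [wlc_params()].
#' @param theta0_deg Base angle in degrees.
#' @param L_grid Vector of positive side lengths.
#' @param n Samples per length (default 400).
#' @param seed Optional integer master seed.
#' @return A tibble of class `tc_angle_curve`: `L`, `mean_angle_deg`,
#'   `sd_angle_deg`, `n`, `n_resampled`.
#' @export
#' @examples
#' angle_stats_curve(wlc_params(xi = 2, v0 = 0.4), 45,
#'   L_grid = c(6, 20, 60), n = 200, seed = 1
#' )
angle_stats_curve <- function(params, theta0_deg, L_grid, n = 400, seed = NULL) {
  stop_if_not_wlc(params)
  check_number(theta0_deg, "theta0_deg", lower = 0, upper = 90)
  if (any(L_grid <= 0)) abort("`L_grid` must be positive.")
  theta0 <- deg2rad(theta0_deg)
  rows <- purrr::imap(as.double(sort(L_grid)), function(l, i) {
    spec <- triangle_spec(2 * l * cos(theta0), theta0_deg)
    s <- missing_angle_samples(spec, params,
      n = n,
      seed = if (is.null(seed)) NULL else substream_seed(seed, i)
    )
    tibble::tibble(
      L = l, mean_angle_deg = mean(s$angle_deg),
      sd_angle_deg = sd(s$angle_deg), n = n,
      n_resampled = attr(s, "n_resampled")
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("tc_angle_curve", class(out))
  attr(out, "theta0_deg") <- theta0_deg
  attr(out, "params") <- params
  out
}
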