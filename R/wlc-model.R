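# The worm-like-chain statistical model.
#
# The local angle phi(s) along an extrapolated side, s in [0, L], is a
# Gaussian process: an Ornstein-Uhlenbeck process around the base angle
# theta0, with correlation length xi and stationary variance v0/2, pinned at
# phi(0) = theta0 ("the walker starts aligned with the perceived base
# angle"). A stationary-start mode is provided for sensitivity checks. The
# side endpoint is x = integral cos(phi) ds, y = integral sin(phi) ds;
# endpoint moments follow from bivariate-Gaussian trigonometric expectations
# evaluated by Gauss-Legendre quadrature.

# Var(phi(s) - theta0)
wlc_var_s <- function(s, xi, v0, pinned = TRUE) {
  if (pinned) (v0 / 2) * (1 - exp(-2 * s / xi)) else rep(v0 / 2, length(s))
}

# Cov(phi(s) - theta0, phi(s') - theta0); vectorized, s and sp same shape
wlc_cov_s <- function(s, sp, xi, v0, pinned = TRUE) {
  base <- (v0 / 2) * exp(-abs(s - sp) / xi)
  if (pinned) base - (v0 / 2) * exp(-(s + sp) / xi) else base
}

# Endpoint moments of one extrapolated side, base-on-x frame, start at the
# origin. Gauss-Legendre in 1-D for the means and nested Gauss-Legendre over
# the triangle s < s' (doubled) for the second moments; the integrands are
# smooth there, so modest node counts give ~1e-8 relative accuracy.
ep_moments_core <- function(theta0, xi, v0, L, n = NULL, pinned = TRUE) {
  if (v0 == 0) {
    return(list(
      mean_x = L * cos(theta0), mean_y = L * sin(theta0),
      var_x = 0, var_y = 0, cov_xy = 0
    ))
  }
  if (is.null(n)) n <- min(480L, max(96L, ceiling(8 * L / xi)))
  gl <- pracma::gaussLegendre(n, 0, L)
  s <- gl$x
  w <- gl$w
  e1 <- exp(-wlc_var_s(s, xi, v0, pinned) / 2)
  I1 <- sum(w * e1)
  mean_x <- cos(theta0) * I1
  mean_y <- sin(theta0) * I1

  glu <- pracma::gaussLegendre(n, 0, 1)
  sp <- outer(s, glu$x, function(a, b) a + (L - a) * b)
  wsp <- outer(L - s, glu$w)
  S <- matrix(s, n, n)
  vs <- wlc_var_s(S, xi, v0, pinned)
  vsp <- wlc_var_s(sp, xi, v0, pinned)
  cc <- wlc_cov_s(S, sp, xi, v0, pinned)
  IA <- 2 * sum(w * rowSums(wsp * exp(-(vs + vsp - 2 * cc) / 2)))
  IB <- 2 * sum(w * rowSums(wsp * exp(-(vs + vsp + 2 * cc) / 2)))
  Ex2 <- 0.5 * (IA + cos(2 * theta0) * IB)
  Ey2 <- 0.5 * (IA - cos(2 * theta0) * IB)
  Exy <- 0.5 * sin(2 * theta0) * IB
  list(
    mean_x = mean_x, mean_y = mean_y,
    var_x = max(Ex2 - mean_x^2, 0), var_y = max(Ey2 - mean_y^2, 0),
    cov_xy = Exy - mean_x * mean_y
  )
}

#' Analytic endpoint moments of one extrapolated side
#'
#' Mean, variance and covariance of the endpoint `(x, y)` of a single side
#' trajectory of arc length `L`, together with the bias
#' `delta = E[y] - L sin(theta0)` (negative: toward the base). Moments are
#' computed by deterministic quadrature of the exact Gaussian trigonometric
#' expectations; `check = TRUE` re-evaluates at a finer grid and warns if the
#' result has not converged to `1e-6` relative.
#'
#' @param params A [wlc_params()].
#' @param theta0_deg Base angle in degrees.
#' @param L Side (arc) length; may be a vector.
#' @param pinned If `TRUE` (default) the angle process is pinned at
#'   `phi(0) = theta0`; if `FALSE` it starts in its stationary law.
#' @param n_quad Quadrature nodes per dimension (default: adaptive in `L/xi`).
#' @param check Verify quadrature convergence (default `TRUE`).
#' @return A tibble with one row per `L`: `theta0_deg`, `L`, `mean_x`,
#'   `mean_y`, `var_x`, `var_y`, `cov_xy`, `bias`, `sigma_x`, `sigma_y`.
#' @export
#' @examples
#' endpoint_moments(wlc_params(xi = 2, v0 = 0.26), theta0_deg = 36, L = c(1, 10))
endpoint_moments <- function(params, theta0_deg, L, pinned = TRUE,
                             n_quad = NULL, check = TRUE) {
  stop_if_not_wlc(params)
  check_number(theta0_deg, "theta0_deg", lower = 0, upper = 90)
  if (!is.numeric(L) || any(!is.finite(L)) || any(L <= 0)) {
    abort("`L` must be positive and finite.")
  }
  theta0 <- deg2rad(theta0_deg)
  rows <- purrr::map(L, function(l) {
    m <- ep_moments_core(theta0, params$xi, params$v0, l, n = n_quad, pinned = pinned)
    if (check && params$v0 > 0) {
      n0 <- n_quad %||% min(480L, max(96L, ceiling(8 * l / params$xi)))
      m2 <- ep_moments_core(theta0, params$xi, params$v0, l,
        n = n0 + 64L, pinned = pinned
      )
      rel <- abs(m2$var_y - m$var_y) / max(m2$var_y, .Machine$double.eps)
      if (is.finite(rel) && rel > 1e-6) {
        warn(sprintf("endpoint_moments: quadrature not converged at L = %g (rel. change %.2g); increase `n_quad`.", l, rel))
      }
      m <- m2
    }
    tibble::tibble(
      theta0_deg = theta0_deg, L = l,
      mean_x = m$mean_x, mean_y = m$mean_y,
      var_x = m$var_x, var_y = m$var_y, cov_xy = m$cov_xy,
      bias = m$mean_y - l * sin(theta0),
      sigma_x = sqrt(m$var_x), sigma_y = sqrt(m$var_y)
    )
  })
  dplyr::bind_rows(rows)
}

# Moments of the apex estimate obtained by averaging two mirrored,
# independent side endpoints: E[Y] = E[y], Var halves, E[X] = 0.
vertex_moments_core <- function(theta0, xi, v0, L, pinned = TRUE) {
  m <- ep_moments_core(theta0, xi, v0, L, pinned = pinned)
  list(
    mean_y = m$mean_y, var_y = m$var_y / 2,
    mean_x = 0, var_x = m$var_x / 2,
    bias = m$mean_y - L * sin(theta0)
  )
}

# Exact one-step OU transition sampler for u = phi - theta0. Accumulates the
# endpoint integrals x, y by the trapezoid rule while streaming over
# segments, so memory is O(n_paths). Uses the current RNG state.
ou_endpoint_samples <- function(theta0, xi, v0, L, n_paths, n_segments,
                                pinned = TRUE) {
  h <- L / n_segments
  a <- exp(-h / xi)
  sd_step <- sqrt((v0 / 2) * (1 - a^2))
  u <- if (pinned) rep(0, n_paths) else rnorm(n_paths, 0, sqrt(v0 / 2))
  x <- 0.5 * h * cos(theta0 + u)
  y <- 0.5 * h * sin(theta0 + u)
  for (j in seq_len(n_segments)) {
    u <- u * a + rnorm(n_paths, 0, sd_step)
    wj <- if (j == n_segments) 0.5 * h else h
    phi <- theta0 + u
    x <- x + wj * cos(phi)
    y <- y + wj * sin(phi)
  }
  list(x = x, y = y, phi_end = theta0 + u)
}

#' Sample a discretized angular path and its curve
#'
#' Draws one realization of the angle process `phi(s)` on an even grid by its
#' exact one-step transition, and the associated curve
#' `(x(s), y(s))` by trapezoid quadrature of `(cos phi, sin phi)`.
#'
#' @inheritParams endpoint_moments
#' @param n_segments Number of arc segments (default `max(200, 10 L / xi)`).
#' @param seed Optional integer seed.
#' @return A tibble with columns `s`, `phi`, `x`, `y`.
#' @export
#' @examples
#' sample_path(wlc_params(xi = 2, v0 = 0.26), theta0_deg = 36, L = 10, seed = 1)
sample_path <- function(params, theta0_deg, L, n_segments = NULL, seed = NULL,
                        pinned = TRUE) {
  stop_if_not_wlc(params)
  check_number(theta0_deg, "theta0_deg", lower = 0, upper = 90)
  check_number(L, "L", lower = 0)
  n_segments <- n_segments %||% max(200L, ceiling(10 * L / params$xi))
  n_segments <- check_count(n_segments, "n_segments", min = 2L)
  theta0 <- deg2rad(theta0_deg)
  run <- function() {
    h <- L / n_segments
    a <- exp(-h / params$xi)
    sd_step <- sqrt((params$v0 / 2) * (1 - a^2))
    u <- numeric(n_segments + 1L)
    u[1L] <- if (pinned) 0 else rnorm(1, 0, sqrt(params$v0 / 2))
    innov <- rnorm(n_segments, 0, sd_step)
    for (j in seq_len(n_segments)) u[j + 1L] <- u[j] * a + innov[j]
    phi <- theta0 + u
    s <- seq(0, L, length.out = n_segments + 1L)
    wts <- c(0.5, rep(1, n_segments - 1L), 0.5) * h
    tibble::tibble(
      s = s, phi = phi,
      x = cumsum(wts * cos(phi)) - 0.5 * h * cos(phi),
      y = cumsum(wts * sin(phi)) - 0.5 * h * sin(phi)
    )
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Monte-Carlo endpoint samples of one side
#'
#' Streams many independent angular paths (exact OU transitions) and returns
#' their endpoints; the Monte-Carlo counterpart of [endpoint_moments()].
#'
#' @inheritParams sample_path
#' @param n_paths Number of independent paths.
#' @return A tibble with columns `x`, `y`, `phi_end`.
#' @export
sample_endpoints <- function(params, theta0_deg, L, n_paths, n_segments = NULL,
                             seed = NULL, pinned = TRUE) {
  stop_if_not_wlc(params)
  check_number(theta0_deg, "theta0_deg", lower = 0, upper = 90)
  check_number(L, "L", lower = 0)
  n_paths <- check_count(n_paths, "n_paths", min = 1L)
  n_segments <- n_segments %||% max(200L, ceiling(10 * L / params$xi))
  n_segments <- check_count(n_segments, "n_segments", min = 2L)
  theta0 <- deg2rad(theta0_deg)
  run <- function() {
    e <- ou_endpoint_samples(theta0, params$xi, params$v0, L, n_paths,
      n_segments,
      pinned = pinned
    )
    tibble::tibble(x = e$x, y = e$y, phi_end = e$phi_end)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Sampled apex estimates from the statistical model
#'
#' Draws independent left and right side trajectories, mirrors the right one,
#' and averages the two endpoints into an apex estimate `(X, Y)` — the
#' "average intersection" reading of triangle completion. `method = "paths"`
#' samples exact angular paths; `method = "gaussian"` draws endpoints from a
#' bivariate normal with the analytic moments (the moment-matched
#' construction).
#'
#' @param spec A [triangle_spec()].
#' @param params A [wlc_params()].
#' @param n_samples Number of apex samples (>= 2).
#' @param seed Optional integer seed.
#' @param method `"paths"` (default) or `"gaussian"`.
#' @param n_segments Segments per path for `method = "paths"`.
#' @return A tibble with columns `x`, `y` (apex estimates, in the spec's
#'   orientation), with attributes `"summary"` (a one-row tibble of sample
#'   moments) and `"spec"`.
#' @export
vertex_distribution <- function(spec, params, n_samples, seed = NULL,
                                method = c("paths", "gaussian"),
                                n_segments = NULL) {
  stop_if_not_spec(spec)
  stop_if_not_wlc(params)
  n_samples <- check_count(n_samples, "n_samples", min = 2L)
  method <- match.arg(method)
  L <- side_length(spec)
  theta0 <- spec$theta0
  b2 <- spec$base_length / 2

  draw_side <- function() {
    if (method == "paths") {
      n_segments <- n_segments %||% max(200L, ceiling(10 * L / params$xi))
      ou_endpoint_samples(theta0, params$xi, params$v0, L, n_samples, n_segments)
    } else {
      m <- ep_moments_core(theta0, params$xi, params$v0, L)
      # 2x2 Cholesky
      a11 <- sqrt(m$var_x)
      a21 <- if (a11 > 0) m$cov_xy / a11 else 0
      a22 <- sqrt(max(m$var_y - a21^2, 0))
      z1 <- rnorm(n_samples)
      z2 <- rnorm(n_samples)
      list(x = m$mean_x + a11 * z1, y = m$mean_y + a21 * z1 + a22 * z2)
    }
  }
  run <- function() {
    left <- draw_side()
    right <- draw_side()
    # left tip: (-b/2 + x_l, y_l); right tip mirrored: (b/2 - x_r, y_r)
    X <- (left$x - right$x) / 2
    Y <- (left$y + right$y) / 2
    p <- orient_xy(spec, X, Y)
    tibble::tibble(x = p$x, y = p$y)
  }
  out <- if (is.null(seed)) run() else with_seed(seed, run())
  apex <- true_apex(spec)
  vert <- if (spec$orientation == "y") {
    # undo rotation for the summary's bias convention (height above base)
    list(x = out$y, y = -out$x)
  } else {
    list(x = out$x, y = out$y)
  }
  attr(out, "summary") <- tibble::tibble(
    n = n_samples,
    mean_x = mean(vert$x), mean_y = mean(vert$y),
    sigma_x = sd(vert$x), sigma_y = sd(vert$y),
    bias = mean(vert$y) - L * sin(theta0)
  )
  attr(out, "spec") <- spec
  out
}

#' Bias and spread of the apex estimate across side lengths
#'
#' Deterministic scaling analysis: per side length, analytic endpoint moments
#' combined into apex-estimate (vertex) statistics — the bias
#' `delta(L) = E[Y] - L sin(theta0)` and the standard deviations of the
#' vertical and horizontal apex coordinates.
#'
#' @inheritParams endpoint_moments
#' @param L_grid Vector of at least 5 positive side lengths.
#' @param level `"vertex"` (default; moments of the averaged apex estimate)
#'   or `"side"` (single-side endpoint moments). Averaging two independent
#'   sides halves the variances and leaves the bias unchanged, so the fitted
#'   scaling exponent is identical for both levels.
#' @return A tibble of class `tc_scaling_curve` with columns `L`, `mean_y`,
#'   `bias`, `sigma_y`, `sigma_x`.
#' @export
#' @examples
#' sc <- scaling_curve(wlc_params(xi = 2, v0 = 0.26), 36, c(1, 3, 10, 30, 100))
#' fit_power_law(sc$L, sc$sigma_y)
scaling_curve <- function(params, theta0_deg = 36, L_grid, pinned = TRUE,
                          level = c("vertex", "side")) {
  stop_if_not_wlc(params)
  level <- match.arg(level)
  if (length(L_grid) < 5L) abort("`L_grid` must contain at least 5 side lengths.")
  m <- endpoint_moments(params, theta0_deg, sort(as.double(L_grid)),
    pinned = pinned
  )
  scale <- if (level == "vertex") 0.5 else 1
  out <- tibble::tibble(
    L = m$L,
    mean_y = m$mean_y,
    bias = m$bias,
    sigma_y = sqrt(m$var_y * scale),
    sigma_x = sqrt(m$var_x * scale)
  )
  class(out) <- c("tc_scaling_curve", class(out))
  attr(out, "params") <- params
  attr(out, "theta0_deg") <- theta0_deg
  attr(out, "level") <- level
  attr(out, "model") <- "wlc"
  out
}

#' Fit a power law sigma ~ L^n by log-log least squares
#'
#' @param L Positive sizes.
#' @param sigma Positive spreads.
#' @return A one-row tibble: `exponent`, `intercept` (log10 scale),
#'   `r_squared`.
#' @export
fit_power_law <- function(L, sigma) {
  if (length(L) != length(sigma) || length(L) < 3L) {
    abort("`L` and `sigma` must have equal length >= 3.")
  }
  if (any(L <= 0) || any(sigma <= 0)) abort("`L` and `sigma` must be positive.")
  fit <- lm(log(sigma) ~ log(L))
  rss <- sum(residuals(fit)^2)
  tss <- sum((log(sigma) - mean(log(sigma)))^2)
  tibble::tibble(
    exponent = unname(coef(fit)[2L]),
    intercept = unname(coef(fit)[1L]) / log(10),
    r_squared = if (tss > 0) 1 - rss / tss else NA_real_
  )
}
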