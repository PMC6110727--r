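# The dynamic model: a correlated random walk in time.
#
# The heading theta(t) of each extrapolated line tip obeys the second-order
# stochastic dynamics
#   d2theta/dt2 = (1/tau) * ((theta0 - theta)/xi_t - dtheta/dt) + eta(t),
# with <eta(t) eta(t')> = D delta(t - t'), while the tip advances at speed
# v_p: dx/dt = v_p cos(theta), dy/dt = v_p sin(theta). tau is an inertial
# relaxation time, xi_t the error-correction time scale. The stationary
# heading variance is D tau^2 xi_t / 2, and in the overdamped regime
# (tau << xi_t) the heading process matches the statistical model with
# correlation length v_p * xi_t and angle noise level v0 = D tau^2 xi_t.
#
# Completion runs two independent tips from the base corners with a shared
# clock and, by default, ends when the horizontal tip distance first drops
# below the threshold eps ("gap" rule). A "fixed_arc" rule that extrapolates
# each side for exactly one side length is also provided: it is the
# construction under which the dynamic ensemble converges to the statistical
# model's analytic moments (the gap rule reshapes the endpoint law; see the
# package vignette).

#' Parameters of the dynamic (correlated-random-walk) model
#'
#' @param tau Inertial relaxation time (> 0).
#' @param v_p Extrapolation speed (> 0), length per time.
#' @param xi_t Error-correction time scale (> 0); the equivalent statistical
#'   correlation length is `v_p * xi_t`.
#' @param noise_d White-noise amplitude `D` (>= 0).
#' @param eps Stopping threshold on the tips' horizontal distance (> 0).
#' @param dt Integration step; must satisfy `dt < tau`. Default
#'   `0.01 * min(tau, xi_t)`.
#' @param max_time Cap on simulated time per completion; default `50 L / v_p`
#'   at the point of use.
#' @return An object of class `tc_dynamic_params`.
#' @export
#' @examples
#' dynamic_params(tau = 0.02, v_p = 1, xi_t = 2, noise_d = 65, eps = 0.1)
dynamic_params <- function(tau, v_p, xi_t, noise_d, eps,
                           dt = NULL, max_time = NULL) {
  check_number(tau, "tau", lower = 0)
  check_number(v_p, "v_p", lower = 0)
  check_number(xi_t, "xi_t", lower = 0)
  check_number(noise_d, "noise_d", lower = 0, closed_lower = TRUE)
  check_number(eps, "eps", lower = 0)
  dt <- dt %||% (0.01 * min(tau, xi_t))
  check_number(dt, "dt", lower = 0)
  if (dt >= tau) abort("`dt` must be smaller than `tau`.")
  if (!is.null(max_time)) check_number(max_time, "max_time", lower = 0)
  structure(
    list(
      tau = tau, v_p = v_p, xi_t = xi_t, noise_d = noise_d,
      eps = eps, dt = dt, max_time = max_time
    ),
    class = "tc_dynamic_params"
  )
}

#' @export
print.tc_dynamic_params <- function(x, ...) {
  cat(sprintf(
    "<tc_dynamic_params> tau = %g, v_p = %g, xi_t = %g, D = %g, eps = %g, dt = %g\n",
    x$tau, x$v_p, x$xi_t, x$noise_d, x$eps, x$dt
  ))
  invisible(x)
}

stop_if_not_dynamic <- function(params) {
  if (!inherits(params, "tc_dynamic_params")) {
    abort("`params` must be created by `dynamic_params()`.")
  }
  invisible(params)
}

#' Dynamic parameters matched to a statistical model
#'
#' Chooses dynamic parameters whose overdamped heading process reproduces a
#' [wlc_params()] law: `xi_t = xi / v_p` (correlation length
#' `= v_p * xi_t`), stationary heading variance `v0 / 2` (so
#' `D = v0 / (tau^2 xi_t)`), and a small inertia `tau = tau_frac * xi_t`.
#'
#' @param params A [wlc_params()].
#' @param v_p Extrapolation speed.
#' @param tau_frac Inertial time as a fraction of `xi_t` (default 0.01;
#'   moment distortions from inertia are of this relative order).
#' @param eps Stopping threshold; default `0.05 * xi`.
#' @param dt_frac Step as a fraction of `tau` (default 0.02).
#' @return A `tc_dynamic_params` object.
#' @export
#' @examples
#' as_dynamic_params(wlc_params(xi = 2, v0 = 0.26))
as_dynamic_params <- function(params, v_p = 1, tau_frac = 0.01, eps = NULL,
                              dt_frac = 0.02) {
  stop_if_not_wlc(params)
  xi_t <- params$xi / v_p
  tau <- tau_frac * xi_t
  dynamic_params(
    tau = tau, v_p = v_p, xi_t = xi_t,
    noise_d = params$v0 / (tau^2 * xi_t),
    eps = eps %||% (0.05 * params$xi),
    dt = dt_frac * tau
  )
}

# Shared Euler-Maruyama step used by the pure-R single-trajectory simulator.
# Returns matrix with columns t, theta, dtheta, x, y.
sim_side_core <- function(theta0, params, n_steps, theta_start = theta0) {
  dt <- params$dt
  sd_eta <- sqrt(params$noise_d / dt)
  th <- numeric(n_steps + 1L)
  w <- numeric(n_steps + 1L)
  x <- numeric(n_steps + 1L)
  y <- numeric(n_steps + 1L)
  th[1L] <- theta_start
  eta <- rnorm(n_steps, 0, sd_eta)
  for (k in seq_len(n_steps)) {
    a <- ((theta0 - th[k]) / params$xi_t - w[k]) / params$tau + eta[k]
    x[k + 1L] <- x[k] + params$v_p * cos(th[k]) * dt
    y[k + 1L] <- y[k] + params$v_p * sin(th[k]) * dt
    th[k + 1L] <- th[k] + w[k] * dt
    w[k + 1L] <- w[k] + a * dt
    if (!is.finite(th[k + 1L])) {
      abort(sprintf("simulate_side: non-finite state at t = %g.", k * dt))
    }
  }
  cbind(t = (0:n_steps) * dt, theta = th, dtheta = w, x = x, y = y)
}

#' Simulate one extrapolated side
#'
#' Euler-Maruyama integration of the heading dynamics for a single side over
#' a fixed time horizon. Initial conditions: `theta(0) = theta0`,
#' `dtheta/dt(0) = 0`. The right side is simulated in a mirrored frame and
#' reported in absolute coordinates (start at `(start_x, start_y)`, heading
#' `pi - theta`), which guarantees exact left/right symmetry of the law.
#'
#' @param theta0_deg Base angle in degrees.
#' @param params A [dynamic_params()].
#' @param total_time Simulated duration.
#' @param direction `"left"` or `"right"`.
#' @param start Numeric length-2 start point (default origin).
#' @param theta_start_deg Initial heading (degrees); defaults to
#'   `theta0_deg`. A nonzero offset exposes the deterministic relaxation of
#'   the heading toward the base angle.
#' @param seed Optional integer seed.
#' @return A tibble with columns `t`, `theta`, `dtheta`, `x`, `y`.
#' @export
#' @examples
#' simulate_side(45, dynamic_params(0.02, 1, 2, 0, 0.1), total_time = 1)
simulate_side <- function(theta0_deg, params, total_time,
                          direction = c("left", "right"), start = c(0, 0),
                          theta_start_deg = theta0_deg, seed = NULL) {
  stop_if_not_dynamic(params)
  check_number(theta0_deg, "theta0_deg", lower = 0, upper = 90)
  check_number(total_time, "total_time", lower = 0)
  direction <- match.arg(direction)
  n_steps <- max(1L, ceiling(total_time / params$dt))
  theta0 <- deg2rad(theta0_deg)
  run <- function() {
    sim_side_core(theta0, params, n_steps,
      theta_start = deg2rad(theta_start_deg)
    )
  }
  m <- if (is.null(seed)) run() else with_seed(seed, run())
  out <- tibble::as_tibble(as.data.frame(m))
  if (direction == "right") {
    out$theta <- pi - out$theta
    out$dtheta <- -out$dtheta
    out$x <- start[1L] - out$x
  } else {
    out$x <- start[1L] + out$x
  }
  out$y <- start[2L] + out$y
  out
}

# intersection of the lines through two tips with given headings
crossing_point <- function(x1, y1, th1, x2, y2, th2) {
  d <- sin(th2 - th1)
  t1 <- ((x2 - x1) * sin(th2) - (y2 - y1) * cos(th2)) / d
  list(x = x1 + t1 * cos(th1), y = y1 + t1 * sin(th1))
}

dyn_ensemble_raw <- function(spec, params, n_reps, seed,
                             stop_rule = c("gap", "fixed_arc")) {
  stop_if_not_spec(spec)
  stop_if_not_dynamic(params)
  stop_rule <- match.arg(stop_rule)
  L <- side_length(spec)
  max_time <- params$max_time %||% (50 * L / params$v_p)
  arc_time <- L / params$v_p
  run <- function() {
    tc_dyn_ensemble_cpp(
      theta0 = spec$theta0, base = spec$base_length, eps = params$eps,
      tau = params$tau, xi_t = params$xi_t, vp = params$v_p,
      D = params$noise_d, dt = params$dt,
      max_steps = as.integer(ceiling(max_time / params$dt)),
      n_rep = as.integer(n_reps),
      gap_stop = (stop_rule == "gap"), arc_time = arc_time
    )
  }
  out <- if (is.null(seed)) run() else with_seed(seed, run())
  tibble::as_tibble(out)
}

#' Complete a triangle once with the dynamic model
#'
#' Runs the two tips until the stopping rule fires and reports the apex
#' estimate. `vertex_rule = "midpoint"` (default) takes the midpoint of the
#' two tips at stopping; `"crossing"` intersects the tips' final headings.
#'
#' @param spec A [triangle_spec()].
#' @param params A [dynamic_params()].
#' @param seed Optional integer seed (same seed, same result, bit for bit).
#' @param stop_rule `"gap"` (threshold on the tips' horizontal distance; the
#'   default) or `"fixed_arc"` (each side extrapolates exactly one side
#'   length).
#' @param vertex_rule `"midpoint"` or `"crossing"`.
#' @return A list of class `tc_completion`: `vertex` (one-row tibble `x`,
#'   `y`, in the spec's orientation), `stop_time`, `stopped_by`
#'   (`"threshold"` or `"max_time"`), `tips` (tip states at stopping).
#' @export
#' @examples
#' p <- dynamic_params(tau = 0.02, v_p = 1, xi_t = 2, noise_d = 0, eps = 0.1)
#' complete_triangle(triangle_spec(2, 45), p, seed = 1)
complete_triangle <- function(spec, params, seed = NULL,
                              stop_rule = c("gap", "fixed_arc"),
                              vertex_rule = c("midpoint", "crossing")) {
  vertex_rule <- match.arg(vertex_rule)
  raw <- dyn_ensemble_raw(spec, params, 1L, seed, stop_rule)
  v <- if (vertex_rule == "midpoint") {
    list(x = raw$x[1L], y = raw$y[1L])
  } else {
    crossing_point(
      raw$tip_left_x[1L], raw$tip_left_y[1L], raw$theta_left[1L],
      raw$tip_right_x[1L], raw$tip_right_y[1L], raw$theta_right[1L]
    )
  }
  p <- orient_xy(spec, v$x, v$y)
  structure(
    list(
      vertex = tibble::tibble(x = p$x, y = p$y),
      stop_time = raw$t_stop[1L],
      stopped_by = if (raw$stopped[1L] == 1L) "threshold" else "max_time",
      tips = raw[, c(
        "tip_left_x", "tip_left_y", "theta_left",
        "tip_right_x", "tip_right_y", "theta_right"
      )],
      spec = spec, params = params, stop_rule = match.arg(stop_rule)
    ),
    class = "tc_completion"
  )
}

#' @export
print.tc_completion <- function(x, ...) {
  cat(sprintf(
    "<tc_completion> vertex (%.4g, %.4g), stop %s at t = %g\n",
    x$vertex$x, x$vertex$y, x$stopped_by, x$stop_time
  ))
  invisible(x)
}

#' Monte-Carlo moments of the dynamic model's apex estimate
#'
#' Repeats [complete_triangle()] `n_reps` times (in compiled code) and
#' summarizes the apex-estimate distribution. Replicates that hit the time
#' cap without crossing the threshold are excluded from the moments and
#' counted (a message reports the count).
#'
#' @inheritParams complete_triangle
#' @param n_reps Number of replicates (>= 100).
#' @return A one-row tibble: `n_reps`, `n_used`, `n_excluded`, `mean_x`,
#'   `mean_y`, `bias`, `sigma_x`, `sigma_y`, `se_mean_x`, `se_mean_y`,
#'   `se_sigma_x`, `se_sigma_y`, `mean_stop_time`, `stop_rule`. Moments are
#'   reported in the upright frame (height above base), regardless of the
#'   spec's orientation.
#' @export
ensemble_moments <- function(spec, params, n_reps = 1000, seed = NULL,
                             stop_rule = c("gap", "fixed_arc"),
                             vertex_rule = c("midpoint", "crossing")) {
  n_reps <- check_count(n_reps, "n_reps", min = 100L)
  stop_rule <- match.arg(stop_rule)
  vertex_rule <- match.arg(vertex_rule)
  raw <- dyn_ensemble_raw(spec, params, n_reps, seed, stop_rule)
  ok <- raw$stopped == 1L
  n_excl <- sum(!ok)
  if (n_excl > 0L) {
    inform(sprintf(
      "ensemble_moments: %d of %d replicates hit max_time and were excluded.",
      n_excl, n_reps
    ))
  }
  use <- raw[ok, ]
  if (vertex_rule == "crossing") {
    cp <- crossing_point(
      use$tip_left_x, use$tip_left_y, use$theta_left,
      use$tip_right_x, use$tip_right_y, use$theta_right
    )
    xs <- cp$x
    ys <- cp$y
  } else {
    xs <- use$x
    ys <- use$y
  }
  n <- length(xs)
  L <- side_length(spec)
  tibble::tibble(
    n_reps = n_reps, n_used = n, n_excluded = n_excl,
    mean_x = mean(xs), mean_y = mean(ys),
    bias = mean(ys) - L * sin(spec$theta0),
    sigma_x = sd(xs), sigma_y = sd(ys),
    se_mean_x = sd(xs) / sqrt(n), se_mean_y = sd(ys) / sqrt(n),
    se_sigma_x = sd(xs) / sqrt(2 * (n - 1)),
    se_sigma_y = sd(ys) / sqrt(2 * (n - 1)),
    mean_stop_time = mean(use$t_stop),
    stop_rule = stop_rule
  )
}
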