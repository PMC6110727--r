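test_that("noise-free simulation is a straight ray at the base angle", {
  p <- dynamic_params(tau = 0.05, v_p = 1, xi_t = 2, noise_d = 0, eps = 0.1, dt = 0.001)
  tr <- simulate_side(45, p, total_time = 1)
  last <- tr[nrow(tr), ]
  expect_equal(last$x, 1 / sqrt(2), tolerance = 1e-9)
  expect_equal(last$y, 1 / sqrt(2), tolerance = 1e-9)
  expect_equal(last$theta, pi / 4, tolerance = 1e-12)
  # mirrored side: same law reflected in x
  tr_r <- simulate_side(45, p, total_time = 1, direction = "right")
  expect_equal(tr_r$x, -tr$x)
  expect_equal(tr_r$y, tr$y)
  expect_equal(tr_r$theta, pi - tr$theta)
})

test_that("heading relaxation follows the damped linear oscillator closed form", {
  theta0 <- deg <- 36 * pi / 180
  delta <- 10 * pi / 180
  for (cfg in list(
    list(tau = 0.1, xi_t = 2), # overdamped: xi_t > 4 tau
    list(tau = 1, xi_t = 2) # underdamped: xi_t < 4 tau
  )) {
    p <- dynamic_params(
      tau = cfg$tau, v_p = 1, xi_t = cfg$xi_t, noise_d = 0,
      eps = 0.1, dt = 5e-4
    )
    tr <- simulate_side(36, p, total_time = 3, theta_start_deg = 46)
    oracle <- osc_relaxation(tr$t, theta0, delta, cfg$tau, cfg$xi_t)
    expect_lt(max(abs(tr$theta - oracle)), 5e-3)
  }
})

test_that("heading variance reaches the white-noise stationary value D tau^2 xi_t / 2", {
  tau <- 0.1
  xi_t <- 1
  D <- 5
  p <- dynamic_params(tau = tau, v_p = 1, xi_t = xi_t, noise_d = D, eps = 0.1, dt = 0.002)
  tr <- simulate_side(36, p, total_time = 800, seed = 21)
  th <- tr$theta[tr$t > 10]
  expect_equal(var(th), D * tau^2 * xi_t / 2, tolerance = 0.12)
})

test_that("noise-free completion stops at the threshold geometry and converges to the apex", {
  spec <- triangle_spec(2, 45)
  p <- dynamic_params(tau = 0.02, v_p = 1, xi_t = 2, noise_d = 0, eps = 0.1, dt = 2e-4)
  res <- complete_triangle(spec, p, seed = 1)
  expect_identical(res$stopped_by, "threshold")
  # straight rays stopped when tips are eps apart: height 1 - (eps/2) tan(45)
  expect_equal(res$vertex$x, 0, tolerance = 1e-9)
  expect_equal(res$vertex$y, 1 - 0.05, tolerance = 2e-3)
  p0 <- dynamic_params(tau = 0.02, v_p = 1, xi_t = 2, noise_d = 0, eps = 1e-4, dt = 2e-4)
  res0 <- complete_triangle(spec, p0, seed = 1)
  expect_equal(res0$vertex$y, 1, tolerance = 2e-3)
  # crossing-rule vertex agrees in the noise-free case
  resx <- complete_triangle(spec, p, seed = 1, vertex_rule = "crossing")
  expect_equal(resx$vertex$y, 1, tolerance = 2e-3)
})

test_that("completions are deterministic given the seed and flag max_time", {
  spec <- triangle_spec(2, 36)
  p <- as_dynamic_params(wlc_params(xi = 2, v0 = 0.26), tau_frac = 0.05, dt_frac = 0.1)
  r1 <- complete_triangle(spec, p, seed = 42)
  r2 <- complete_triangle(spec, p, seed = 42)
  expect_identical(r1$vertex, r2$vertex)
  expect_identical(r1$tips, r2$tips)
  e1 <- ensemble_moments(spec, p, n_reps = 300, seed = 9)
  e2 <- ensemble_moments(spec, p, n_reps = 300, seed = 9)
  expect_identical(e1, e2)
  p_short <- dynamic_params(
    tau = p$tau, v_p = 1, xi_t = p$xi_t, noise_d = 0,
    eps = 1e-9, dt = p$dt, max_time = 0.2
  )
  flagged <- complete_triangle(spec, p_short, seed = 3)
  expect_identical(flagged$stopped_by, "max_time")
})

test_that("left and right extrapolations are statistically independent", {
  spec <- triangle_spec(2 * 4 * cos(36 * pi / 180), 36)
  p <- as_dynamic_params(wlc_params(xi = 2, v0 = 0.26), tau_frac = 0.02, dt_frac = 0.1)
  raw <- tricomp:::dyn_ensemble_raw(spec, p, 4000, seed = 31, stop_rule = "fixed_arc")
  r <- cor(raw$tip_left_y, raw$tip_right_y)
  expect_lt(abs(r), 3 / sqrt(4000))
})

test_that("fixed-arc ensemble matches analytic moments; gap stopping inflates sigma_y by ~sec^2(theta0)", {
  wlc <- wlc_params(xi = 2, v0 = 0.26)
  theta <- 36
  L <- 5
  spec <- triangle_spec(2 * L * cos(theta * pi / 180), theta)
  p <- as_dynamic_params(wlc, tau_frac = 0.01, eps = 0.02, dt_frac = 0.05)
  m <- endpoint_moments(wlc, theta, L)
  sig_y <- sqrt(m$var_y / 2)
  fixed <- ensemble_moments(spec, p, n_reps = 4000, seed = 17, stop_rule = "fixed_arc")
  expect_equal(fixed$mean_y, m$mean_y, tolerance = 4 * fixed$se_mean_y / m$mean_y)
  expect_equal(fixed$sigma_y / sig_y, 1, tolerance = 0.08)
  gap <- ensemble_moments(spec, p, n_reps = 4000, seed = 18, stop_rule = "gap")
  ratio <- gap$sigma_y / sig_y
  sec2 <- 1 / cos(theta * pi / 180)^2
  expect_gt(ratio, 0.85 * sec2)
  expect_lt(ratio, 1.25 * sec2)
  # the gap rule also cancels the downward bias to leading order
  expect_lt(abs(gap$bias), abs(fixed$bias))
})
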