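test_that("parameterizations round-trip exactly", {
  withr::with_seed(3, {
    for (i in 1:20) {
      lp <- runif(1, 0.01, 100)
      f <- runif(1, 0.01, 100)
      p <- wlc_params(l_p = lp, f = f)
      q <- wlc_params(xi = p$xi, v0 = p$v0)
      expect_equal(q$l_p, lp, tolerance = 1e-14)
      expect_equal(q$f, f, tolerance = 1e-14)
    }
  })
  expect_error(wlc_params(xi = 2), "exactly one pair")
  expect_error(wlc_params(xi = -1, v0 = 0.2), "xi")
})

test_that("endpoint moments reduce to exact geometry in the zero-noise limit", {
  m <- endpoint_moments(wlc_params(xi = 2, v0 = 1e-12), 36, 10)
  expect_equal(m$mean_y, 10 * sin(36 * pi / 180), tolerance = 1e-9)
  expect_equal(m$mean_x, 10 * cos(36 * pi / 180), tolerance = 1e-9)
  expect_lt(m$var_y, 1e-9)
  expect_equal(m$bias, 0, tolerance = 1e-9)
})

test_that("sampled paths have the stationary variance and autocorrelation of the angle law", {
  params <- wlc_params(xi = 2, v0 = 0.26)
  # stationary variance v0/2 at the far end of a long path
  e <- sample_endpoints(params, 36, L = 80, n_paths = 20000, seed = 5)
  expect_equal(var(e$phi_end), params$v0 / 2, tolerance = 0.03)
  # ergodic lag autocorrelation exp(-ds/xi) along one long path
  p <- sample_path(params, 36, L = 20000, n_segments = 200000, seed = 6)
  h <- 0.1
  phi <- p$phi[p$s > 20] # discard the pinned transient
  for (lag_xi in c(1, 2)) {
    k <- round(lag_xi * params$xi / h)
    ac <- cor(phi[seq_len(length(phi) - k)], phi[-seq_len(k)])
    expect_lt(abs(ac - exp(-lag_xi)), 0.05)
  }
})

test_that("analytic endpoint moments agree with Monte-Carlo sampling", {
  params <- wlc_params(xi = 2, v0 = 0.26)
  m <- endpoint_moments(params, 36, 20)
  e <- sample_endpoints(params, 36,
    L = 20, n_paths = 40000,
    n_segments = 400, seed = 9
  )
  n <- nrow(e)
  expect_lt(abs(mean(e$y) - m$mean_y), 3 * sd(e$y) / sqrt(n))
  expect_lt(abs(mean(e$x) - m$mean_x), 3 * sd(e$x) / sqrt(n))
  expect_lt(abs(sd(e$y) - m$sigma_y), 3 * m$sigma_y / sqrt(2 * n) + 0.01 * m$sigma_y)
  expect_lt(abs(sd(e$x) - m$sigma_x), 3 * m$sigma_x / sqrt(2 * n) + 0.01 * m$sigma_x)
})

test_that("quadrature is deterministic and converged", {
  params <- wlc_params(xi = 2, v0 = 0.26)
  m1 <- endpoint_moments(params, 36, 50)
  m2 <- endpoint_moments(params, 36, 50)
  expect_identical(m1, m2)
  m3 <- endpoint_moments(params, 36, 50, n_quad = 360)
  expect_equal(m1$var_y, m3$var_y, tolerance = 1e-6)
})

test_that("averaging two independent sides halves the apex variance", {
  params <- wlc_params(xi = 2, v0 = 0.26)
  spec <- triangle_spec(2 * 10 * cos(36 * pi / 180), 36)
  v <- vertex_distribution(spec, params, 40000, seed = 12)
  side <- endpoint_moments(params, 36, side_length(spec))
  expect_equal(var(v$y), side$var_y / 2, tolerance = 0.05)
  expect_equal(var(v$x), side$var_x / 2, tolerance = 0.05)
  expect_equal(mean(v$x), 0, tolerance = 0.01)
})

test_that("bias grows linearly with the closed-form asymptotic slope", {
  params <- wlc_params(xi = 2, v0 = 0.26)
  grid <- seq(20, 100, by = 10)
  m <- endpoint_moments(params, 36, grid)
  fit <- lm(bias ~ L, data = m)
  expect_true(all(m$bias < 0))
  expect_gt(summary(fit)$r.squared, 0.999)
  oracle <- sin(36 * pi / 180) * (exp(-params$v0 / 4) - 1)
  expect_equal(unname(coef(fit)[2]), oracle, tolerance = 0.01)
})

test_that("vertical spread scales sub-linearly: local slopes bracket the global exponent", {
  sc <- scaling_curve(wlc_params(xi = 2, v0 = 0.26), 36, log_spaced(1, 100, 15))
  expect_true(all(diff(sc$sigma_y) > 0))
  local <- diff(log(sc$sigma_y)) / diff(log(sc$L))
  expect_gt(local[1], 1) # persistence-dominated at L << xi
  expect_equal(local[length(local)], 0.5, tolerance = 0.1) # diffusive at L >> xi
  fit <- fit_power_law(sc$L, sc$sigma_y)
  expect_gt(fit$exponent, 0.5)
  expect_lt(fit$exponent, 1)
})

test_that("stationary-start mode changes the transient, not the long-range law", {
  params <- wlc_params(xi = 2, v0 = 0.26)
  pin <- endpoint_moments(params, 36, 2)
  stat <- endpoint_moments(params, 36, 2, pinned = FALSE)
  expect_lt(stat$mean_y, pin$mean_y) # full noise from s = 0
  long_p <- endpoint_moments(params, 36, 200)
  long_s <- endpoint_moments(params, 36, 200, pinned = FALSE)
  expect_equal(long_s$mean_y / long_p$mean_y, 1, tolerance = 0.005)
})
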