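make_sigma_table <- function(exponent, n_part = 8, Ls = c(1, 2, 4, 8, 16)) {
  d <- tidyr::expand_grid(participant = seq_len(n_part), L = Ls)
  d$sigma <- 0.3 * d$L^exponent
  d
}

test_that("exact power-law input recovers the exponent to machine precision", {
  f77 <- fit_scaling_exponent(make_sigma_table(0.77), n_boot = 50, seed = 1)
  expect_equal(f77$exponent, 0.77, tolerance = 1e-12)
  expect_equal(f77$median_exponent, 0.77, tolerance = 1e-12)
  f1 <- fit_scaling_exponent(make_sigma_table(1), n_boot = 50, seed = 1)
  expect_equal(f1$exponent, 1, tolerance = 1e-12)
  expect_true(f1$ci[1] <= f1$median_exponent && f1$median_exponent <= f1$ci[2])
})

test_that("scaling fits are scale-invariant in sigma and reject bad input", {
  d <- make_sigma_table(0.7)
  f1 <- fit_scaling_exponent(d, n_boot = 30, seed = 2)
  d2 <- d
  d2$sigma <- d2$sigma * 37
  f2 <- fit_scaling_exponent(d2, n_boot = 30, seed = 2)
  expect_equal(f1$exponent, f2$exponent, tolerance = 1e-12)
  expect_equal(f2$intercept - f1$intercept, log10(37), tolerance = 1e-10)
  expect_identical(f1$boot, f2$boot)
  d_bad <- d
  d_bad$sigma[1] <- 0
  expect_error(fit_scaling_exponent(d_bad), "positive")
  expect_error(fit_scaling_exponent(d[d$L == 1, ]), "3 distinct")
})

test_that("tidy and glance summarize a scaling fit", {
  f <- fit_scaling_exponent(make_sigma_table(0.77), n_boot = 40, seed = 3)
  td <- tidy(f)
  expect_identical(td$term, c("exponent", "intercept"))
  expect_equal(td$estimate[1], 0.77, tolerance = 1e-10)
  g <- glance(f)
  expect_equal(g$n_boot, 40)
  expect_true(g$ci_low <= g$median_exponent)
})

test_that("chi-squared statistic matches hand evaluation and permutation invariance", {
  expect_equal(chisq_gof(c(0.5, 0.5), c(10, 10))$statistic, 0)
  z <- chisq_gof(c(0.6, 0.4), c(30, 20))
  expect_equal(z$statistic, 0, tolerance = 1e-12)
  h <- chisq_gof(c(0.5, 0.5), c(12, 8))
  expect_equal(h$statistic, 0.8)
  expect_equal(h$df, 1L)
  a <- chisq_gof(c(0.2, 0.3, 0.5), c(10, 20, 20))
  b <- chisq_gof(c(0.5, 0.2, 0.3), c(20, 10, 20))
  expect_equal(a$statistic, b$statistic)
  one <- chisq_gof(c(0.2, 0.3, 0.5), c(10, 20, 20), df_mode = "one")
  expect_equal(one$df, 1L)
  expect_message(
    chisq_gof(c(0.5, 0.5, 0), c(10, 8, 2)),
    "merged"
  )
})

test_that("Bayes factors match direct arithmetic, multiply over splits, and flag overflow", {
  expect_equal(bayes_factor(c(0.5, 0.5), c(0.5, 0.5), c(7, 3))$bf, 1)
  expect_equal(bayes_factor(c(0.6, 0.4), c(0.3, 0.7), c(0, 0))$bf, 1)
  toy <- bayes_factor(c(0.5, 0.3, 0.2), c(0.25, 0.5, 0.25), c(10, 5, 5))
  expect_equal(toy$bf, 2^10 * 0.6^5 * 0.8^5, tolerance = 1e-12)
  expect_equal(toy$bf, 26.09, tolerance = 1e-3)
  # multiplicativity: counts n = n' + n''
  p1 <- c(0.5, 0.3, 0.2)
  p2 <- c(0.25, 0.5, 0.25)
  full <- bayes_factor(p1, p2, c(10, 5, 5))$log10_bf
  parts <- bayes_factor(p1, p2, c(4, 2, 1))$log10_bf +
    bayes_factor(p1, p2, c(6, 3, 4))$log10_bf
  expect_equal(full, parts, tolerance = 1e-12)
  up <- bayes_factor(c(0.5, 0.5, 0), c(0.4, 0.3, 0.3), c(1, 1, 1))
  expect_identical(up$overflow, "-inf")
  expect_equal(up$bf, 0)
  dn <- bayes_factor(c(0.4, 0.3, 0.3), c(0.5, 0.5, 0), c(1, 1, 1))
  expect_identical(dn$overflow, "+inf")
  expect_identical(dn$bf, Inf)
})

test_that("threshold classification uses strict inequalities with a closed 'same' interval", {
  d <- tibble::tibble(
    init = c(100, 100, 100, 100, 100),
    after = c(106, 94, 105, 95, 100) # 105/95 sit exactly on the threshold
  )
  out <- apply_categorical_thresholds(d, threshold = 0.05)
  expect_identical(out$category, c("increase", "decrease", "same", "same", "same"))
  expect_error(
    apply_categorical_thresholds(tibble::tibble(init = 0, after = 1)),
    "nonzero"
  )
  cv <- median_response_cv(
    tibble::tibble(g = rep(1:2, each = 4), v = c(rep(5, 4), c(1, 2, 3, 4))),
    "v", "g"
  )
  expect_equal(cv, mean(c(0, sd(1:4) / 2.5)))
})

test_that("Bayes factor favors the generating model on synthetic categorical counts", {
  cp <- categorical_params("fig3d")
  pw <- predict_response("VIA", cp, seed = 5, n_pairs = 4000)
  pn <- predict_response("VIA", cp, model = "null", seed = 6, n_pairs = 4000)
  p_wlc <- c(pw$p_increase, pw$p_decrease, pw$p_same)
  p_null <- c(pn$p_increase, pn$p_decrease, pn$p_same)
  wins <- withr::with_seed(99, {
    vapply(1:50, function(i) {
      counts <- as.integer(rmultinom(1, 400, p_wlc))
      bayes_factor(p_wlc, p_null, counts)$log10_bf > 0
    }, logical(1))
  })
  expect_gte(mean(wins), 0.95)
})
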