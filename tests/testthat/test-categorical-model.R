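test_that("there are exactly eight valid question codes; invalid codes are rejected", {
  q <- question_codes()
  expect_equal(nrow(q), 8)
  expect_setequal(q$code, c("VIA", "VDA", "VID", "VDD", "AIA", "ADA", "AID", "ADD"))
  expect_error(
    predict_response("XIA", categorical_params("fig3d"), seed = 1),
    "Invalid question code"
  )
  expect_error(categorical_params("fig3d", nonsense = 1), "Unknown categorical")
})

test_that("deterministic geometry forces unanimous answers in the zero-noise limit", {
  p <- categorical_params("fig3d", v0 = 1e-8)
  # distance doubles, apex scales up: 100% "up"
  r <- predict_response("VID", p, seed = 1, n_pairs = 200)
  expect_equal(r$p_increase, 1)
  expect_identical(r$modal, "up")
  # identity manipulation with vanishing variance: 100% "same"
  p_id <- categorical_params("fig3d", v0 = 1e-8, dist_factor_location = 1)
  r_id <- predict_response("VID", p_id, seed = 1, n_pairs = 200)
  expect_equal(r_id$p_same, 1)
  # symmetric manipulations reverse direction exactly
  r_up <- predict_response("VIA", p, seed = 2, n_pairs = 200)
  r_dn <- predict_response("VDA", p, seed = 2, n_pairs = 200)
  expect_equal(r_up$p_increase, 1)
  expect_equal(r_dn$p_decrease, 1)
})

test_that("response distributions normalize, and a master seed reproduces the table", {
  tab <- predict_all(categorical_params("fig3d"), seed = 101)
  expect_equal(nrow(tab), 8)
  expect_equal(tab$p_increase + tab$p_decrease + tab$p_same, rep(1, 8))
  tab2 <- predict_all(categorical_params("fig3d"), seed = 101)
  expect_identical(tab, tab2)
})

test_that("the 'same' proportion is nondecreasing in the threshold", {
  p_same <- vapply(c(0.02, 0.05, 0.1, 0.2, 0.4), function(th) {
    p <- categorical_params("fig3d", th_l = th, th_a = th)
    predict_response("AID", p, seed = 55, n_pairs = 2000)$p_same
  }, numeric(1))
  expect_true(all(diff(p_same) >= 0))
})

test_that("modal predictions reproduce the qualitative response pattern", {
  tab <- predict_all(categorical_params("fig3d"), seed = 7, n_pairs = 4000)
  modal <- setNames(tab$modal, tab$code)
  # location questions: the Euclidean-correct category dominates
  expect_identical(modal[["VIA"]], "up")
  expect_identical(modal[["VDA"]], "down")
  expect_identical(modal[["VID"]], "up")
  expect_identical(modal[["VDD"]], "down")
  # angle-of-angle questions: Euclidean-correct
  expect_identical(modal[["AIA"]], "smaller")
  expect_identical(modal[["ADA"]], "bigger")
  # angle-of-distance questions: the modal answer follows the manipulation,
  # against Euclid's scale invariance
  expect_identical(modal[["AID"]], "bigger")
  expect_identical(modal[["ADD"]], "smaller")
})

test_that("proportions are stable across master seeds at the default sample size", {
  ps <- vapply(1:10, function(s) {
    predict_response("VID", categorical_params("fig3d"), seed = s)$p_increase
  }, numeric(1))
  expect_lt(max(ps) - min(ps), 0.05)
})

test_that("the methods preset runs and preserves its published parameter values", {
  p <- categorical_params("methods")
  expect_equal(p$xi, 1.25)
  expect_equal(p$v0, 0.5)
  expect_equal(p$l_init_location, 3.2)
  expect_equal(p$l_init_angle, 1.25)
  tab <- predict_all(p, seed = 3, n_pairs = 400)
  expect_equal(tab$p_increase + tab$p_decrease + tab$p_same, rep(1, 8))
  expect_identical(setNames(tab$modal, tab$code)[["VID"]], "up")
})

test_that("null-model predictions treat distance manipulations as scale-invariant for angles", {
  tab <- predict_all(categorical_params("fig3d"),
    model = "null",
    null_params = null_params(5), seed = 11, n_pairs = 4000
  )
  aid <- tab[tab$code == "AID", ]
  # straight-line angles do not depend on size: "same" dominates
  expect_gt(aid$p_same, aid$p_increase)
  expect_gt(aid$p_same, aid$p_decrease)
})
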