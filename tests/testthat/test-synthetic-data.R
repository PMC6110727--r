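test_that("experiment designs match the published structure", {
  d1 <- experiment_design(1)
  expect_equal(d1$n_participants, 40)
  expect_equal(d1$repeats, 10L)
  expect_equal(sort(d1$groups$angles_deg[[1]]), c(30, 36, 45))
  expect_equal(d1$groups$pixel_scale, c(1900, 1900))
  expect_equal(experiment_design(2)$n_participants, 100)
  expect_equal(experiment_design(2)$groups$pixel_scale, c(900, 1300))
  d3 <- experiment_design(3)
  expect_identical(d3$orientation, "y")
  expect_equal(d3$n_participants, 29)
  expect_identical(experiment_design(4)$task, "angle")
  expect_equal(experiment_design(5)$n_participants, 407)
  expect_error(experiment_design(6), "1-5")
})

test_that("a synthetic localization run has the designed shape and is seed-reproducible", {
  tab <- generate_experiment(experiment_design(1), seed = 1)
  expect_equal(nrow(tab), 6000) # 40 participants x 15 triangles x 10 repeats
  expect_equal(unname(table(tab$participant)), rep(150L, 40), ignore_attr = TRUE)
  expect_true(all(is.finite(tab$resp_x) & is.finite(tab$resp_y)))
  expect_true(all(tab$rt > 0))
  tab2 <- generate_experiment(experiment_design(1), seed = 1)
  expect_identical(tab, tab2)
  tab3 <- generate_experiment(experiment_design(1), seed = 2)
  expect_false(identical(tab$resp_y, tab3$resp_y))
})

test_that("response times increase with triangle size", {
  tab <- generate_experiment(experiment_design(1), seed = 4)
  r <- cor(tab$side_length, tab$rt, method = "spearman")
  expect_gt(r, 0.3)
})

test_that("group rescaling divides the designated group's responses", {
  tab <- generate_experiment(experiment_design(2), seed = 3)
  out <- rescale_groups(tab, 13 / 9, "g2")
  sel <- tab$group == "g2"
  expect_equal(out$resp_y[sel], tab$resp_y[sel] / (13 / 9))
  expect_identical(out$resp_y[!sel], tab$resp_y[!sel])
  twice <- rescale_groups(out, 13 / 9, "g2")
  expect_equal(twice$resp_y[sel], tab$resp_y[sel] / (13 / 9)^2)
  expect_error(rescale_groups(tab, 1.2, "g9"), "not present")
})

test_that("the two-stage summary matches brute-force pooling for one participant", {
  tab <- generate_experiment(experiment_design(1), seed = 5)
  one <- tab[tab$participant == 7, ]
  s <- summarize_localization(one)
  oracle <- pooled_localization(one)
  s$cell <- paste(s$base_angle_deg, s$base_length)
  s <- s[order(s$cell), ]
  expect_equal(s$bias_y, oracle$bias_y, tolerance = 1e-12)
  expect_equal(s$sigma_y, oracle$sigma_y, tolerance = 1e-12)
  expect_equal(s$bias_x, oracle$bias_x, tolerance = 1e-12)
})

test_that("a constant vertical shift moves the bias by exactly that amount", {
  tab <- generate_experiment(experiment_design(1), seed = 6)
  shifted <- tab
  shifted$resp_y <- shifted$resp_y - 0.05
  s0 <- summarize_localization(tab)
  s1 <- summarize_localization(shifted)
  expect_equal(s1$bias_y, s0$bias_y - 0.05, tolerance = 1e-12)
  expect_equal(s1$sigma_y, s0$sigma_y, tolerance = 1e-12)
})

test_that("tables round-trip through CSV, including permissive column mapping", {
  tab <- generate_experiment(experiment_design(3), seed = 7)
  path <- withr::local_tempfile(fileext = ".csv")
  write_response_table(tab, path)
  back <- read_response_table(path)
  expect_equal(nrow(back), nrow(tab))
  expect_equal(back$resp_y, tab$resp_y, tolerance = 1e-10)
  expect_identical(back$group, tab$group)
  # a file with foreign headers maps onto the canonical schema
  foreign <- back
  names(foreign)[names(foreign) == "resp_x"] <- "click_x"
  names(foreign)[names(foreign) == "resp_y"] <- "click_y"
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(as.data.frame(foreign), path2, row.names = FALSE)
  mapped <- read_response_table(path2, col_map = c(
    resp_x = "click_x", resp_y = "click_y"
  ))
  expect_equal(mapped$resp_y, back$resp_y)
  expect_error(read_response_table(path2, col_map = c(resp_x = "nope")), "not found")
})

test_that("the rotated presentation yields the identical scaling fit under the same seed", {
  d3 <- experiment_design(3)
  tab_rot <- generate_experiment(d3, seed = 8)
  d3x <- d3
  d3x$orientation <- "x"
  tab_x <- generate_experiment(d3x, seed = 8)
  p_rot <- localization_by_participant(tab_rot)
  p_x <- localization_by_participant(tab_x)
  expect_equal(p_rot$sigma_y, p_x$sigma_y, tolerance = 1e-12)
  f_rot <- fit_scaling_exponent(p_rot,
    n_boot = 100, seed = 1,
    l_col = "side_length", sigma_col = "sigma_y"
  )
  f_x <- fit_scaling_exponent(p_x,
    n_boot = 100, seed = 1,
    l_col = "side_length", sigma_col = "sigma_y"
  )
  expect_equal(f_rot$exponent, f_x$exponent, tolerance = 1e-12)
  expect_identical(f_rot$boot, f_x$boot)
})

test_that("generators imprint their scaling signature on a full synthetic run", {
  tab_wlc <- generate_experiment(experiment_design(1), "wlc", seed = 9)
  f_wlc <- fit_scaling_exponent(
    localization_by_participant(tab_wlc),
    n_boot = 400, seed = 2, l_col = "side_length", sigma_col = "sigma_y"
  )
  expect_lt(f_wlc$ci[2], 1) # sub-linear: CI excludes 1
  tab_null <- generate_experiment(experiment_design(1), "null", seed = 9)
  f_null <- fit_scaling_exponent(
    localization_by_participant(tab_null),
    n_boot = 400, seed = 2, l_col = "side_length", sigma_col = "sigma_y"
  )
  expect_true(f_null$ci[1] <= 1 && 1 <= f_null$ci[2]) # linear: CI covers 1
})

test_that("the angle-task and categorical-task generators produce valid tables", {
  tab4 <- generate_experiment(experiment_design(4), seed = 10)
  expect_equal(nrow(tab4), 65 * 150)
  expect_true(all(is.finite(tab4$resp_angle_deg)))
  expect_true(all(tab4$true_angle_deg == 180 - 2 * tab4$base_angle_deg))

  tab5 <- generate_experiment(experiment_design(5), seed = 11)
  expect_equal(nrow(tab5), 407 * 8)
  expect_true(all(tab5$answer %in% c("up", "down", "bigger", "smaller", "same")))
  expect_true(all(tab5$education_years >= 8 & tab5$education_years <= 33))
  expect_equal(sort(unique(tab5$question)), sort(question_codes()$code))
  ages <- tab5$age[!duplicated(tab5$participant)]
  expect_true(median(ages) >= 25 && median(ages) <= 37)
})
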