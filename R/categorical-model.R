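# Categorical reasoning predictions.
#
# Eight three-way questions about a fragmented triangle: what happens to the
# missing vertex location (V) or the missing angle size (A) when the base
# angles (A) or the base distance (D) increase (I) or decrease (D)? The
# model answers by sampling the judged quantity under the initial and the
# manipulated stimulus, pairing the draws by index, and classifying each
# pair's relative change against a +-5% threshold (strict inequalities for
# the change categories, the closed interval for "same").

#' The eight categorical question codes
#'
#' Codes concatenate judged quantity (V = vertex location, A = angle size),
#' manipulation direction (I/D), and manipulated property (A = base angles,
#' D = base distance).
#'
#' @return A tibble: `code`, `judged`, `direction`, `manipulated`, and the
#'   category labels used for increase/decrease responses.
#' @export
question_codes <- function() {
  tibble::tibble(
    code = c("VIA", "VDA", "VID", "VDD", "AIA", "ADA", "AID", "ADD"),
    judged = rep(c("V", "A"), each = 4L),
    direction = rep(c("I", "D"), 4L),
    manipulated = rep(rep(c("A", "D"), each = 2L), 2L),
    label_increase = rep(c("up", "bigger"), each = 4L),
    label_decrease = rep(c("down", "smaller"), each = 4L)
  )
}

#' Parameters for the categorical predictor
#'
#' Two published parameter sets are shipped as presets and deliberately kept
#' distinct:
#' * `"fig3d"`: xi = 2, v0 = 0.4, thresholds 0.05, initial base angle 36
#'   degrees, initial side length 2 with distance manipulations x2 / x1/2
#'   (side lengths spanning 2-4), angle manipulations 36 -> 45 / 36 -> 27
#'   degrees.
#' * `"methods"`: xi = 1.25, v0 = 0.5, thresholds 0.05, initial side length
#'   3.2 for location questions and 1.25 for angle questions, angle
#'   manipulation 36 -> 45 degrees, distance factors 1.25 (location) and
#'   1.5 (angle), reciprocal factors for decreases.
#'
#' @param preset `"fig3d"` (default) or `"methods"`.
#' @param ... Named overrides of any field (`xi`, `v0`, `th_l`, `th_a`,
#'   `theta_init_deg`, `theta_increase_deg`, `theta_decrease_deg`,
#'   `l_init_location`, `l_init_angle`, `dist_factor_location`,
#'   `dist_factor_angle`, `n_pairs`).
#' @return An object of class `tc_categorical_params`.
#' @export
#' @examples
#' categorical_params("fig3d")
#' categorical_params("methods", n_pairs = 1000)
categorical_params <- function(preset = c("fig3d", "methods"), ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    fig3d = list(
      xi = 2, v0 = 0.4, th_l = 0.05, th_a = 0.05,
      theta_init_deg = 36, theta_increase_deg = 45, theta_decrease_deg = 27,
      l_init_location = 2, l_init_angle = 2,
      dist_factor_location = 2, dist_factor_angle = 2,
      n_pairs = 400
    ),
    methods = list(
      xi = 1.25, v0 = 0.5, th_l = 0.05, th_a = 0.05,
      theta_init_deg = 36, theta_increase_deg = 45, theta_decrease_deg = 27,
      l_init_location = 3.2, l_init_angle = 1.25,
      dist_factor_location = 1.25, dist_factor_angle = 1.5,
      n_pairs = 400
    )
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(base))
  if (length(unknown)) {
    abort(paste0("Unknown categorical parameter(s): ", toString(unknown)))
  }
  out <- modifyList(base, over)
  for (nm in c("xi", "v0", "th_l", "th_a", "l_init_location", "l_init_angle")) {
    check_number(out[[nm]], nm, lower = 0)
  }
  out$n_pairs <- check_count(out$n_pairs, "n_pairs", min = 2L)
  out$preset <- preset
  structure(out, class = "tc_categorical_params")
}

# initial and manipulated stimulus for one question
question_specs <- function(q, params) {
  th0 <- params$theta_init_deg
  l0 <- if (q$judged == "V") params$l_init_location else params$l_init_angle
  b0 <- 2 * l0 * cos(deg2rad(th0))
  init <- triangle_spec(b0, th0)
  after <- if (q$manipulated == "A") {
    th1 <- if (q$direction == "I") params$theta_increase_deg else params$theta_decrease_deg
    triangle_spec(b0, th1) # distance fixed, corner angles change
  } else {
    f <- if (q$judged == "V") params$dist_factor_location else params$dist_factor_angle
    f <- if (q$direction == "I") f else 1 / f
    triangle_spec(b0 * f, th0) # angles fixed, distance scales
  }
  list(init = init, after = after)
}

# n draws of the judged quantity for a stimulus, under the WLC or null model
draw_judged <- function(spec, judged, model, wlc, nullp, n, seed) {
  if (model == "wlc") {
    if (judged == "V") {
      m <- vertex_moments_core(spec$theta0, wlc$xi, wlc$v0, side_length(spec))
      g <- gamma_from_moments(m$mean_y, m$var_y)
      with_seed(seed, rgamma(n, shape = g$shape, scale = g$scale))
    } else {
      missing_angle_samples(spec, wlc, n = n, seed = seed)$angle_rad
    }
  } else {
    s <- sample_vertex_null(spec, nullp, n, seed = seed)
    if (judged == "V") s$y else s$angle_rad
  }
}

classify_relative <- function(init, after, th) {
  r <- (after - init) / init
  ifelse(r > th, "increase", ifelse(r < -th, "decrease", "same"))
}

#' Predict the response distribution for one categorical question
#'
#' Samples the judged quantity independently under the initial and the
#' manipulated stimulus (no common random numbers), pairs draws by index,
#' and classifies relative changes against the threshold.
#'
#' @param code One of the eight [question_codes()].
#' @param params A [categorical_params()].
#' @param model `"wlc"` (default) or `"null"` (straight lines with noisy
#'   base angles).
#' @param null_params A [null_params()]; used when `model = "null"`.
#' @param seed Optional integer seed.
#' @param n_pairs Override of `params$n_pairs`.
#' @return A one-row tibble of class `tc_response_distribution`: `code`,
#'   `model`, `p_increase`, `p_decrease`, `p_same`, `modal` (the labelled
#'   modal category), `n_pairs`.
#' @export
#' @examples
#' predict_response("VID", categorical_params("fig3d"), seed = 1)
predict_response <- function(code, params, model = c("wlc", "null"),
                             null_params = tricomp::null_params(5),
                             seed = NULL, n_pairs = NULL) {
  if (!inherits(params, "tc_categorical_params")) {
    abort("`params` must be created by `categorical_params()`.")
  }
  model <- match.arg(model)
  qtab <- question_codes()
  if (!code %in% qtab$code) {
    abort(sprintf("Invalid question code '%s'.", code))
  }
  q <- as.list(qtab[qtab$code == code, ])
  n <- n_pairs %||% params$n_pairs
  n <- check_count(n, "n_pairs", min = 2L)
  specs <- question_specs(q, params)
  wlc <- wlc_params(xi = params$xi, v0 = params$v0)
  seed <- seed %||% sample.int(.Machine$integer.max, 1L)
  draws_init <- draw_judged(
    specs$init, q$judged, model, wlc, null_params, n,
    substream_seed(seed, 1L)
  )
  draws_after <- draw_judged(
    specs$after, q$judged, model, wlc, null_params, n,
    substream_seed(seed, 2L)
  )
  th <- if (q$judged == "V") params$th_l else params$th_a
  cls <- classify_relative(draws_init, draws_after, th)
  p <- c(
    increase = mean(cls == "increase"),
    decrease = mean(cls == "decrease"),
    same = mean(cls == "same")
  )
  modal_key <- names(p)[which.max(p)]
  out <- tibble::tibble(
    code = code, model = model,
    p_increase = p[["increase"]], p_decrease = p[["decrease"]],
    p_same = p[["same"]],
    modal = switch(modal_key,
      increase = q$label_increase, decrease = q$label_decrease, same = "same"
    ),
    n_pairs = n
  )
  class(out) <- c("tc_response_distribution", class(out))
  out
}

#' Predict all eight categorical questions
#'
#' One [predict_response()] per code, with independent substreams derived
#' from the master seed (the same master seed reproduces the whole table).
#'
#' @inheritParams predict_response
#' @param seed Master seed.
#' @return An 8-row tibble of class `tc_response_distribution`.
#' @export
#' @examples
#' predict_all(categorical_params("fig3d"), seed = 1)
predict_all <- function(params, model = c("wlc", "null"),
                        null_params = tricomp::null_params(5),
                        seed = NULL, n_pairs = NULL) {
  model <- match.arg(model)
  seed <- seed %||% sample.int(.Machine$integer.max, 1L)
  codes <- question_codes()$code
  out <- purrr::imap(codes, function(code, i) {
    predict_response(code, params,
      model = model, null_params = null_params,
      seed = substream_seed(seed, 10L + i), n_pairs = n_pairs
    )
  })
  out <- dplyr::bind_rows(out)
  class(out) <- c("tc_response_distribution", class(out))
  out
}
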