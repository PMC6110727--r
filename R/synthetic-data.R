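# Synthetic participant data.
#
# Generators that reproduce the *structure* of the five behavioral
# experiments (designs, trial counts, stimulus sets, response and
# response-time columns), with responses drawn from one of the package's
# models. They exist so that every pipeline stage — summaries, scaling
# fits, categorical analyses — can be exercised and validated end to end
# without the deposited response files; they make no attempt to mimic
# individual human idiosyncrasies beyond the model law, motor noise, and a
# size-dependent response time.

#' Built-in experiment designs
#'
#' * Experiment 1 — in-lab localization: 40 participants in two groups of
#'   20, base angles 30/36/45 degrees, five base lengths per group
#'   (0.02-1 and 0.04-1, 1 = 1900 px), 10 repeats of 15 triangles.
#' * Experiment 2 — online localization replication: 100 participants, base
#'   angles 30/45/60 or 36/51/66 degrees, base lengths 0.1-1, vertical
#'   scales 900/1300 px.
#' * Experiment 3 — rotated localization (base on the vertical axis): 29
#'   participants, 1 = 1000 px.
#' * Experiment 4 — missing-angle estimation (slider): 65 participants.
#' * Experiment 5 — categorical reasoning: 407 participants, 8 three-way
#'   questions, with demographics.
#'
#' @param id Experiment number, 1-5.
#' @return An object of class `tc_experiment_design`: a list with `id`,
#'   `task` (`"localization"`, `"angle"`, or `"categorical"`), `repeats`,
#'   `orientation`, and a `groups` tibble (`group`, `n_participants`,
#'   `pixel_scale`, list-columns `angles_deg` and `base_lengths`).
#' @export
#' @examples
#' experiment_design(1)
experiment_design <- function(id) {
  id <- check_count(id, "id", min = 1L)
  if (id > 5L) abort("`id` must be 1-5.")
  g <- function(...) tibble::tibble(...)
  design <- switch(id,
    list( # 1
      task = "localization", repeats = 10L, orientation = "x",
      groups = g(
        group = c("g1", "g2"), n_participants = c(20L, 20L),
        pixel_scale = c(1900, 1900),
        angles_deg = list(c(30, 36, 45), c(30, 36, 45)),
        base_lengths = list(
          c(0.02, 0.08, 0.25, 0.5, 1),
          c(0.04, 0.16, 0.32, 0.64, 1)
        )
      )
    ),
    list( # 2
      task = "localization", repeats = 10L, orientation = "x",
      groups = g(
        group = c("g1", "g2"), n_participants = c(50L, 50L),
        pixel_scale = c(900, 1300),
        angles_deg = list(c(30, 45, 60), c(36, 51, 66)),
        base_lengths = list(
          c(0.1, 0.25, 0.5, 0.75, 1),
          c(0.1, 0.25, 0.5, 0.75, 1)
        )
      )
    ),
    list( # 3
      task = "localization", repeats = 10L, orientation = "y",
      groups = g(
        group = "g1", n_participants = 29L, pixel_scale = 1000,
        angles_deg = list(c(30, 45, 60)),
        base_lengths = list(c(0.1, 0.25, 0.5, 0.75, 1))
      )
    ),
    list( # 4
      task = "angle", repeats = 10L, orientation = "x",
      groups = g(
        group = "g1", n_participants = 65L, pixel_scale = 1000,
        angles_deg = list(c(30, 45, 60)),
        base_lengths = list(c(0.1, 0.25, 0.5, 0.75, 1))
      )
    ),
    list( # 5
      task = "categorical", repeats = 1L, orientation = "x",
      groups = g(
        group = "g1", n_participants = 407L, pixel_scale = 600,
        angles_deg = list(36), base_lengths = list(1)
      )
    )
  )
  design$id <- id
  design$n_participants <- sum(design$groups$n_participants)
  structure(design, class = "tc_experiment_design")
}

#' @export
print.tc_experiment_design <- function(x, ...) {
  cat(sprintf(
    "<tc_experiment_design> experiment %d: %s task, %d participants, %d group(s)\n",
    x$id, x$task, x$n_participants, nrow(x$groups)
  ))
  invisible(x)
}

# all stimulus cells of a design: one row per (group, angle, base length)
design_cells <- function(design) {
  purrr::pmap(design$groups, function(group, n_participants, pixel_scale,
                                      angles_deg, base_lengths) {
    tidyr::expand_grid(
      group = group, base_angle_deg = angles_deg, base_length = base_lengths
    ) |>
      dplyr::mutate(
        pixel_scale = pixel_scale, n_participants = n_participants
      )
  }) |>
    dplyr::bind_rows() |>
    dplyr::mutate(
      side_length = .data$base_length / (2 * cos(deg2rad(.data$base_angle_deg)))
    )
}

# default model parameters for a design: correlation length two times the
# smallest side length shown, the localization/angle noise presets otherwise
default_generator_params <- function(design, generator) {
  cells <- design_cells(design)
  l_min <- min(cells$side_length)
  if (generator == "null") {
    null_params(5)
  } else {
    v0 <- if (design$task == "angle") 0.4 else 0.26
    wlc_params(xi = 2 * l_min, v0 = v0)
  }
}

draw_cell_vertex <- function(generator, spec, wlc, nullp, n) {
  if (generator == "wlc") {
    m <- vertex_moments_core(spec$theta0, wlc$xi, wlc$v0, side_length(spec))
    g <- gamma_from_moments(m$mean_y, m$var_y)
    list(
      x = rnorm(n, 0, sqrt(m$var_x)),
      y = rgamma(n, shape = g$shape, scale = g$scale)
    )
  } else if (generator == "null") {
    s <- sample_vertex_null(spec, nullp, n)
    list(x = s$x, y = s$y)
  } else { # dynamic, matched to the wlc parameters
    dp <- as_dynamic_params(wlc,
      v_p = 1, tau_frac = 0.05,
      eps = 0.05 * wlc$xi, dt_frac = 0.1
    )
    raw <- dyn_ensemble_raw(spec, dp, n, seed = NULL, stop_rule = "gap")
    list(x = raw$x, y = raw$y)
  }
}

#' Generate a synthetic behavioral dataset
#'
#' Draws every trial's response from the chosen generating model for that
#' trial's stimulus, adds isotropic Gaussian motor noise, and attaches a
#' response time increasing with side length (`rt = a + b L + noise`).
#' Deterministic given `seed`; identical seeds give bit-identical tables.
#'
#' @param design An [experiment_design()].
#' @param generator `"wlc"` (statistical model; the default), `"dynamic"`
#'   (correlated-random-walk ensemble, matched parameters), or `"null"`
#'   (straight lines with noisy base angles).
#' @param params Model parameters ([wlc_params()] for `"wlc"`/`"dynamic"`,
#'   [null_params()] for `"null"`). Default: correlation length two times
#'   the smallest side length in the design, noise level 0.26 (0.4 for the
#'   angle task); 5-degree angle noise for the null generator.
#' @param motor_noise_sd Motor noise SD in normalized units. The default is
#'   0: the generators exist to test recovery of each model's scaling
#'   signature, and any motor component comparable to the models' spread at
#'   the smallest stimuli (about 1e-3 normalized units, i.e. 1-2 px)
#'   flattens the small-size end of the curve for *both* generators and
#'   biases the fitted exponents downward. Set a positive value (e.g. 5e-4,
#'   about one pixel) to emulate click noise explicitly.
#' @param rt_a,rt_b,rt_sd Response-time intercept (s), slope per normalized
#'   side length, and noise SD.
#' @param angle_motor_sd_deg Motor noise for slider settings, degrees.
#' @param participant_jitter SD of a per-participant multiplicative
#'   log-normal jitter on the correlation length (default 0 = off;
#'   `"wlc"` generator only).
#' @param seed Optional integer seed.
#' @return A tibble (`tc_response_table`): one row per trial. Localization
#'   tables have columns `participant`, `group`, `trial`, `base_angle_deg`,
#'   `base_length`, `side_length`, `pixel_scale`, `orientation`, `true_x`,
#'   `true_y`, `resp_x`, `resp_y`, `rt`; the angle task replaces the
#'   response columns by `true_angle_deg`, `resp_angle_deg`; the
#'   categorical task has `question`, `answer`, `rt`, `age`, `gender`,
#'   `education_years`.
#' @export
#' @examples
#' tab <- generate_experiment(experiment_design(3), seed = 1)
#' nrow(tab) # 29 participants x 150 trials
generate_experiment <- function(design, generator = c("wlc", "dynamic", "null"),
                                params = NULL, motor_noise_sd = 0,
                                rt_a = 1, rt_b = 2, rt_sd = 0.7,
                                angle_motor_sd_deg = 2,
                                participant_jitter = 0, seed = NULL) {
  if (!inherits(design, "tc_experiment_design")) {
    abort("`design` must be created by `experiment_design()`.")
  }
  generator <- match.arg(generator)
  params <- params %||% default_generator_params(design, generator)
  wlc <- if (generator %in% c("wlc", "dynamic")) {
    stop_if_not_wlc(params)
    params
  } else {
    NULL
  }
  nullp <- if (generator == "null") {
    stop_if_not_null(params)
    params
  } else {
    null_params(5)
  }
  seed <- seed %||% sample.int(.Machine$integer.max, 1L)
  out <- with_seed(seed, {
    if (design$task == "categorical") {
      generate_categorical_trials(design, generator, wlc, nullp)
    } else {
      generate_stimulus_trials(
        design, generator, wlc, nullp, motor_noise_sd,
        rt_a, rt_b, rt_sd, angle_motor_sd_deg, participant_jitter
      )
    }
  })
  class(out) <- c("tc_response_table", class(out))
  attr(out, "design_id") <- design$id
  attr(out, "generator") <- generator
  attr(out, "seed") <- seed
  out
}

generate_stimulus_trials <- function(design, generator, wlc, nullp,
                                     motor_noise_sd, rt_a, rt_b, rt_sd,
                                     angle_motor_sd_deg, participant_jitter) {
  cells <- design_cells(design)
  first_id <- c(0L, cumsum(design$groups$n_participants))
  names(first_id) <- c(design$groups$group, "")
  rows <- purrr::pmap(cells, function(group, base_angle_deg, base_length,
                                      pixel_scale, n_participants, side_length) {
    spec <- triangle_spec(base_length, base_angle_deg,
      orientation = design$orientation, pixel_scale = pixel_scale
    )
    n <- n_participants * design$repeats
    pid <- first_id[[group]] + rep(seq_len(n_participants), each = design$repeats)
    upright <- triangle_spec(base_length, base_angle_deg, orientation = "x")
    if (design$task == "angle") {
      wl <- wlc %||% wlc_params(xi = 1, v0 = 0.4)
      resp <- if (generator == "null") {
        sample_vertex_null(upright, nullp, n)$angle_deg
      } else {
        missing_angle_samples(upright, wl, n = n)$angle_deg
      }
      resp <- resp + rnorm(n, 0, angle_motor_sd_deg)
      tab <- tibble::tibble(
        participant = pid, group = group,
        base_angle_deg = base_angle_deg, base_length = base_length,
        side_length = side_length, pixel_scale = pixel_scale,
        orientation = design$orientation,
        true_angle_deg = 180 - 2 * base_angle_deg,
        resp_angle_deg = resp
      )
    } else {
      v <- if (participant_jitter > 0 && generator == "wlc") {
        mult <- exp(rnorm(n_participants, 0, participant_jitter))
        parts <- purrr::map(seq_len(n_participants), function(i) {
          draw_cell_vertex(
            generator, upright,
            wlc_params(xi = wlc$xi * mult[i], v0 = wlc$v0), nullp,
            design$repeats
          )
        })
        list(
          x = unlist(purrr::map(parts, "x")),
          y = unlist(purrr::map(parts, "y"))
        )
      } else {
        draw_cell_vertex(generator, upright, wlc, nullp, n)
      }
      rx <- v$x + rnorm(n, 0, motor_noise_sd)
      ry <- v$y + rnorm(n, 0, motor_noise_sd)
      p <- orient_xy(spec, rx, ry)
      apex <- true_apex(spec)
      tab <- tibble::tibble(
        participant = pid, group = group,
        base_angle_deg = base_angle_deg, base_length = base_length,
        side_length = side_length, pixel_scale = pixel_scale,
        orientation = design$orientation,
        true_x = apex$x, true_y = apex$y,
        resp_x = p$x, resp_y = p$y
      )
    }
    tab$rt <- pmax(0.2, rt_a + rt_b * side_length + rnorm(n, 0, rt_sd))
    tab
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::arrange(.data$participant, .data$base_angle_deg, .data$base_length)
  out |>
    dplyr::mutate(trial = dplyr::row_number(), .by = "participant") |>
    dplyr::relocate("trial", .after = "group")
}

generate_categorical_trials <- function(design, generator, wlc, nullp) {
  cp <- if (is.null(wlc)) {
    categorical_params("fig3d")
  } else {
    categorical_params("fig3d", xi = wlc$xi, v0 = wlc$v0)
  }
  model <- if (generator == "null") "null" else "wlc"
  pred <- predict_all(cp,
    model = model, null_params = nullp,
    seed = sample.int(.Machine$integer.max, 1L), n_pairs = 2000
  )
  n <- design$n_participants
  qtab <- question_codes()
  demo <- tibble::tibble(
    participant = seq_len(n),
    age = round(pmin(72, 18 + rgamma(n, shape = 2, scale = 7.5))),
    gender = sample(c("female", "male", "unspecified"), n,
      replace = TRUE, prob = c(157, 247, 3) / 407
    ),
    education_years = round(pmin(33, pmax(8, rnorm(n, 15.3, 2.5))))
  )
  rows <- purrr::map(seq_len(nrow(qtab)), function(i) {
    q <- qtab[i, ]
    p <- pred[pred$code == q$code, ]
    labels <- c(q$label_increase, q$label_decrease, "same")
    ans <- sample(labels, n,
      replace = TRUE,
      prob = c(p$p_increase, p$p_decrease, p$p_same)
    )
    rt_mu <- if (q$direction == "I") 18 else 16
    tibble::tibble(
      participant = seq_len(n), group = "g1", question = q$code,
      answer = ans, rt = pmax(1, rnorm(n, rt_mu, 4))
    )
  })
  dplyr::bind_rows(rows) |>
    dplyr::left_join(demo, by = "participant") |>
    dplyr::arrange(.data$participant, .data$question)
}

#' Rescale the coordinate responses of one group
#'
#' Divides the designated group's response coordinates by `factor` — the
#' operation used to put two groups shown at different screen scales on a
#' common footing (e.g. dividing by 13/9).
#'
#' @param table A localization response table.
#' @param factor Positive divisor.
#' @param group Group label to rescale.
#' @return The table with rescaled `resp_x`, `resp_y` for that group.
#' @export
rescale_groups <- function(table, factor, group) {
  if (!all(c("group", "resp_x", "resp_y") %in% names(table))) {
    abort("`table` must have columns `group`, `resp_x`, `resp_y`.")
  }
  check_number(factor, "factor", lower = 0)
  if (!group %in% table$group) abort(sprintf("Group '%s' not present.", group))
  sel <- table$group == group
  table$resp_x[sel] <- table$resp_x[sel] / factor
  table$resp_y[sel] <- table$resp_y[sel] / factor
  table
}

# map responses and targets to the upright frame (base on the x-axis)
upright_deviation <- function(table) {
  dx <- table$resp_x - table$true_x
  dy <- table$resp_y - table$true_y
  rot <- table$orientation == "y"
  # inverse of the +90-degree rotation: (x, y) -> (y, -x)
  tibble::tibble(
    dev_x = ifelse(rot, dy, dx),
    dev_y = ifelse(rot, -dx, dy)
  )
}

#' Per-participant localization statistics
#'
#' For each participant and stimulus cell (base angle x base length):
#' deviations from the true apex in the upright frame, summarized as bias
#' (mean deviation) and spread (SD) per coordinate. Cells with fewer than 2
#' repeats are excluded with a message.
#'
#' @param table A localization response table (see [generate_experiment()]).
#' @return A tibble: `participant`, `group`, `base_angle_deg`,
#'   `base_length`, `side_length`, `n_resp`, `bias_x`, `bias_y`, `sigma_x`,
#'   `sigma_y`.
#' @export
localization_by_participant <- function(table) {
  needed <- c(
    "participant", "group", "base_angle_deg", "base_length",
    "side_length", "orientation", "true_x", "true_y", "resp_x", "resp_y"
  )
  if (!all(needed %in% names(table))) {
    abort(paste0(
      "Localization table must have columns: ",
      toString(setdiff(needed, names(table)))
    ))
  }
  dev <- upright_deviation(table)
  d <- dplyr::bind_cols(
    table[, c(
      "participant", "group", "base_angle_deg", "base_length",
      "side_length"
    )],
    dev
  )
  out <- d |>
    dplyr::summarise(
      n_resp = dplyr::n(),
      bias_x = mean(.data$dev_x), bias_y = mean(.data$dev_y),
      sigma_x = sd(.data$dev_x), sigma_y = sd(.data$dev_y),
      .by = c("participant", "group", "base_angle_deg", "base_length", "side_length")
    )
  few <- out$n_resp < 2L
  if (any(few)) {
    inform(sprintf(
      "localization_by_participant: %d cell(s) with < 2 repeats excluded.",
      sum(few)
    ))
    out <- out[!few, ]
  }
  out
}

#' Across-participant localization summary
#'
#' The two-stage summary used for behavioral results: statistics are first
#' computed per participant ([localization_by_participant()]), then averaged
#' across participants — mean and SD of the per-participant biases and
#' spreads per stimulus cell, exactly in that order.
#'
#' @inheritParams localization_by_participant
#' @return A tibble keyed by `base_angle_deg`, `base_length`, `side_length`
#'   with `n_participants` and mean/SD columns for `bias_x`, `bias_y`,
#'   `sigma_x`, `sigma_y`.
#' @export
summarize_localization <- function(table) {
  localization_by_participant(table) |>
    dplyr::summarise(
      n_participants = dplyr::n_distinct(.data$participant),
      dplyr::across(
        c("bias_x", "bias_y", "sigma_x", "sigma_y"),
        list(mean = mean, sd = sd),
        .names = "{.col}_{.fn}"
      ),
      .by = c("base_angle_deg", "base_length", "side_length")
    ) |>
    dplyr::rename(
      bias_x = "bias_x_mean", bias_y = "bias_y_mean",
      sigma_x = "sigma_x_mean", sigma_y = "sigma_y_mean"
    ) |>
    dplyr::arrange(.data$side_length)
}

#' Write or read a response table
#'
#' Plain-CSV serialization of the trial schema documented in
#' [generate_experiment()]. The reader optionally maps user-supplied column
#' names onto the canonical schema via `col_map` (a named character vector,
#' `canonical = "file_column"`), so deposited files with different headers
#' can be loaded without editing them.
#'
#' @param table A response table.
#' @param path CSV file path.
#' @param col_map Optional named character vector renaming file columns to
#'   canonical names.
#' @return `read_response_table()` returns a tibble;
#'   `write_response_table()` returns `path` invisibly.
#' @export
write_response_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_response_table
#' @export
read_response_table <- function(path, col_map = NULL) {
  d <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  if (!is.null(col_map)) {
    if (is.null(names(col_map)) || any(names(col_map) == "")) {
      abort("`col_map` must be a fully named character vector.")
    }
    missing <- setdiff(unname(col_map), names(d))
    if (length(missing)) {
      abort(paste0("Columns not found in file: ", toString(missing)))
    }
    for (i in seq_along(col_map)) {
      names(d)[names(d) == col_map[[i]]] <- names(col_map)[i]
    }
  }
  d
}
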