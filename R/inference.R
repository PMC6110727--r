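# Inference layer: scaling-exponent estimation with participant bootstrap,
# chi-squared goodness of fit for categorical predictions, and the
# Bayes-factor comparison between the worm-like-chain model and the
# straight-line noisy-angle null.

#' Fit the scaling exponent sigma ~ L^n with a participant bootstrap
#'
#' Expects one spread value per participant and side length. The point
#' estimate averages `sigma` across participants per `L` and fits an
#' ordinary least-squares line to (log L, log sigma). Uncertainty comes from
#' resampling participants with replacement (the participant is the
#' bootstrap unit): per bootstrap, per-L means are recomputed and the line
#' refit; the median exponent and a 95% percentile interval are reported.
#'
#' @param data A data frame with columns `participant`, `L`, `sigma`
#'   (names configurable). Non-positive `sigma` entries are rejected.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Optional integer seed.
#' @param participant_col,l_col,sigma_col Column names.
#' @return An object of class `tc_scaling_fit` with elements `exponent`,
#'   `intercept`, `r_squared`, `median_exponent`, `ci` (length-2), `boot`
#'   (bootstrap exponents), `n_boot`, `n_participants`. Supports
#'   [generics::tidy()], [generics::glance()] and [ggplot2::autoplot()].
#' @export
#' @examples
#' d <- tidyr::expand_grid(participant = 1:8, L = c(1, 2, 4, 8, 16))
#' d$sigma <- 0.3 * d$L^0.77
#' glance(fit_scaling_exponent(d, n_boot = 50, seed = 1))
fit_scaling_exponent <- function(data, n_boot = 1000, seed = NULL,
                                 participant_col = "participant",
                                 l_col = "L", sigma_col = "sigma") {
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  for (col in c(participant_col, l_col, sigma_col)) {
    if (!col %in% names(data)) abort(sprintf("Column `%s` not found.", col))
  }
  n_boot <- check_count(n_boot, "n_boot", min = 1L)
  d <- tibble::tibble(
    participant = data[[participant_col]],
    L = as.double(data[[l_col]]),
    sigma = as.double(data[[sigma_col]])
  )
  d <- d[complete.cases(d), ]
  if (any(d$sigma <= 0)) abort("All `sigma` values must be positive.")
  if (dplyr::n_distinct(d$L) < 3L) abort("Need at least 3 distinct side lengths.")
  # participant x L matrix of log-sigma (averaging duplicates)
  agg <- d |>
    dplyr::summarise(sigma = mean(.data$sigma), .by = c("participant", "L")) |>
    tidyr::pivot_wider(names_from = "L", values_from = "sigma")
  mat <- as.matrix(agg[, -1L, drop = FALSE])
  Ls <- as.double(colnames(mat))
  ord <- order(Ls)
  mat <- mat[, ord, drop = FALSE]
  logL <- log(Ls[ord])

  slope_of <- function(rows) {
    sig <- colMeans(mat[rows, , drop = FALSE], na.rm = TRUE)
    ls <- log(sig)
    ok <- is.finite(ls)
    x <- logL[ok]
    y <- ls[ok]
    sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  }
  n_part <- nrow(mat)
  ybar <- log(colMeans(mat, na.rm = TRUE))
  full <- lm(ybar ~ logL)
  rss <- sum(residuals(full)^2)
  tss <- sum((ybar - mean(ybar))^2)
  boots <- with_seed(
    seed %||% sample.int(.Machine$integer.max, 1L),
    vapply(
      seq_len(n_boot),
      function(i) slope_of(sample.int(n_part, n_part, replace = TRUE)),
      numeric(1L)
    )
  )
  structure(
    list(
      exponent = unname(coef(full)[2L]),
      intercept = unname(coef(full)[1L]) / log(10),
      r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
      median_exponent = median(boots),
      ci = unname(quantile(boots, c(0.025, 0.975))),
      boot = boots,
      n_boot = n_boot,
      n_participants = n_part,
      L_values = Ls[ord]
    ),
    class = "tc_scaling_fit"
  )
}

#' @export
print.tc_scaling_fit <- function(x, ...) {
  cat(sprintf(
    "<tc_scaling_fit> exponent %.3f (median %.3f, 95%% CI [%.3f, %.3f], %d bootstraps, %d participants)\n",
    x$exponent, x$median_exponent, x$ci[1L], x$ci[2L], x$n_boot, x$n_participants
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.tc_scaling_fit <- function(x, ...) {
  tibble::tibble(
    term = c("exponent", "intercept"),
    estimate = c(x$exponent, x$intercept),
    conf.low = c(x$ci[1L], NA_real_),
    conf.high = c(x$ci[2L], NA_real_)
  )
}

#' @export
glance.tc_scaling_fit <- function(x, ...) {
  tibble::tibble(
    exponent = x$exponent,
    median_exponent = x$median_exponent,
    ci_low = x$ci[1L], ci_high = x$ci[2L],
    r_squared = x$r_squared,
    n_boot = x$n_boot, n_participants = x$n_participants
  )
}

#' Chi-squared goodness of fit of model proportions to observed counts
#'
#' Pearson statistic `sum((O - E)^2 / E)` with `E = N p`. Cells with zero
#' expected probability are merged into the largest-probability cell (with a
#' message). `df_mode = "k_minus_1"` uses `k - 1` degrees of freedom for the
#' `k` (post-merge) categories; `df_mode = "one"` collapses the table to a
#' designated category versus the rest (1 df), a compatibility mode for
#' analyses that report 1-df tests on three-way responses.
#'
#' @param model_proportions Probability vector (sums to 1).
#' @param observed_counts Nonnegative integer counts, same length.
#' @param df_mode `"k_minus_1"` (default) or `"one"`.
#' @param collapse_to Index of the category kept separate in `"one"` mode
#'   (default: the model's modal category).
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `n`.
#' @export
#' @examples
#' chisq_gof(c(0.5, 0.5), c(12, 8)) # statistic 0.8
chisq_gof <- function(model_proportions, observed_counts,
                      df_mode = c("k_minus_1", "one"), collapse_to = NULL) {
  df_mode <- match.arg(df_mode)
  p <- as.double(model_proportions)
  o <- as.double(observed_counts)
  if (length(p) != length(o)) abort("Proportions and counts must have equal length.")
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8) abort("`model_proportions` must sum to 1.")
  if (any(o < 0) || any(o != round(o))) abort("`observed_counts` must be nonnegative integers.")
  n <- sum(o)
  if (n <= 0) abort("`observed_counts` must sum to a positive total.")
  if (df_mode == "one") {
    keep <- collapse_to %||% which.max(p)
    p <- c(p[keep], sum(p[-keep]))
    o <- c(o[keep], sum(o[-keep]))
  }
  if (any(p == 0)) {
    into <- which.max(p)
    drop <- which(p == 0)
    o[into] <- o[into] + sum(o[drop])
    p <- p[-drop]
    o <- o[-drop]
    inform(sprintf("chisq_gof: %d zero-expectation cell(s) merged.", length(drop)))
  }
  e <- n * p
  stat <- sum((o - e)^2 / e)
  df <- length(p) - 1L
  tibble::tibble(
    statistic = stat, df = df,
    p_value = pchisq(stat, df, lower.tail = FALSE), n = n
  )
}

#' Bayes factor comparing two categorical models
#'
#' `BF = prod_i (p_model_i / p_null_i)^(n_i)`, computed in log space, for
#' observed category counts `n`. A category with nonzero count but zero
#' probability under one model yields an infinite or zero Bayes factor,
#' returned with an overflow flag rather than an error.
#'
#' @param p_model,p_null Probability vectors of equal length (each sums
#'   to 1).
#' @param counts Nonnegative integer counts, same length.
#' @return A one-row tibble: `bf`, `log10_bf`, `overflow` (`"none"`,
#'   `"+inf"`, `"-inf"`, or `"indeterminate"`).
#' @export
#' @examples
#' bayes_factor(c(0.5, 0.3, 0.2), c(0.25, 0.5, 0.25), c(10, 5, 5)) # ~26.1
bayes_factor <- function(p_model, p_null, counts) {
  pm <- as.double(p_model)
  pn <- as.double(p_null)
  n <- as.double(counts)
  if (length(pm) != length(pn) || length(pm) != length(n)) {
    abort("`p_model`, `p_null` and `counts` must have equal length.")
  }
  for (v in list(pm, pn)) {
    if (any(v < 0) || abs(sum(v) - 1) > 1e-8) {
      abort("Model probabilities must be nonnegative and sum to 1.")
    }
  }
  if (any(n < 0) || any(n != round(n))) {
    abort("`counts` must be nonnegative integers.")
  }
  act <- n > 0
  zm <- act & pm == 0
  zn <- act & pn == 0
  overflow <- "none"
  if (any(zm & zn)) {
    overflow <- "indeterminate"
    log_bf <- NaN
  } else if (any(zm)) {
    overflow <- "-inf"
    log_bf <- -Inf
  } else if (any(zn)) {
    overflow <- "+inf"
    log_bf <- Inf
  } else {
    log_bf <- sum(n[act] * (log(pm[act]) - log(pn[act])))
  }
  tibble::tibble(
    bf = exp(log_bf), log10_bf = log_bf / log(10), overflow = overflow
  )
}

#' Classify paired estimates by relative change
#'
#' The same rule the categorical model applies to its own samples, exposed
#' for behavioral tables: relative change `r = (after - init) / init`,
#' `r > threshold` is `"increase"`, `r < -threshold` is `"decrease"`, and
#' the closed interval in between is `"same"`.
#'
#' @param data A data frame holding initial and follow-up estimates.
#' @param threshold Relative-change cutoff (default 0.05, > 0).
#' @param init_col,after_col Column names.
#' @return `data` with columns `relative_change` and `category` appended.
#' @export
#' @examples
#' apply_categorical_thresholds(
#'   tibble::tibble(init = c(1, 1, 1), after = c(1.06, 0.95, 1.01))
#' )
apply_categorical_thresholds <- function(data, threshold = 0.05,
                                         init_col = "init", after_col = "after") {
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  check_number(threshold, "threshold", lower = 0)
  for (col in c(init_col, after_col)) {
    if (!col %in% names(data)) abort(sprintf("Column `%s` not found.", col))
  }
  init <- as.double(data[[init_col]])
  if (any(init == 0)) abort("Initial values must be nonzero.")
  r <- (as.double(data[[after_col]]) - init) / init
  data$relative_change <- r
  data$category <- classify_relative(init, as.double(data[[after_col]]), threshold)
  data
}

#' Median coefficient of variation across response groups
#'
#' The statistic used to set the categorical threshold: per group, the
#' coefficient of variation (sd / mean) of the responses; the median is
#' taken across groups.
#'
#' @param data A data frame.
#' @param value_col Response column name.
#' @param group_cols Character vector of grouping columns.
#' @return A single number.
#' @export
median_response_cv <- function(data, value_col, group_cols) {
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  cv <- data |>
    dplyr::summarise(
      cv = sd(.data[[value_col]]) / mean(.data[[value_col]]),
      .by = dplyr::all_of(group_cols)
    )
  median(cv$cv, na.rm = TRUE)
}
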