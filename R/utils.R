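# Internal helpers: angle units, argument checks, seed substreams.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         closed_lower = FALSE, closed_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  lo_ok <- if (closed_lower) x >= lower else x > lower
  hi_ok <- if (closed_upper) x <= upper else x < upper
  if (!lo_ok || !hi_ok) {
    abort(sprintf(
      "`%s` must lie in %s%g, %g%s (got %g).", name,
      if (closed_lower) "[" else "(", lower, upper,
      if (closed_upper) "]" else ")", x
    ))
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != round(x) || x < min) {
    abort(sprintf("`%s` must be an integer >= %d.", name, min))
  }
  as.integer(x)
}

#' Derive a reproducible substream seed
#'
#' Counter-based splitting of a master seed into per-stage seeds, so that
#' adding a stage never perturbs the draws of earlier stages. The result is
#' always a valid 32-bit integer seed.
#'
#' @param seed Master seed (integer).
#' @param counter Stage counter (integer; stages should use distinct values).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' substream_seed(1, 1)
#' substream_seed(1, 2)
substream_seed <- function(seed, counter) {
  seed <- check_count(seed, "seed", min = 0L)
  counter <- check_count(counter, "counter", min = 0L)
  m <- 2147483646
  # multipliers small enough that the product is exact in double precision
  as.integer(((seed %% m) * 69069 + (counter %% m) * 12345 + 1) %% m + 1)
}

# Evaluate `expr` under a given seed without touching the caller's RNG state.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}
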