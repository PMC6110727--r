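# Parameters of the worm-like-chain (WLC) statistical model.
#
# The angular process phi(s) along the extrapolated line is penalized by a
# curvature term with weight l_p (persistence length) and by deviations from
# the remembered base angle with weight f (global error correction). The two
# combine into a correlation length xi = sqrt(l_p / f) and an angle noise
# level V0 = (l_p * f)^(-1/2); the stationary angular variance is V0 / 2.

#' Parameters of the worm-like-chain angular process
#'
#' Supply either the mechanistic pair (`l_p`, `f`) or the reduced pair
#' (`xi`, `v0`); the other pair is derived exactly
#' (`xi = sqrt(l_p/f)`, `v0 = (l_p f)^(-1/2)`, inverted as `l_p = xi/v0`,
#' `f = 1/(xi v0)`).
#'
#' @param l_p Persistence length (> 0); penalizes local curvature.
#' @param f Global-correction weight (> 0); penalizes deviations from the
#'   base angle.
#' @param xi Correlation length (> 0), in the same length units as the
#'   triangle side length.
#' @param v0 Angle noise level (> 0); the stationary variance of the local
#'   angle is `v0/2` (radians squared).
#' @return An object of class `tc_wlc_params` carrying all four quantities.
#' @export
#' @examples
#' wlc_params(xi = 2, v0 = 0.26)
#' wlc_params(l_p = 4, f = 1)
wlc_params <- function(l_p = NULL, f = NULL, xi = NULL, v0 = NULL) {
  has_lf <- !is.null(l_p) && !is.null(f)
  has_xv <- !is.null(xi) && !is.null(v0)
  if (has_lf == has_xv) {
    abort("Supply exactly one pair: (`l_p`, `f`) or (`xi`, `v0`).")
  }
  if (has_lf) {
    check_number(l_p, "l_p", lower = 0)
    check_number(f, "f", lower = 0)
    xi <- sqrt(l_p / f)
    v0 <- 1 / sqrt(l_p * f)
  } else {
    check_number(xi, "xi", lower = 0)
    check_number(v0, "v0", lower = 0)
    l_p <- xi / v0
    f <- 1 / (xi * v0)
  }
  structure(
    list(l_p = l_p, f = f, xi = xi, v0 = v0),
    class = "tc_wlc_params"
  )
}

#' @export
print.tc_wlc_params <- function(x, ...) {
  cat(sprintf(
    "<tc_wlc_params> xi = %g, v0 = %g  (l_p = %g, f = %g)\n",
    x$xi, x$v0, x$l_p, x$f
  ))
  invisible(x)
}

is_wlc_params <- function(x) inherits(x, "tc_wlc_params")

stop_if_not_wlc <- function(params) {
  if (!is_wlc_params(params)) abort("`params` must be created by `wlc_params()`.")
  invisible(params)
}

#' Named parameter presets
#'
#' The parameter sets used throughout the package's replication analyses:
#' `"fig2"` (xi = 2, v0 = 0.26) for the localization scaling curve,
#' `"angles"` (xi = 2, v0 = 0.4) for missing-angle predictions, and the two
#' categorical-task presets `"fig3d"` and `"methods"` (see
#' [categorical_params()]).
#'
#' @param name Preset name.
#' @return A `tc_wlc_params` object.
#' @export
#' @examples
#' wlc_preset("fig2")
wlc_preset <- function(name = c("fig2", "angles", "fig3d", "methods")) {
  name <- match.arg(name)
  switch(name,
    fig2 = wlc_params(xi = 2, v0 = 0.26),
    angles = wlc_params(xi = 2, v0 = 0.4),
    fig3d = wlc_params(xi = 2, v0 = 0.4),
    methods = wlc_params(xi = 1.25, v0 = 0.5)
  )
}
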