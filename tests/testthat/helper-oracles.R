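# Shared oracles and small utilities for the test suite.

log_spaced <- function(lo, hi, n) exp(seq(log(lo), log(hi), length.out = n))

# Closed-form solution of the noise-free heading dynamics
#   tau theta'' + theta' + (theta - theta0)/xi_t = 0,
# theta(0) = theta0 + delta, theta'(0) = 0. Overdamped iff xi_t > 4 tau.
osc_relaxation <- function(t, theta0, delta, tau, xi_t) {
  disc <- 1 - 4 * tau / xi_t
  if (disc > 0) {
    l1 <- (-1 + sqrt(disc)) / (2 * tau)
    l2 <- (-1 - sqrt(disc)) / (2 * tau)
    c1 <- l2 / (l2 - l1)
    c2 <- -l1 / (l2 - l1)
    theta0 + delta * (c1 * exp(l1 * t) + c2 * exp(l2 * t))
  } else {
    om <- sqrt(-disc) / (2 * tau)
    g <- 1 / (2 * tau)
    theta0 + delta * exp(-g * t) * (cos(om * t) + g / om * sin(om * t))
  }
}

# Brute-force pooled localization statistics for a single participant,
# ignoring the per-participant/across-participant split (they coincide for
# one participant).
pooled_localization <- function(tab) {
  stopifnot(length(unique(tab$participant)) == 1L)
  dx <- tab$resp_x - tab$true_x
  dy <- tab$resp_y - tab$true_y
  if (any(tab$orientation == "y")) {
    tmp <- dx
    dx <- dy
    dy <- -tmp
  }
  out <- data.frame(
    cell = paste(tab$base_angle_deg, tab$base_length),
    dx = dx, dy = dy
  )
  agg <- do.call(rbind, lapply(split(out, out$cell), function(d) {
    data.frame(
      cell = d$cell[1], bias_x = mean(d$dx), bias_y = mean(d$dy),
      sigma_x = sd(d$dx), sigma_y = sd(d$dy)
    )
  }))
  agg[order(agg$cell), ]
}
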