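---
title: "Modelling triangle completion: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling triangle completion: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tricomp)
```

This vignette explains the models implemented in `tricomp`, the assumptions
behind them, and the design choices we made where the modelling problem was
genuinely open. Everything quantitative stated here is computed by the
package's test suite or by the code shown.

## The task and the coordinate conventions

A fragmented isosceles triangle is specified by its base length $b$, base
angle $\theta_0 \in (0, \pi/2)$, an orientation (base on the horizontal or,
for the rotated presentation, the vertical axis), and a pixel scale. We
place the base corners at $(\pm b/2, 0)$ and the true apex in the upper
half-plane at height $L \sin\theta_0$, where $L = b / (2\cos\theta_0)$ is
the side length — the canonical size variable throughout, because bias and
spread of human apex estimates track the *side* length rather than base
length or angle separately. With this convention "bias toward the base" is
a signed negative vertical deviation. Angles are stored in radians
internally and exposed in degrees at every interface. Degenerate stimuli
($\theta_0 \le 0$ or $\ge 90^\circ$, non-positive lengths) are rejected at
construction.

## The statistical (worm-like-chain) model

The local heading $\varphi(s)$ of an extrapolated side, parameterized by
arc length $s \in [0, L]$, is drawn from the Gaussian law
$P[\varphi] \propto e^{-E}$ with

$$E = \tfrac12 \int_0^L \left[ l_p \left(\tfrac{d\varphi}{ds}\right)^2
      + f\,(\varphi - \theta_0)^2 \right] ds .$$

The curvature penalty $l_p$ (persistence length) enforces local
smoothness; the restoring weight $f$ implements a global error correction
toward the remembered base angle. Two reduced parameters govern everything:
the correlation length $\xi = \sqrt{l_p/f}$ and the angle noise level
$V_0 = (l_p f)^{-1/2}$ (stationary heading variance $V_0/2$). The
parameterizations are interconvertible exactly (`wlc_params()` accepts
either pair and round-trips to machine precision).

**Boundary condition (open choice).** The energy functional does not fix
$\varphi(0)$. We adopt the *pinned* reading — an Ornstein–Uhlenbeck process
started at $\varphi(0) = \theta_0$, so
$\mathrm{Var}\,\varphi(s) = (V_0/2)(1 - e^{-2s/\xi})$ — because the walker
starts at a visible corner whose angle it has just inspected. A
stationary-start mode (`pinned = FALSE`) is provided for sensitivity
checks; it changes the short-range transient only, and the long-range law
(bias slope, scaling exponent) is unaffected.

**Endpoint moments.** With $x = \int_0^L \cos\varphi\,ds$,
$y = \int_0^L \sin\varphi\,ds$, all first and second moments reduce to
Gaussian characteristic-function identities, e.g.
$\mathbb{E}[y] = \sin\theta_0 \int_0^L e^{-V(s)/2}\,ds$, and double
integrals of $\exp[-(V(s) + V(s') \mp 2C(s,s'))/2]$ for the second
moments. `endpoint_moments()` evaluates them with Gauss–Legendre
quadrature: one-dimensional for the means, and a nested rule over the
triangle $s < s'$ (where the integrand is smooth — the $|s - s'|$ kink
lies on the boundary) for the second moments. Node counts scale with
$L/\xi$ (capped at 480); a refinement check warns if the variance has not
converged to $10^{-6}$ relative. The apex estimate is the average of two
mirrored, independent side endpoints, which leaves the bias unchanged and
halves both variances.

Two closed forms anchor the implementation and are asserted in the tests:
the asymptotic bias slope
$\delta(L)/L \to \sin\theta_0\,(e^{-V_0/4} - 1) < 0$ (linear-in-$L$
downward bias), and the crossover of the spread from
$\sigma_y \sim L^{3/2}$ (persistence-dominated, $L \ll \xi$) to
$\sigma_y \sim L^{1/2}$ (error-correction-dominated, $L \gg \xi$). Over a
100-fold range of $L$ with $\xi = 2$, $V_0 = 0.26$, $\theta_0 = 36^\circ$,
the globally fitted exponent is 0.77 — sub-linear, between the two regimes:

```{r scaling}
curve <- scaling_curve(wlc_params(xi = 2, v0 = 0.26), 36,
                       exp(seq(log(1), log(100), length.out = 15)))
fit_power_law(curve$L, curve$sigma_y)
```

Path sampling (`sample_path()`, `sample_endpoints()`) uses the exact
one-step OU transition, so the only discretization error is in the
trapezoid quadrature of $\cos\varphi, \sin\varphi$ along the path; the
analytic and Monte-Carlo routes are cross-checked against each other in
the test suite at matched problem sizes (e.g. $4\times10^4$ paths at
$L = 20$).

## The dynamic model and its relation to the statistical one

The time-domain model integrates, per side,

$$\ddot\theta = \frac{1}{\tau}\left[\frac{\theta_0 - \theta}{\xi_t}
  - \dot\theta\right] + \eta(t), \qquad
  \dot x = v_p\cos\theta,\quad \dot y = v_p\sin\theta,$$

with white noise $\langle\eta(t)\eta(t')\rangle = D\,\delta(t-t')$.
Euler–Maruyama is used with per-step innovations
$\mathcal N(0, D/dt)$; the default step is $dt = 0.01\,\min(\tau,\xi_t)$
and steps $\ge \tau$ are rejected. Initial conditions are
$\theta(0) = \theta_0$, $\dot\theta(0) = 0$ (the walker starts aligned
with the perceived base angle); the right side is simulated in a mirrored
frame and reflected, so the left/right laws are symmetric by construction.
The stationary heading variance is $D\tau^2\xi_t/2$ (asserted against
long simulations), and in the overdamped regime $\tau \ll \xi_t$ the
heading is an OU process in time, matching the statistical model with
correlation length $v_p\,\xi_t$ and $V_0 = D\tau^2\xi_t$.
`as_dynamic_params()` performs this matching (default $\tau = 0.01\,\xi_t$,
which keeps inertial distortions of the endpoint moments at the percent
level or below).

**Stopping rule (the most consequential open choice).** The completion
process runs both tips on a shared clock and, in the `"gap"` rule, ends
when the horizontal tip distance first drops below a threshold
$\varepsilon$, with the apex estimate taken as the tip midpoint (an
"intersect the last headings" variant is available via
`vertex_rule = "crossing"`). Linearizing the dynamics shows — and our
simulations confirm — that this construction *reshapes* the endpoint law
relative to fixed-length extrapolation:

- the vertical estimate becomes
  $Y \approx \tfrac{(b-\varepsilon)}{2}\tan\theta_0 + S/(2\cos\theta_0)$
  with $S$ the summed zero-mean heading-integral fluctuation, so the
  downward bias is *cancelled* to leading order (only the
  $O(\varepsilon)$ geometric shortfall remains);
- $\mathrm{Var}(Y)$ is inflated by $1/\cos^4\theta_0$ (a factor 2.3 at
  $36^\circ$) because slow horizontal progress extends the stopping time
  and feeds horizontal fluctuations into the vertical coordinate, while
  $\mathrm{Var}(X)$ is unchanged.

Consequently the gap-stopped ensemble cannot agree moment-for-moment with
the fixed-length statistical model, although the *scaling exponent* of
$\sigma_y(L)$ is unaffected (the distortion is a constant factor). The
construction under which the two formulations describe the same endpoint
law — and under which we verify their agreement to within Monte-Carlo
error — is the `"fixed_arc"` rule: each side extrapolates exactly one side
length and the mirrored endpoints are averaged. Both rules are
implemented; `complete_triangle()` and `ensemble_moments()` default to
`"gap"` (the mechanistic reading of a completion process that ends when
the lines meet), and the equivalence checks use `"fixed_arc"`. A unit test
pins the gap-rule variance inflation at $\approx \sec^2\theta_0$ in
$\sigma_y$ so that this behavior is documented executable knowledge, not
folklore.

## Missing-angle predictions

The apex-estimate distribution is summarized by a Gamma law for the
vertical coordinate, moment-matched to the analytic mean and variance
(shape $m^2/v$, scale $v/m$ — exact by construction), and a centered
Gaussian for the horizontal coordinate with the model's post-averaging
spread (the per-side vs post-averaging choice is not fixed by the
construction; we draw post-averaging). Each sampled apex $(X, Y)$ defines
effective base angles at the fixed corners,
$\alpha_{L,R} = \mathrm{atan2}(Y,\, b/2 \pm X)$, and the missing angle
$\pi - \alpha_L - \alpha_R$; the $\pi$-sum identity holds exactly per
sample. Draws with $Y \le 0$ are rejected and resampled (counted and
reported) rather than truncated, preserving the Gamma moments to good
approximation while keeping the geometry valid.

A structural feature worth knowing: the predicted angular SD is
*non-monotone* in $L$. It rises while $L \lesssim 3\xi$ (the
persistence-dominated regime, where $\sigma_y$ grows faster than $L$) and
falls beyond. The monotone predictions — mean missing angle overestimated
and increasing, SD decreasing — therefore concern the error-correction
regime, and the package's default prediction grid spans
$L \in [6, 100]$ at $\xi = 2$ ($L/\xi \in [3, 50]$), ten log-spaced
points, with $V_0 = 0.4$ for angle tasks. Within that regime the mean
rises by roughly $1^\circ$–$2^\circ$ and the SD falls severalfold; at
$V_0 = 0.4$ the overestimation at $\theta_0 = 45^\circ$ is about
$5^\circ$ above the Euclidean $90^\circ$.

## Categorical predictions

Eight questions ask what happens to the missing vertex location (V) or
angle (A) when the base angles (A) or the base distance (D) increase (I)
or decrease (D). The model samples the judged quantity independently under
the initial and the manipulated stimulus (no common random numbers — the
two imagined triangles are separate simulations), pairs draws by index,
and classifies the relative change $r$ with strict thresholds:
$r > 0.05$ "increase", $r < -0.05$ "decrease", the closed interval
between "same". The `"same"` proportion is provably nondecreasing in the
threshold, which the tests assert.

Two published parameter sets are shipped as presets and deliberately kept
distinct rather than reconciled: `"fig3d"` ($\xi = 2$, $V_0 = 0.4$,
thresholds 0.05, initial base angle $36^\circ$) and `"methods"`
($\xi = 1.25$, $V_0 = 0.5$, initial side lengths 3.2/1.25, angle
manipulation $36^\circ \to 45^\circ$, distance factors 1.25/1.5). Where
the sources leave the manipulation sizes open we chose: initial side
length 2 with distance factors $\times 2$ / $\times\tfrac12$ for
`"fig3d"` (side lengths spanning 2–4), angle manipulations
$36^\circ \to 45^\circ$ / $36^\circ \to 27^\circ$, and reciprocal factors
for decreases throughout (a scale-symmetric manipulation). Under these
settings the model's modal answers are Euclidean-correct for all four
location questions and for the angle-of-angle questions, while for the
angle-of-distance questions (AID/ADD) the modal answer follows the
manipulation direction ("bigger" when the triangle grows) with a narrow
margin over the opposite answer — the model's signature departure from
scale-invariant reasoning, and the question family on which observed
behavior is near chance.

The straight-line null model answers the same questions via noisy-angle
ray intersections; its angle distribution is size-invariant, so it
predicts "same" for AID/ADD — which is what makes the Bayes-factor
comparison on those questions informative in the other direction.

## The null model

Straight rays from the base corners with i.i.d. Gaussian base-angle noise
(default SD $5^\circ$). Having no internal length scale, its apex spread
is *exactly* proportional to $L$ (fitted slope $1.00$, asserted at
$\pm 0.02$), and its missing-angle samples are independent of size. One
analytic subtlety we found and encode in the tests: the second-order mean
vertical bias vanishes identically at $\theta_0 = 45^\circ$ (the convexity
of $\tan$ cancels the concavity of the intersection formula), is downward
for $\theta_0 < 45^\circ$, and upward above. Near-parallel draws
($\tan\theta_L + \tan\theta_R \le 10^{-6}$) are resampled with a logged
count rather than clipped.

## Inference layer

`fit_scaling_exponent()` fits $\log\sigma$ on $\log L$ by OLS after
averaging per-participant spreads per length, and bootstraps *participants*
(1000 resamples by default) for the median exponent and a 95% percentile
interval. `chisq_gof()` uses the Pearson statistic with $k-1$ degrees of
freedom after merging zero-expectation cells; a 1-df compatibility mode
(collapse to a designated category versus the rest) is provided because
published analyses of three-way responses sometimes report 1-df tests.
`bayes_factor()` computes
$\prod_i (p^{\mathrm{model}}_i / p^{\mathrm{null}}_i)^{n_i}$ in log space,
returning signed overflow flags instead of errors when a nonzero count
meets a zero probability; multiplicativity over count splits is exact.

## The synthetic-data generators

`experiment_design(1..5)` encodes the five behavioral designs exactly
(40 participants × 15 triangles × 10 repeats for the in-lab localization
experiment, 1 unit ≡ 1900 px, and so on through the rotated, angle-task
and categorical designs). `generate_experiment()` draws every trial from
the chosen generating model — moment-matched Gamma/Gaussian sampling for
the statistical model, ray intersections for the null, the compiled
ensemble for the dynamic model — with the correlation length defaulting to
twice the smallest side length in the design. Response times follow
$a + bL + \text{noise}$ with a positive slope, reproducing a positive
size–time association (Spearman $r \approx 0.5$ on the localization
design).

**Motor noise default.** The generator accepts isotropic Gaussian motor
noise but defaults to zero. The null model's spread at the smallest
stimulus of the in-lab design is $\sim 8\times10^{-4}$ normalized units
($\approx 1.5$ px), so motor noise at any realistic click precision
dominates the small end of the scaling curve, flattens it for *both*
generators, and destroys the property the generators exist to support —
that statistical-model data yield a bootstrap exponent interval excluding
1 while null data yield one containing it. With the defaults that
discrimination succeeds in 18 of 20 replications; the two failures trace
to a genuine design feature (fitting one power law across cells that mix
base angles biases the null slope slightly upward, since
$\sigma_y = L\,g(\theta_0)\,\sigma_\alpha$ and $g(\theta_0)$ covaries with
$L$ in the design).

What the generators deliberately do **not** emulate: individual
differences beyond an optional per-participant jitter of the correlation
length, learning or fatigue across trials, anisotropic or
stimulus-dependent motor error, lapses, and the slider mechanics of the
angle task. Passing recovery tests on synthetic data therefore shows the
pipeline is correct and the designs are informative — not that real
behavior follows the model.

## Numerical choices, reproducibility, problem sizes

- Quadrature: Gauss–Legendre, nodes $\propto L/\xi$ capped at 480,
  convergence warned at $10^{-6}$ relative on the variance.
- SDE integration: Euler–Maruyama, $dt = 0.01\,\min(\tau, \xi_t)$ default
  ($0.02\,\tau$ in matched-parameter comparisons), non-finite states abort
  with a diagnostic, time-capped completions are flagged `max_time` and
  excluded from moments with a logged count, never silently.
- Randomness: every sampling function takes a `seed` and runs under
  `withr::with_seed`, leaving the caller's RNG untouched; multi-stage
  analyses derive per-stage substreams with a counter-based splitter
  (`substream_seed()`), so adding a stage never perturbs earlier draws.
  Identical seeds give bit-identical outputs, including whole synthetic
  datasets and `run_replication()` artifact files.
- Test-suite problem sizes were chosen to keep the full suite around two
  minutes on one core while leaving Monte-Carlo tolerances honest:
  $2$–$4\times10^4$ paths for analytic-vs-sampling checks, $10^4$
  replicates per point for the dynamic–statistical comparisons, 20
  end-to-end recovery replications, $2$–$3\times10^4$ draws where modal or
  monotonicity claims are asserted.

## Known limitations

- The gap-rule/fixed-length discrepancy described above means raw moments
  of the default completion process differ from the analytic statistical
  moments by known factors; analyses that need the analytic law should use
  the fixed-arc construction or the statistical model directly.
- The angular-SD non-monotonicity confines the "variance decreases with
  size" prediction to $L \gtrsim 3\xi$.
- Noise is Gaussian and orientation-independent by construction; heavy
  tails, angle-dependent noise, or degradation of the remembered base
  angle over the course of extrapolation are outside the model family.
- The categorical predictor inherits the ambiguity of the published
  manipulation sizes; both presets are available and neither is endorsed.
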