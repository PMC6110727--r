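#include <Rcpp.h>
using namespace Rcpp;

// Euler-Maruyama ensemble of paired line extrapolations.
//
// Each replicate runs two independent trajectories (left and right, the
// right one simulated in a mirrored frame) with shared clock:
//   theta'' = (1/tau) * ((theta0 - theta)/xi_t - theta') + eta(t),
//   x' = vp cos(theta), y' = vp sin(theta),
// eta discretized as N(0, D/dt) per step. Positions advance with the
// pre-step angle; then theta and theta' are updated.
//
// gap_stop = true : stop when the tips' x-distance (base - xL - xR) first
//                   drops below eps; replicates that never cross within
//                   max_steps are flagged (stopped = 0).
// gap_stop = false: stop after round(arc_time / dt) steps (fixed arc length).
//
// Uses R's RNG, so results are reproducible under set.seed(); draw order is
// left then right within each step, replicates sequential.
// [[Rcpp::export]]
DataFrame tc_dyn_ensemble_cpp(double theta0, double base, double eps,
                              double tau, double xi_t, double vp, double D,
                              double dt, int max_steps, int n_rep,
                              bool gap_stop, double arc_time) {
  NumericVector X(n_rep), Y(n_rep), t_stop(n_rep);
  NumericVector thL_out(n_rep), thR_out(n_rep);
  NumericVector xLo(n_rep), yLo(n_rep), xRo(n_rep), yRo(n_rep);
  IntegerVector stopped(n_rep);
  const double sd_eta = std::sqrt(D / dt);
  const int n_fixed = gap_stop ? max_steps : (int)std::lround(arc_time / dt);

  for (int r = 0; r < n_rep; ++r) {
    double thl = theta0, wl = 0.0, xl = 0.0, yl = 0.0;
    double thr = theta0, wr = 0.0, xr = 0.0, yr = 0.0;
    int k = 0;
    bool hit = false;
    const int limit = gap_stop ? max_steps : n_fixed;
    while (k < limit) {
      double al = ((theta0 - thl) / xi_t - wl) / tau + R::rnorm(0.0, sd_eta);
      double ar = ((theta0 - thr) / xi_t - wr) / tau + R::rnorm(0.0, sd_eta);
      xl += vp * std::cos(thl) * dt;
      yl += vp * std::sin(thl) * dt;
      xr += vp * std::cos(thr) * dt;
      yr += vp * std::sin(thr) * dt;
      thl += wl * dt;
      wl += al * dt;
      thr += wr * dt;
      wr += ar * dt;
      ++k;
      if (!std::isfinite(thl) || !std::isfinite(thr)) break;
      if (gap_stop && std::fabs(base - xl - xr) < eps) {
        hit = true;
        break;
      }
    }
    if (!gap_stop) hit = (k == n_fixed);
    stopped[r] = hit ? 1 : 0;
    t_stop[r] = k * dt;
    X[r] = (xl - xr) / 2.0;           // tips at (-b/2 + xl) and (b/2 - xr)
    Y[r] = (yl + yr) / 2.0;
    thL_out[r] = thl;
    thR_out[r] = M_PI - thr;          // absolute heading of mirrored side
    xLo[r] = -base / 2.0 + xl;
    yLo[r] = yl;
    xRo[r] = base / 2.0 - xr;
    yRo[r] = yr;
  }
  return DataFrame::create(
      _["x"] = X, _["y"] = Y, _["t_stop"] = t_stop, _["stopped"] = stopped,
      _["theta_left"] = thL_out, _["theta_right"] = thR_out,
      _["tip_left_x"] = xLo, _["tip_left_y"] = yLo, _["tip_right_x"] = xRo,
      _["tip_right_y"] = yRo);
}
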