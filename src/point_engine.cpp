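// Point-particle engine: overdamped Langevin dynamics for N non-interacting
// colonies with magnetic alignment, translational/rotational noise and the
// oxygen-gated two-rate reversal process.  Euler-Maruyama in time; the
// reversal is a per-step Bernoulli hazard 1 - exp(-lambda * dt), exact for
// piecewise-constant rates.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double erfc_nc(double x) {
  return 2.0 * R::pnorm(-x * M_SQRT2, 0.0, 1.0, 1, 0);
}

static inline double wrap_pi(double phi) {
  double w = phi - 2.0 * M_PI * std::floor((phi + M_PI) / (2.0 * M_PI));
  if (w == -M_PI) w = M_PI;
  return w;
}

static inline double oxy_c(double x, double t, double C0, double DC,
                           bool enabled) {
  if (!enabled || t <= 0.0) return 0.0;
  if (x <= 0.0) return C0;
  return C0 * erfc_nc(x / (2.0 * std::sqrt(DC * t)));
}

// Decision function: increased rate when the oxygen signal and the swimming
// direction disagree with the favourable configuration; sensing off => no
// reversals at all (escape response is oxygen-gated).
static inline double decision(double c, int d, double lm, double lp,
                              double c_star, bool sensing) {
  if (!sensing) return 0.0;
  if ((c >= c_star && d == -1) || (c < c_star && d == 1)) return lp;
  return lm;
}

// [[Rcpp::export]]
List point_engine_run(NumericVector x0, NumericVector y0, NumericVector phi0,
                      IntegerVector mode0,
                      double v_jump, double v_return, double D, double Dr,
                      double lambda_minus, double lambda_plus,
                      double phi_B, double k,
                      double C0, double DC, double c_star, bool oxy_enabled,
                      double dt, int nsteps, int record_every) {
  const int n = x0.size();
  if (k * dt >= 0.5) stop("stability guard violated: k * dt must be < 0.5");
  if (lambda_plus * dt > 1.0)
    stop("timestep too coarse: lambda_plus * dt > 1");
  if (lambda_plus * dt > 0.1)
    warning("lambda * dt exceeds 0.1; reversal hazard is coarse");

  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> phi(phi0.begin(), phi0.end());
  std::vector<int> mode(mode0.begin(), mode0.end());
  std::vector<double> rate(n, oxy_enabled ? lambda_minus : 0.0);

  const int nrec = nsteps / record_every + 1;
  NumericVector rec_t(nrec * n), rec_x(nrec * n), rec_y(nrec * n),
      rec_phi(nrec * n), rec_rate(nrec * n);
  IntegerVector rec_id(nrec * n), rec_mode(nrec * n);

  std::vector<double> ev_t, ev_x;
  std::vector<int> ev_id, ev_mode;

  int ridx = 0;
  const double sq_phi = std::sqrt(2.0 * Dr * dt);
  const double sq_xy = std::sqrt(2.0 * D * dt);

  // frame 0: initial state
  for (int i = 0; i < n; ++i) {
    rec_t[ridx] = 0.0; rec_id[ridx] = i + 1; rec_x[ridx] = x[i];
    rec_y[ridx] = y[i]; rec_phi[ridx] = phi[i]; rec_mode[ridx] = mode[i];
    rec_rate[ridx] = rate[i]; ++ridx;
  }

  for (int step = 1; step <= nsteps; ++step) {
    const double t_new = step * dt;
    NumericVector z_phi = rnorm(n), z_x = rnorm(n), z_y = rnorm(n);
    NumericVector u = runif(n);
    for (int i = 0; i < n; ++i) {
      const double vt = (mode[i] == 1) ? v_jump : -v_return;
      const double phi_old = phi[i];
      phi[i] = wrap_pi(phi_old + k * std::sin(phi_B - phi_old) * dt +
                       sq_phi * z_phi[i]);
      x[i] += vt * std::cos(phi_old) * dt + sq_xy * z_x[i];
      y[i] += vt * std::sin(phi_old) * dt + sq_xy * z_y[i];
      if (x[i] < 0.0) x[i] = 0.0;  // interface boundary: clamped reflection
      if (!std::isfinite(x[i]) || !std::isfinite(y[i]) ||
          !std::isfinite(phi[i]))
        stop("integrator produced non-finite state for colony %d at t = %f",
             i + 1, t_new);
      const double c = oxy_c(x[i], t_new, C0, DC, oxy_enabled);
      const double vt_now = (mode[i] == 1) ? v_jump : -v_return;
      const int d = (vt_now * std::cos(phi[i] - phi_B) >= 0.0) ? 1 : -1;
      rate[i] = decision(c, d, lambda_minus, lambda_plus, c_star, oxy_enabled);
      if (u[i] < -std::expm1(-rate[i] * dt)) {
        mode[i] = -mode[i];
        ev_t.push_back(t_new); ev_id.push_back(i + 1);
        ev_mode.push_back(mode[i]); ev_x.push_back(x[i]);
      }
    }
    if (step % record_every == 0) {
      for (int i = 0; i < n; ++i) {
        rec_t[ridx] = t_new; rec_id[ridx] = i + 1; rec_x[ridx] = x[i];
        rec_y[ridx] = y[i]; rec_phi[ridx] = phi[i]; rec_mode[ridx] = mode[i];
        rec_rate[ridx] = rate[i]; ++ridx;
      }
    }
  }

  return List::create(
      _["time_s"] = rec_t, _["colony_id"] = rec_id, _["x_um"] = rec_x,
      _["y_um"] = rec_y, _["phi_rad"] = rec_phi, _["mode"] = rec_mode,
      _["rate_per_s"] = rec_rate,
      _["ev_time_s"] = NumericVector(ev_t.begin(), ev_t.end()),
      _["ev_colony_id"] = IntegerVector(ev_id.begin(), ev_id.end()),
      _["ev_mode"] = IntegerVector(ev_mode.begin(), ev_mode.end()),
      _["ev_x_um"] = NumericVector(ev_x.begin(), ev_x.end()));
}
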