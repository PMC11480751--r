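// Finite-size squirmer engine near a plane no-slip wall at x = 0.
//
// Each colony is a sphere of radius a with a prescribed tangential surface
// slip u_s(theta) = B1 sin(theta) (1 + beta cos(theta)) (B1 = 3/2 * signed
// swim speed; beta > 0 = puller).  Near-field interactions are modelled by
// leading-order lubrication resistances acting on the relative surface
// velocity at the closest points (normal ~ 1/gap, tangential ~ log(1/gap),
// both tapered to zero at the neighbour cutoff) plus an exponential steric
// repulsion.  Every step solves the overdamped force/torque balance
//   (R_iso + R_lub) V = F_thrust + F_steric + T_magnetic + slip drive
// for all translational and angular velocities simultaneously: each body
// moves so that its net force and net torque vanish.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double erfc_nc2(double x) {
  return 2.0 * R::pnorm(-x * M_SQRT2, 0.0, 1.0, 1, 0);
}
static inline double wrap_pi2(double phi) {
  double w = phi - 2.0 * M_PI * std::floor((phi + M_PI) / (2.0 * M_PI));
  if (w == -M_PI) w = M_PI;
  return w;
}
// y into [0, width) without fmod
static inline double wrap_period(double y, double width) {
  return y - width * std::floor(y / width);
}

struct SqParams {
  double a, eta, beta, contact_eps, rep_strength, rep_range, cutoff;
  double lub_n, lub_t, width;  // width <= 0: no periodicity in y
  double zeta_t() const { return 6.0 * M_PI * eta * a; }
  double zeta_r() const { return 8.0 * M_PI * eta * a * a * a; }
  double h_cut() const { return (cutoff - 2.0) * a; }
};

// tangential surface slip of a squirmer at the surface point in direction n
// (unit vector from the centre), for orientation p and signed B1
static inline void slip_at(double px, double py, double nx, double ny,
                           double B1, double beta, double &sx, double &sy) {
  const double pn = px * nx + py * ny;
  const double f = -B1 * (1.0 + beta * pn);
  sx = f * (px - pn * nx);
  sy = f * (py - pn * ny);
}

static inline double steric_force(double h, const SqParams &P) {
  const double e = std::exp(-h / P.rep_range);
  return P.rep_strength * e / (1.0 - e);
}

// lubrication coefficients, tapered so both vanish at the gap cutoff
static inline void lub_coeffs(double h, const SqParams &P, bool wall,
                              double &Cn, double &Ct) {
  const double hc = P.h_cut();
  const double hh = std::min(std::max(h, P.contact_eps * P.a), hc);
  const double n0 = wall ? 6.0 : 1.5;  // sphere-wall vs reduced two-sphere
  Cn = P.lub_n * n0 * M_PI * P.eta * P.a * P.a * (1.0 / hh - 1.0 / hc);
  Ct = P.lub_t * 0.5 * M_PI * P.eta * P.a * std::log(hc / hh);
}

// Pair force/torque on both bodies for *given* velocities (diagnostics and
// the exported R-level pair_interaction/wall_interaction).
// out: Fxi, Fyi, taui, Fxj, Fyj, tauj
static void pair_forces(double dx, double dy, double r,
                        double pxi, double pyi, double pxj, double pyj,
                        double B1i, double B1j,
                        double Uxi, double Uyi, double wi,
                        double Uxj, double Uyj, double wj,
                        const SqParams &P, double *out) {
  for (int q = 0; q < 6; ++q) out[q] = 0.0;
  const double h = r - 2.0 * P.a;
  if (h >= P.h_cut()) return;
  const double nx = dx / r, ny = dy / r;     // from i to j
  const double tx = -ny, ty = nx;            // z x n
  double Cn, Ct;
  lub_coeffs(h, P, false, Cn, Ct);
  double sxi, syi, sxj, syj;
  slip_at(pxi, pyi, nx, ny, B1i, P.beta, sxi, syi);
  slip_at(pxj, pyj, -nx, -ny, B1j, P.beta, sxj, syj);
  const double dux = (Uxi - Uxj) + P.a * (wi + wj) * tx + (sxi - sxj);
  const double duy = (Uyi - Uyj) + P.a * (wi + wj) * ty + (syi - syj);
  const double dun = dux * nx + duy * ny;
  const double dut = dux * tx + duy * ty;
  const double Fs = steric_force(std::max(h, P.contact_eps * P.a), P);
  // force on i: lubrication resisting relative surface motion + steric
  out[0] = -Cn * dun * nx - Ct * dut * tx - Fs * nx;
  out[1] = -Cn * dun * ny - Ct * dut * ty - Fs * ny;
  out[2] = -P.a * Ct * dut;
  out[3] = -out[0];
  out[4] = -out[1];
  out[5] = -P.a * Ct * dut;  // same-sign torque on both bodies
}

static void wall_forces(double x, double pxi, double pyi, double B1i,
                        double Uxi, double Uyi, double wi,
                        const SqParams &P, double *out) {
  out[0] = out[1] = out[2] = 0.0;
  const double h = x - P.a;
  if (h >= P.h_cut()) return;
  const double nx = -1.0, ny = 0.0;  // toward the wall
  const double tx = 0.0, ty = -1.0;  // z x n
  double Cn, Ct;
  lub_coeffs(h, P, true, Cn, Ct);
  double sx, sy;
  slip_at(pxi, pyi, nx, ny, B1i, P.beta, sx, sy);
  const double dux = Uxi + P.a * wi * tx + sx;
  const double duy = Uyi + P.a * wi * ty + sy;
  const double dun = dux * nx + duy * ny;
  const double dut = dux * tx + duy * ty;
  const double Fs = steric_force(std::max(h, P.contact_eps * P.a), P);
  out[0] = -Cn * dun * nx - Ct * dut * tx - Fs * nx;
  out[1] = -Cn * dun * ny - Ct * dut * ty - Fs * ny;
  out[2] = -P.a * Ct * dut;
}

// [[Rcpp::export]]
NumericVector squirmer_pair_forces_cpp(NumericVector si, NumericVector sj,
                                       NumericVector vi, NumericVector vj,
                                       double B1i, double B1j,
                                       List par) {
  SqParams P{par["a"], par["eta"], par["beta"], par["contact_eps"],
             par["rep_strength"], par["rep_range"], par["cutoff"],
             par["lub_n"], par["lub_t"], par["width"]};
  double dx = sj[0] - si[0], dy = sj[1] - si[1];
  if (P.width > 0) dy -= P.width * std::round(dy / P.width);
  const double r = std::sqrt(dx * dx + dy * dy);
  if (r <= 0) stop("coincident squirmer centres");
  double out[6];
  pair_forces(dx, dy, r, std::cos(si[2]), std::sin(si[2]), std::cos(sj[2]),
              std::sin(sj[2]), B1i, B1j, vi[0], vi[1], vi[2], vj[0], vj[1],
              vj[2], P, out);
  return NumericVector(out, out + 6);
}

// [[Rcpp::export]]
NumericVector squirmer_wall_forces_cpp(NumericVector si, NumericVector vi,
                                       double B1i, List par) {
  SqParams P{par["a"], par["eta"], par["beta"], par["contact_eps"],
             par["rep_strength"], par["rep_range"], par["cutoff"],
             par["lub_n"], par["lub_t"], par["width"]};
  if (si[0] < P.a * (1.0 - 1e-9)) stop("squirmer centre inside the wall");
  double out[3];
  wall_forces(si[0], std::cos(si[2]), std::sin(si[2]), B1i, vi[0], vi[1],
              vi[2], P, out);
  return NumericVector(out, out + 3);
}

struct Assembled {
  arma::mat A;
  arma::vec b;
};

// assemble the resistance system for the current configuration
static void assemble(const std::vector<double> &x, const std::vector<double> &y,
                     const std::vector<double> &phi,
                     const std::vector<int> &mode, double v_jump,
                     double v_return, double phi_B, double k,
                     const SqParams &P, arma::mat &A, arma::vec &b,
                     double *min_gap) {
  const int n = (int)x.size();
  A.zeros();
  b.zeros();
  const double zt = P.zeta_t(), zr = P.zeta_r();
  std::vector<double> px(n), py(n), B1(n);
  for (int i = 0; i < n; ++i) {
    px[i] = std::cos(phi[i]);
    py[i] = std::sin(phi[i]);
    const double vt = (mode[i] == 1) ? v_jump : -v_return;
    B1[i] = 1.5 * vt;
    const int ui = 3 * i, wi = 3 * i + 2;
    A(ui, ui) += zt;
    A(ui + 1, ui + 1) += zt;
    A(wi, wi) += zr;
    b(ui) += zt * vt * px[i];
    b(ui + 1) += zt * vt * py[i];
    b(wi) += zr * k * std::sin(phi_B - phi[i]);
  }
  const double hc = P.h_cut();
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = x[j] - x[i], dy = y[j] - y[i];
      if (P.width > 0) dy -= P.width * std::round(dy / P.width);
      const double r = std::sqrt(dx * dx + dy * dy);
      if (r <= 0) stop("coincident squirmer centres (colonies %d, %d)", i + 1, j + 1);
      const double h = r - 2.0 * P.a;
      if (h < *min_gap) *min_gap = h;
      if (h >= hc) continue;
      const double nx = dx / r, ny = dy / r, tx = -ny, ty = nx;
      double Cn, Ct;
      lub_coeffs(h, P, false, Cn, Ct);
      double sxi, syi, sxj, syj;
      slip_at(px[i], py[i], nx, ny, B1[i], P.beta, sxi, syi);
      slip_at(px[j], py[j], -nx, -ny, B1[j], P.beta, sxj, syj);
      const double dsx = sxi - sxj, dsy = syi - syj;
      const double dst = dsx * tx + dsy * ty;  // slip is tangential
      const double Fs = steric_force(std::max(h, P.contact_eps * P.a), P);
      const int ui = 3 * i, uj = 3 * j, wi = 3 * i + 2, wj = 3 * j + 2;
      const double M00 = Cn * nx * nx + Ct * tx * tx;
      const double M01 = Cn * nx * ny + Ct * tx * ty;
      const double M11 = Cn * ny * ny + Ct * ty * ty;
      // force balances
      A(ui, ui) += M00;       A(ui, ui + 1) += M01;
      A(ui + 1, ui) += M01;   A(ui + 1, ui + 1) += M11;
      A(uj, uj) += M00;       A(uj, uj + 1) += M01;
      A(uj + 1, uj) += M01;   A(uj + 1, uj + 1) += M11;
      A(ui, uj) -= M00;       A(ui, uj + 1) -= M01;
      A(ui + 1, uj) -= M01;   A(ui + 1, uj + 1) -= M11;
      A(uj, ui) -= M00;       A(uj, ui + 1) -= M01;
      A(uj + 1, ui) -= M01;   A(uj + 1, ui + 1) -= M11;
      const double cat = Ct * P.a;
      A(ui, wi) += cat * tx;  A(ui + 1, wi) += cat * ty;
      A(ui, wj) += cat * tx;  A(ui + 1, wj) += cat * ty;
      A(uj, wi) -= cat * tx;  A(uj + 1, wi) -= cat * ty;
      A(uj, wj) -= cat * tx;  A(uj + 1, wj) -= cat * ty;
      // torque balances (same-sign coupling on both bodies)
      A(wi, ui) += cat * tx;  A(wi, ui + 1) += cat * ty;
      A(wi, uj) -= cat * tx;  A(wi, uj + 1) -= cat * ty;
      A(wj, ui) += cat * tx;  A(wj, ui + 1) += cat * ty;
      A(wj, uj) -= cat * tx;  A(wj, uj + 1) -= cat * ty;
      const double caa = Ct * P.a * P.a;
      A(wi, wi) += caa;  A(wi, wj) += caa;
      A(wj, wj) += caa;  A(wj, wi) += caa;
      // slip drive and steric on the right-hand side
      b(ui) += -Ct * dst * tx - Fs * nx;
      b(ui + 1) += -Ct * dst * ty - Fs * ny;
      b(uj) += Ct * dst * tx + Fs * nx;
      b(uj + 1) += Ct * dst * ty + Fs * ny;
      b(wi) += -P.a * Ct * dst;
      b(wj) += -P.a * Ct * dst;
    }
    // wall at x = 0
    const double hw = x[i] - P.a;
    if (hw < *min_gap) *min_gap = hw;
    if (hw < hc) {
      const double nx = -1.0, ny = 0.0, tx = 0.0, ty = -1.0;
      double Cn, Ct;
      lub_coeffs(hw, P, true, Cn, Ct);
      double sx, sy;
      slip_at(px[i], py[i], nx, ny, B1[i], P.beta, sx, sy);
      const double st = sx * tx + sy * ty;
      const double Fs = steric_force(std::max(hw, P.contact_eps * P.a), P);
      const int ui = 3 * i, wi = 3 * i + 2;
      A(ui, ui) += Cn * nx * nx + Ct * tx * tx;
      A(ui, ui + 1) += Cn * nx * ny + Ct * tx * ty;
      A(ui + 1, ui) += Cn * nx * ny + Ct * tx * ty;
      A(ui + 1, ui + 1) += Cn * ny * ny + Ct * ty * ty;
      A(ui, wi) += Ct * P.a * tx;
      A(ui + 1, wi) += Ct * P.a * ty;
      A(wi, ui) += Ct * P.a * tx;
      A(wi, ui + 1) += Ct * P.a * ty;
      A(wi, wi) += Ct * P.a * P.a;
      b(ui) += -Ct * st * tx - Fs * nx;
      b(ui + 1) += -Ct * st * ty - Fs * ny;
      b(wi) += -P.a * Ct * st;
    }
  }
}

// hard no-overlap projection: separate any overlapping pair symmetrically
// along the line of centres (a few Gauss-Seidel sweeps), then re-clamp at
// the wall.  Keeps the contact regularisation honest: lubrication and
// steric forces resist approach, the projection removes the residual
// sub-regularisation creep.
static void project_overlaps(std::vector<double> &x, std::vector<double> &y,
                             const SqParams &P, int sweeps = 8) {
  const int n = (int)x.size();
  for (int s = 0; s < sweeps; ++s) {
    bool any = false;
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        double dx = x[j] - x[i], dy = y[j] - y[i];
        if (P.width > 0) dy -= P.width * std::round(dy / P.width);
        const double r = std::sqrt(dx * dx + dy * dy);
        if (r <= 0 || r >= 2.0 * P.a) continue;
        const double push = 0.5 * (2.0 * P.a - r);
        const double nx = dx / r, ny = dy / r;
        x[i] -= push * nx; y[i] -= push * ny;
        x[j] += push * nx; y[j] += push * ny;
        any = true;
      }
      if (x[i] < P.a) { x[i] = P.a; any = true; }
      if (P.width > 0) y[i] = wrap_period(y[i], P.width);
    }
    if (!any) break;
  }
}

// one deterministic advance over dt, with recursive halving if the linear
// solve fails or produces non-finite velocities
static void advance(std::vector<double> &x, std::vector<double> &y,
                    std::vector<double> &phi, const std::vector<int> &mode,
                    double v_jump, double v_return, double phi_B, double k,
                    const SqParams &P, double dt, int depth, arma::mat &A,
                    arma::vec &b, arma::vec &v, double *min_gap) {
  const int n = (int)x.size();
  assemble(x, y, phi, mode, v_jump, v_return, phi_B, k, P, A, b, min_gap);
  bool ok = arma::solve(v, A, b, arma::solve_opts::no_approx);
  if (!ok || !v.is_finite()) {
    if (depth >= 6)
      stop("velocity solve failed after repeated timestep halving; "
           "reduce dt or soften the interaction parameters");
    advance(x, y, phi, mode, v_jump, v_return, phi_B, k, P, dt / 2, depth + 1,
            A, b, v, min_gap);
    advance(x, y, phi, mode, v_jump, v_return, phi_B, k, P, dt / 2, depth + 1,
            A, b, v, min_gap);
    return;
  }
  for (int i = 0; i < n; ++i) {
    x[i] += v(3 * i) * dt;
    y[i] += v(3 * i + 1) * dt;
    phi[i] += v(3 * i + 2) * dt;
    if (x[i] < P.a) x[i] = P.a;  // hard wall safeguard
    if (P.width > 0) y[i] = wrap_period(y[i], P.width);
  }
}

// [[Rcpp::export]]
List squirmer_engine_run(NumericVector x0, NumericVector y0,
                         NumericVector phi0, IntegerVector mode0, List par,
                         double v_jump, double v_return, double D, double Dr,
                         double lambda_minus, double lambda_plus,
                         double phi_B, double k, double C0, double DC,
                         double c_star, bool oxy_enabled, double dt,
                         int nsteps, int record_every) {
  SqParams P{par["a"], par["eta"], par["beta"], par["contact_eps"],
             par["rep_strength"], par["rep_range"], par["cutoff"],
             par["lub_n"], par["lub_t"], par["width"]};
  const int n = x0.size();
  if (k * dt >= 0.5) stop("stability guard violated: k * dt must be < 0.5");
  if (lambda_plus * dt > 1.0) stop("timestep too coarse: lambda_plus * dt > 1");

  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> phi(phi0.begin(), phi0.end());
  std::vector<int> mode(mode0.begin(), mode0.end());
  std::vector<double> rate(n, oxy_enabled ? lambda_minus : 0.0);

  const int nrec = (n > 0) ? (nsteps / record_every + 1) : 0;
  NumericVector rec_t(nrec * n), rec_x(nrec * n), rec_y(nrec * n),
      rec_phi(nrec * n), rec_rate(nrec * n);
  IntegerVector rec_id(nrec * n), rec_mode(nrec * n);
  std::vector<double> ev_t, ev_x;
  std::vector<int> ev_id, ev_mode;

  arma::mat A(3 * n, 3 * n);
  arma::vec b(3 * n), v(3 * n, arma::fill::zeros);
  double min_gap = R_PosInf;

  int ridx = 0;
  for (int i = 0; i < n; ++i) {
    rec_t[ridx] = 0.0; rec_id[ridx] = i + 1; rec_x[ridx] = x[i];
    rec_y[ridx] = y[i]; rec_phi[ridx] = phi[i]; rec_mode[ridx] = mode[i];
    rec_rate[ridx] = rate[i]; ++ridx;
  }
  const double sq_phi = std::sqrt(2.0 * Dr * dt);
  const double sq_xy = std::sqrt(2.0 * D * dt);

  for (int step = 1; step <= nsteps; ++step) {
    const double t_new = step * dt;
    if (n > 0) {
      advance(x, y, phi, mode, v_jump, v_return, phi_B, k, P, dt, 0, A, b, v,
              &min_gap);
      NumericVector z_phi = rnorm(n), z_x = rnorm(n), z_y = rnorm(n);
      NumericVector u = runif(n);
      for (int i = 0; i < n; ++i) {
        if (Dr > 0) phi[i] += sq_phi * z_phi[i];
        if (D > 0) {
          x[i] += sq_xy * z_x[i];
          y[i] += sq_xy * z_y[i];
          if (x[i] < P.a) x[i] = P.a;
          if (P.width > 0) y[i] = wrap_period(y[i], P.width);
        }
      }
      project_overlaps(x, y, P);
      for (int i = 0; i < n; ++i) {
        phi[i] = wrap_pi2(phi[i]);
        if (!std::isfinite(x[i]) || !std::isfinite(phi[i]))
          stop("integrator produced non-finite state for colony %d at t = %f "
               "(consider a smaller dt)", i + 1, t_new);
        // oxygen-gated reversal process, identical to the point engine
        double c = 0.0;
        if (oxy_enabled && t_new > 0) {
          const double xs = x[i];
          c = (xs <= 0) ? C0 : C0 * erfc_nc2(xs / (2.0 * std::sqrt(DC * t_new)));
        }
        const double vt_now = (mode[i] == 1) ? v_jump : -v_return;
        const int d = (vt_now * std::cos(phi[i] - phi_B) >= 0.0) ? 1 : -1;
        if (!oxy_enabled)
          rate[i] = 0.0;
        else if ((c >= c_star && d == -1) || (c < c_star && d == 1))
          rate[i] = lambda_plus;
        else
          rate[i] = lambda_minus;
        if (u[i] < -std::expm1(-rate[i] * dt)) {
          mode[i] = -mode[i];
          ev_t.push_back(t_new); ev_id.push_back(i + 1);
          ev_mode.push_back(mode[i]); ev_x.push_back(x[i]);
        }
      }
    }
    if (n > 0 && step % record_every == 0) {
      for (int i = 0; i < n; ++i) {
        rec_t[ridx] = t_new; rec_id[ridx] = i + 1; rec_x[ridx] = x[i];
        rec_y[ridx] = y[i]; rec_phi[ridx] = phi[i]; rec_mode[ridx] = mode[i];
        rec_rate[ridx] = rate[i]; ++ridx;
      }
    }
  }

  NumericVector Ux(n), Uy(n), Om(n);
  for (int i = 0; i < n; ++i) {
    Ux[i] = v(3 * i); Uy[i] = v(3 * i + 1); Om[i] = v(3 * i + 2);
  }
  return List::create(
      _["time_s"] = rec_t, _["colony_id"] = rec_id, _["x_um"] = rec_x,
      _["y_um"] = rec_y, _["phi_rad"] = rec_phi, _["mode"] = rec_mode,
      _["rate_per_s"] = rec_rate,
      _["ev_time_s"] = NumericVector(ev_t.begin(), ev_t.end()),
      _["ev_colony_id"] = IntegerVector(ev_id.begin(), ev_id.end()),
      _["ev_mode"] = IntegerVector(ev_mode.begin(), ev_mode.end()),
      _["ev_x_um"] = NumericVector(ev_x.begin(), ev_x.end()),
      _["min_gap_um"] = min_gap,
      _["Ux_um_s"] = Ux, _["Uy_um_s"] = Uy, _["omega_rad_s"] = Om);
}
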