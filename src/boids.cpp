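// Boid dynamics: cohesion, separation and alignment over topological
// (Voronoi) or metric neighbors, unit-normalized force terms scaled by the
// steering factor S, constant speed V, uniform angular noise of half-width
// eta (degrees), periodic box, forward-Euler position update.
//
// The run loop rebuilds the neighbor graph every step. Noise draws come from
// R's global RNG (one uniform per boid per step, consumed also when eta = 0)
// so trajectories are reproducible from set.seed() and comparable across
// noise levels.

#include "delaunay.h"
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

inline double mimg(double d, double L) { return d - L * std::round(d / L); }

inline double wrap01(double v, double L) {
  v -= L * std::floor(v / L);
  if (v >= L) v -= L; // guard against round-off at the upper edge
  if (v < 0) v = 0;
  return v;
}

void neighbor_lists(const std::vector<double> &x, const std::vector<double> &y,
                    double Lx, double Ly, bool metric, double R,
                    std::vector<std::vector<int>> &nb) {
  const int n = (int)x.size();
  nb.assign(n, {});
  if (!metric) {
    auto pairs = periodic_delaunay_pairs(x, y, Lx, Ly);
    for (auto &pr : pairs) {
      nb[pr.first].push_back(pr.second);
      nb[pr.second].push_back(pr.first);
    }
  } else {
    const double R2 = R * R;
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        double dx = mimg(x[i] - x[j], Lx), dy = mimg(y[i] - y[j], Ly);
        if (dx * dx + dy * dy <= R2) {
          nb[i].push_back(j);
          nb[j].push_back(i);
        }
      }
  }
}

inline void add_unit(double fx, double fy, double &ax, double &ay) {
  double nrm = std::sqrt(fx * fx + fy * fy);
  if (nrm < 1e-12) return; // zero term dropped, not divided by its norm
  ax += fx / nrm;
  ay += fy / nrm;
}

// Raw rule forces and their unit-normalized sum for one configuration.
void boid_forces(const std::vector<double> &x, const std::vector<double> &y,
                 const std::vector<double> &vx, const std::vector<double> &vy,
                 const std::vector<std::vector<int>> &nb, double Lx, double Ly,
                 std::vector<double> &fsx, std::vector<double> &fsy,
                 std::vector<double> &fax, std::vector<double> &fay,
                 std::vector<double> &fcx, std::vector<double> &fcy,
                 std::vector<double> &ftx, std::vector<double> &fty) {
  const int n = (int)x.size();
  fsx.assign(n, 0); fsy.assign(n, 0);
  fax.assign(n, 0); fay.assign(n, 0);
  fcx.assign(n, 0); fcy.assign(n, 0);
  ftx.assign(n, 0); fty.assign(n, 0);
  for (int i = 0; i < n; ++i) {
    const int ni = (int)nb[i].size();
    if (ni == 0) continue;
    double sx = 0, sy = 0, svx = 0, svy = 0, scx = 0, scy = 0;
    for (int j : nb[i]) {
      double dx = mimg(x[i] - x[j], Lx), dy = mimg(y[i] - y[j], Ly);
      double r2 = dx * dx + dy * dy;
      if (r2 > 0) {
        sx += dx / r2;
        sy += dy / r2;
      }
      svx += vx[j];
      svy += vy[j];
      scx -= dx; // minimum-image (r_j - r_i)
      scy -= dy;
    }
    fsx[i] = sx;
    fsy[i] = sy;
    fax[i] = svx / ni - vx[i];
    fay[i] = svy / ni - vy[i];
    fcx[i] = scx / ni;
    fcy[i] = scy / ni;
    double ax = 0, ay = 0;
    add_unit(fsx[i], fsy[i], ax, ay);
    add_unit(fax[i], fay[i], ax, ay);
    add_unit(fcx[i], fcy[i], ax, ay);
    ftx[i] = ax;
    fty[i] = ay;
  }
}

} // namespace

// [[Rcpp::export(name = ".boid_forces_cpp")]]
List boid_forces_cpp(NumericMatrix pos, NumericMatrix vel, double Lx,
                     double Ly, bool metric, double R) {
  const int n = pos.nrow();
  std::vector<double> x(n), y(n), vx(n), vy(n);
  for (int i = 0; i < n; ++i) {
    x[i] = pos(i, 0); y[i] = pos(i, 1);
    vx[i] = vel(i, 0); vy[i] = vel(i, 1);
  }
  std::vector<std::vector<int>> nb;
  neighbor_lists(x, y, Lx, Ly, metric, R, nb);
  std::vector<double> fsx, fsy, fax, fay, fcx, fcy, ftx, fty;
  boid_forces(x, y, vx, vy, nb, Lx, Ly, fsx, fsy, fax, fay, fcx, fcy, ftx,
              fty);
  NumericMatrix fs(n, 2), fa(n, 2), fc(n, 2), ft(n, 2);
  IntegerVector deg(n);
  for (int i = 0; i < n; ++i) {
    fs(i, 0) = fsx[i]; fs(i, 1) = fsy[i];
    fa(i, 0) = fax[i]; fa(i, 1) = fay[i];
    fc(i, 0) = fcx[i]; fc(i, 1) = fcy[i];
    ft(i, 0) = ftx[i]; ft(i, 1) = fty[i];
    deg[i] = (int)nb[i].size();
  }
  return List::create(_["f_sep"] = fs, _["f_alg"] = fa, _["f_coh"] = fc,
                      _["f_total"] = ft, _["degree"] = deg);
}

// [[Rcpp::export(name = ".boids_run_cpp")]]
List boids_run_cpp(NumericMatrix pos0, NumericVector theta0, double Lx,
                   double Ly, double V, double S, double eta_deg, double dt,
                   bool metric, double R, int n_steps, int record_every,
                   double conv_tol, int conv_window) {
  const int n = pos0.nrow();
  std::vector<double> x(n), y(n), th(n), vx(n), vy(n);
  for (int i = 0; i < n; ++i) {
    x[i] = pos0(i, 0);
    y[i] = pos0(i, 1);
    th[i] = theta0[i];
  }
  const double eta = eta_deg * M_PI / 180.0;
  std::vector<double> va;
  va.reserve(n_steps);
  List rec_pos, rec_theta;
  std::vector<int> rec_steps;

  auto record = [&](int step) {
    NumericMatrix p(n, 2);
    NumericVector t(n);
    for (int i = 0; i < n; ++i) {
      p(i, 0) = x[i];
      p(i, 1) = y[i];
      t[i] = th[i];
    }
    rec_pos.push_back(p);
    rec_theta.push_back(t);
    rec_steps.push_back(step);
  };
  record(0);

  std::vector<std::vector<int>> nb;
  std::vector<double> fsx, fsy, fax, fay, fcx, fcy, ftx, fty;
  int steps_done = 0;
  bool converged = false;
  for (int step = 1; step <= n_steps; ++step) {
    if (step % 1000 == 0) Rcpp::checkUserInterrupt();
    neighbor_lists(x, y, Lx, Ly, metric, R, nb);
    for (int i = 0; i < n; ++i) {
      vx[i] = V * std::cos(th[i]);
      vy[i] = V * std::sin(th[i]);
    }
    boid_forces(x, y, vx, vy, nb, Lx, Ly, fsx, fsy, fax, fay, fcx, fcy, ftx,
                fty);
    double svx = 0, svy = 0;
    for (int i = 0; i < n; ++i) {
      const double wx = vx[i] + S * ftx[i], wy = vy[i] + S * fty[i];
      double thn = (wx == 0.0 && wy == 0.0) ? th[i] : std::atan2(wy, wx);
      const double u = unif_rand(); // consumed at every eta for comparability
      thn += (2.0 * u - 1.0) * eta;
      th[i] = thn;
      const double nvx = V * std::cos(thn), nvy = V * std::sin(thn);
      x[i] = wrap01(x[i] + nvx * dt, Lx);
      y[i] = wrap01(y[i] + nvy * dt, Ly);
      svx += nvx;
      svy += nvy;
    }
    va.push_back(std::sqrt(svx * svx + svy * svy) / (n * V));
    steps_done = step;
    bool last = (step == n_steps);
    if (conv_tol > 0 && step >= 2 * conv_window && step % conv_window == 0) {
      double m1 = 0, m0 = 0;
      for (int k = step - conv_window; k < step; ++k) m1 += va[k];
      for (int k = step - 2 * conv_window; k < step - conv_window; ++k)
        m0 += va[k];
      if (std::fabs(m1 - m0) / conv_window < conv_tol) {
        converged = true;
        last = true;
      }
    }
    if (step % record_every == 0 || last) {
      if (rec_steps.back() != step) record(step);
    }
    if (converged) break;
  }
  return List::create(_["va"] = NumericVector(va.begin(), va.end()),
                      _["rec_steps"] = IntegerVector(rec_steps.begin(),
                                                     rec_steps.end()),
                      _["positions"] = rec_pos, _["headings"] = rec_theta,
                      _["steps_done"] = steps_done,
                      _["converged"] = converged);
}
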