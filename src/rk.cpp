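// Adaptive Dormand-Prince 5(4) integration of planar power-law fields in
// logarithmic state coordinates (positivity is structural), with
// Poincare-section crossing detection for the return map.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

struct Field {
  std::vector<double> cx, ax, bx, cy, ay, by;
  // derivative of (log x, log y)
  inline void deriv(double lx, double ly, double &du, double &dv) const {
    du = 0.0; dv = 0.0;
    for (size_t i = 0; i < cx.size(); ++i)
      du += cx[i] * std::exp((ax[i] - 1.0) * lx + bx[i] * ly);
    for (size_t i = 0; i < cy.size(); ++i)
      dv += cy[i] * std::exp(ay[i] * lx + (by[i] - 1.0) * ly);
  }
};

static const double C2 = 1.0 / 5, C3 = 3.0 / 10, C4 = 4.0 / 5, C5 = 8.0 / 9;
static const double A21 = 1.0 / 5;
static const double A31 = 3.0 / 40, A32 = 9.0 / 40;
static const double A41 = 44.0 / 45, A42 = -56.0 / 15, A43 = 32.0 / 9;
static const double A51 = 19372.0 / 6561, A52 = -25360.0 / 2187,
                    A53 = 64448.0 / 6561, A54 = -212.0 / 729;
static const double A61 = 9017.0 / 3168, A62 = -355.0 / 33,
                    A63 = 46732.0 / 5247, A64 = 49.0 / 176,
                    A65 = -5103.0 / 18656;
static const double B1 = 35.0 / 384, B3 = 500.0 / 1113, B4 = 125.0 / 192,
                    B5 = -2187.0 / 6784, B6 = 11.0 / 84;
static const double E1 = 35.0 / 384 - 5179.0 / 57600,
                    E3 = 500.0 / 1113 - 7571.0 / 16695,
                    E4 = 125.0 / 192 - 393.0 / 640,
                    E5 = -2187.0 / 6784 + 92097.0 / 339200,
                    E6 = 11.0 / 84 - 187.0 / 2100, E7 = -1.0 / 40;

// one DP5 step of size h from (u,v); returns error estimate, fills (u1,v1)
static double dp5_step(const Field &f, double u, double v, double h,
                       double &u1, double &v1) {
  double k1u, k1v, k2u, k2v, k3u, k3v, k4u, k4v, k5u, k5v, k6u, k6v,
      k7u, k7v;
  f.deriv(u, v, k1u, k1v);
  f.deriv(u + h * A21 * k1u, v + h * A21 * k1v, k2u, k2v);
  f.deriv(u + h * (A31 * k1u + A32 * k2u),
          v + h * (A31 * k1v + A32 * k2v), k3u, k3v);
  f.deriv(u + h * (A41 * k1u + A42 * k2u + A43 * k3u),
          v + h * (A41 * k1v + A42 * k2v + A43 * k3v), k4u, k4v);
  f.deriv(u + h * (A51 * k1u + A52 * k2u + A53 * k3u + A54 * k4u),
          v + h * (A51 * k1v + A52 * k2v + A53 * k3v + A54 * k4v), k5u, k5v);
  f.deriv(u + h * (A61 * k1u + A62 * k2u + A63 * k3u + A64 * k4u + A65 * k5u),
          v + h * (A61 * k1v + A62 * k2v + A63 * k3v + A64 * k4v + A65 * k5v),
          k6u, k6v);
  u1 = u + h * (B1 * k1u + B3 * k3u + B4 * k4u + B5 * k5u + B6 * k6u);
  v1 = v + h * (B1 * k1v + B3 * k3v + B4 * k4v + B5 * k5v + B6 * k6v);
  f.deriv(u1, v1, k7u, k7v);
  double eu = h * (E1 * k1u + E3 * k3u + E4 * k4u + E5 * k5u + E6 * k6u +
                   E7 * k7u);
  double ev = h * (E1 * k1v + E3 * k3v + E4 * k4v + E5 * k5v + E6 * k6v +
                   E7 * k7v);
  return std::sqrt(eu * eu + ev * ev);
}

static Field make_field(NumericVector cx, NumericVector ax, NumericVector bx,
                        NumericVector cy, NumericVector ay, NumericVector by) {
  Field f;
  f.cx = as<std::vector<double>>(cx); f.ax = as<std::vector<double>>(ax);
  f.bx = as<std::vector<double>>(bx); f.cy = as<std::vector<double>>(cy);
  f.ay = as<std::vector<double>>(ay); f.by = as<std::vector<double>>(by);
  return f;
}

// [[Rcpp::export]]
List cpp_integrate(NumericVector cx, NumericVector ax, NumericVector bx,
                   NumericVector cy, NumericVector ay, NumericVector by,
                   double x0, double y0, double t_end, double rtol,
                   double atol, int max_steps, double log_box, bool store,
                   double stop_y_below) {
  Field f = make_field(cx, ax, bx, cy, ay, by);
  double u = std::log(x0), v = std::log(y0), t = 0.0, h = 1e-4;
  std::vector<double> ts, xs, ys;
  std::string status = "maxsteps";
  if (store) { ts.push_back(t); xs.push_back(x0); ys.push_back(y0); }
  for (int it = 0; it < max_steps; ++it) {
    if (t >= t_end) { status = "completed"; break; }
    if (h > t_end - t) h = t_end - t;
    double u1, v1;
    double err = dp5_step(f, u, v, h, u1, v1);
    double sc = atol + rtol * std::max(std::max(std::fabs(u), std::fabs(v)),
                                       1.0);
    double ratio = err / sc;
    if (ratio <= 1.0) {
      t += h; u = u1; v = v1;
      if (store) { ts.push_back(t); xs.push_back(std::exp(u));
                   ys.push_back(std::exp(v)); }
      if (std::fabs(u) > log_box || std::fabs(v) > log_box) {
        status = "blowup"; break;
      }
      if (std::exp(v) < stop_y_below) { status = "axis"; break; }
    }
    double fac = ratio > 0 ? 0.9 * std::pow(ratio, -0.2) : 5.0;
    if (std::isnan(fac)) fac = 0.2;
    if (fac > 5.0) fac = 5.0; if (fac < 0.2) fac = 0.2;
    h *= fac;
    if (h < 1e-14) { status = "stepfail"; break; }
  }
  return List::create(_["times"] = ts, _["x"] = xs, _["y"] = ys,
                      _["t"] = t, _["x_end"] = std::exp(u),
                      _["y_end"] = std::exp(v), _["status"] = status);
}

// first n_cross crossings of the section {y = 1, x > 1} with ydot matching
// the orientation at the start point
// [[Rcpp::export]]
List cpp_return_map(NumericVector cx, NumericVector ax, NumericVector bx,
                    NumericVector cy, NumericVector ay, NumericVector by,
                    double x0, int n_cross, double t_max, double rtol,
                    double atol, double log_box) {
  Field f = make_field(cx, ax, bx, cy, ay, by);
  double u = std::log(x0), v = 0.0, t = 0.0, h = 1e-4;
  double du0, dv0;
  f.deriv(u, v, du0, dv0);
  if (dv0 == 0.0)
    return List::create(_["status"] = "tangent_start");
  double dir = dv0 > 0 ? 1.0 : -1.0;
  std::vector<double> cross_x, cross_t;
  std::string status = "no_return";
  int max_steps = 100000000; // guarded by t_max
  for (int it = 0; it < max_steps; ++it) {
    if (t >= t_max) break;
    double u1, v1;
    double err = dp5_step(f, u, v, h, u1, v1);
    double sc = atol + rtol * std::max(std::max(std::fabs(u), std::fabs(v)),
                                       1.0);
    double ratio = err / sc;
    if (ratio <= 1.0) {
      // look for a sign change of v=log(y) within the accepted step
      if (t > 0 && ((v > 0 && v1 <= 0) || (v < 0 && v1 >= 0))) {
        double lo = 0.0, hi = h, um = u1, vm = v1;
        for (int b = 0; b < 80; ++b) {
          double mid = 0.5 * (lo + hi);
          dp5_step(f, u, v, mid, um, vm);
          if ((v > 0 && vm <= 0) || (v < 0 && vm >= 0)) hi = mid; else lo = mid;
          if (hi - lo < 1e-15 * (1.0 + hi)) break;
        }
        dp5_step(f, u, v, hi, um, vm);
        double duc, dvc;
        f.deriv(um, 0.0, duc, dvc);
        if (um > 1e-12 && dvc * dir > 0) {
          cross_x.push_back(std::exp(um));
          cross_t.push_back(t + hi);
          if ((int)cross_x.size() >= n_cross) {
            status = "ok";
            // continue from just after the crossing
            t += hi; u = um; v = vm;
            break;
          }
        }
      }
      t += h; u = u1; v = v1;
      if (std::fabs(u) > log_box || std::fabs(v) > log_box) {
        status = "left_box"; break;
      }
    }
    double fac = ratio > 0 ? 0.9 * std::pow(ratio, -0.2) : 5.0;
    if (std::isnan(fac)) fac = 0.2;
    if (fac > 5.0) fac = 5.0; if (fac < 0.2) fac = 0.2;
    h *= fac;
    if (h < 1e-14) { status = "stepfail"; break; }
  }
  if (status == "no_return" && (int)cross_x.size() > 0) status = "partial";
  return List::create(_["x"] = cross_x, _["t"] = cross_t,
                      _["status"] = status);
}
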