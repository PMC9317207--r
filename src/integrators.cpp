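#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Replicator vector field in reduced-coefficient form:
//   dx/dt = x(1-x)(a y + b),  dy/dt = y(1-y)(c x + d).
static inline void field(double a, double b, double c, double d,
                         double x, double y, double &fx, double &fy) {
  fx = x * (1.0 - x) * (a * y + b);
  fy = y * (1.0 - y) * (c * x + d);
}

static const double CX[4] = {0.0, 0.0, 1.0, 1.0};
static const double CY[4] = {0.0, 1.0, 0.0, 1.0};

// Corner convergence test: within delta of a corner AND field norm < delta^2.
// Returns corner index 0..3 (O, A, B, C) or -1.
static inline int corner_test(double a, double b, double c, double d,
                              double x, double y, double delta) {
  double fx, fy;
  for (int k = 0; k < 4; ++k) {
    double dx = x - CX[k], dy = y - CY[k];
    if (std::sqrt(dx * dx + dy * dy) < delta) {
      field(a, b, c, d, x, y, fx, fy);
      if (std::sqrt(fx * fx + fy * fy) < delta * delta) return k;
    }
  }
  return -1;
}

// Dormand-Prince 5(4) tableau.
static const double A21 = 1.0 / 5.0;
static const double A31 = 3.0 / 40.0, A32 = 9.0 / 40.0;
static const double A41 = 44.0 / 45.0, A42 = -56.0 / 15.0, A43 = 32.0 / 9.0;
static const double A51 = 19372.0 / 6561.0, A52 = -25360.0 / 2187.0,
                    A53 = 64448.0 / 6561.0, A54 = -212.0 / 729.0;
static const double A61 = 9017.0 / 3168.0, A62 = -355.0 / 33.0,
                    A63 = 46732.0 / 5247.0, A64 = 49.0 / 176.0,
                    A65 = -5103.0 / 18656.0;
static const double B1 = 35.0 / 384.0, B3 = 500.0 / 1113.0,
                    B4 = 125.0 / 192.0, B5 = -2187.0 / 6784.0,
                    B6 = 11.0 / 84.0;
static const double E1 = 35.0 / 384.0 - 5179.0 / 57600.0,
                    E3 = 500.0 / 1113.0 - 7571.0 / 16695.0,
                    E4 = 125.0 / 192.0 - 393.0 / 640.0,
                    E5 = -2187.0 / 6784.0 + 92097.0 / 339200.0,
                    E6 = 11.0 / 84.0 - 187.0 / 2100.0,
                    E7 = -1.0 / 40.0;

// Core integrator. method: 0 = adaptive DP5(4), 1 = fixed RK4, 2 = Euler.
// Records states roughly every record_interval time units plus the final
// state. Tracks max excursion outside [0,1]^2 (before clamping) and, when
// track_saddle, the minimum distance to (sx, sy) over all accepted steps.
// [[Rcpp::export]]
List integrate_core(double a, double b, double c, double d,
                    double x0, double y0,
                    int method, double dt, double rtol, double atol,
                    double t_max, double delta, bool clamp,
                    double record_interval,
                    bool track_saddle, double sx, double sy) {
  std::vector<double> ts, xs, ys;
  double t = 0.0, x = x0, y = y0;
  double conv_time = NA_REAL;
  int corner = -1;
  double excursion = 0.0;
  double saddle_dist = R_PosInf;
  bool nonfinite = false;

  ts.push_back(t); xs.push_back(x); ys.push_back(y);
  double next_rec = record_interval;

  if (track_saddle) {
    double ddx = x - sx, ddy = y - sy;
    saddle_dist = std::sqrt(ddx * ddx + ddy * ddy);
  }

  corner = corner_test(a, b, c, d, x, y, delta);
  if (corner >= 0) conv_time = 0.0;

  double h = (method == 0) ? std::min(0.01, t_max) : dt;
  double hnext = h;
  // Cap adaptive steps at one time unit so corner-convergence times are
  // localized to within a step; the convergence-time orderings rely on it.
  const double hmin = 1e-12, hmax = std::min(1.0, t_max);
  long max_steps = (method == 0) ? 5000000L : 200000000L;
  long steps = 0;

  double fx, fy;
  while (corner < 0 && t < t_max && steps < max_steps) {
    if (t + h > t_max) h = t_max - t;
    double xn, yn;
    bool accepted = true;

    if (method == 2) {                      // Euler
      field(a, b, c, d, x, y, fx, fy);
      xn = x + h * fx;
      yn = y + h * fy;
    } else if (method == 1) {               // classical RK4
      double k1x, k1y, k2x, k2y, k3x, k3y, k4x, k4y;
      field(a, b, c, d, x, y, k1x, k1y);
      field(a, b, c, d, x + 0.5 * h * k1x, y + 0.5 * h * k1y, k2x, k2y);
      field(a, b, c, d, x + 0.5 * h * k2x, y + 0.5 * h * k2y, k3x, k3y);
      field(a, b, c, d, x + h * k3x, y + h * k3y, k4x, k4y);
      xn = x + h / 6.0 * (k1x + 2.0 * k2x + 2.0 * k3x + k4x);
      yn = y + h / 6.0 * (k1y + 2.0 * k2y + 2.0 * k3y + k4y);
    } else {                                // adaptive Dormand-Prince 5(4)
      double k1x, k1y, k2x, k2y, k3x, k3y, k4x, k4y, k5x, k5y, k6x, k6y,
             k7x, k7y;
      field(a, b, c, d, x, y, k1x, k1y);
      field(a, b, c, d, x + h * A21 * k1x, y + h * A21 * k1y, k2x, k2y);
      field(a, b, c, d, x + h * (A31 * k1x + A32 * k2x),
                        y + h * (A31 * k1y + A32 * k2y), k3x, k3y);
      field(a, b, c, d, x + h * (A41 * k1x + A42 * k2x + A43 * k3x),
                        y + h * (A41 * k1y + A42 * k2y + A43 * k3y), k4x, k4y);
      field(a, b, c, d,
            x + h * (A51 * k1x + A52 * k2x + A53 * k3x + A54 * k4x),
            y + h * (A51 * k1y + A52 * k2y + A53 * k3y + A54 * k4y), k5x, k5y);
      field(a, b, c, d,
            x + h * (A61 * k1x + A62 * k2x + A63 * k3x + A64 * k4x + A65 * k5x),
            y + h * (A61 * k1y + A62 * k2y + A63 * k3y + A64 * k4y + A65 * k5y),
            k6x, k6y);
      xn = x + h * (B1 * k1x + B3 * k3x + B4 * k4x + B5 * k5x + B6 * k6x);
      yn = y + h * (B1 * k1y + B3 * k3y + B4 * k4y + B5 * k5y + B6 * k6y);
      field(a, b, c, d, xn, yn, k7x, k7y);
      double errx = h * (E1 * k1x + E3 * k3x + E4 * k4x + E5 * k5x +
                         E6 * k6x + E7 * k7x);
      double erry = h * (E1 * k1y + E3 * k3y + E4 * k4y + E5 * k5y +
                         E6 * k6y + E7 * k7y);
      double scx = atol + rtol * std::max(std::fabs(x), std::fabs(xn));
      double scy = atol + rtol * std::max(std::fabs(y), std::fabs(yn));
      double err = std::sqrt(0.5 * ((errx / scx) * (errx / scx) +
                                    (erry / scy) * (erry / scy)));
      if (!std::isfinite(err)) { nonfinite = true; break; }
      double fac = (err > 0.0) ? 0.9 * std::pow(err, -0.2) : 5.0;
      fac = std::min(5.0, std::max(0.2, fac));
      if (err > 1.0 && h > hmin) {
        h = std::max(hmin, h * fac);
        accepted = false;
      } else {
        hnext = std::min(hmax, std::max(hmin, h * fac));
      }
    }

    ++steps;
    if (!accepted) continue;

    if (!std::isfinite(xn) || !std::isfinite(yn)) { nonfinite = true; break; }

    t += h;
    if (method == 0) h = hnext;

    double exc = std::max(std::max(-xn, xn - 1.0), std::max(-yn, yn - 1.0));
    if (exc > excursion) excursion = exc;
    if (clamp) {
      xn = std::min(1.0, std::max(0.0, xn));
      yn = std::min(1.0, std::max(0.0, yn));
    }
    x = xn; y = yn;

    if (track_saddle) {
      double ddx = x - sx, ddy = y - sy;
      double dd = std::sqrt(ddx * ddx + ddy * ddy);
      if (dd < saddle_dist) saddle_dist = dd;
    }

    if (t >= next_rec || t >= t_max) {
      ts.push_back(t); xs.push_back(x); ys.push_back(y);
      while (next_rec <= t) next_rec += record_interval;
    }

    corner = corner_test(a, b, c, d, x, y, delta);
    if (corner >= 0) conv_time = t;
  }

  if (ts.back() < t) { ts.push_back(t); xs.push_back(x); ys.push_back(y); }

  return List::create(
    _["times"] = wrap(ts), _["x"] = wrap(xs), _["y"] = wrap(ys),
    _["corner"] = corner, _["convergence_time"] = conv_time,
    _["steps"] = (double)steps, _["max_excursion"] = excursion,
    _["min_saddle_dist"] = saddle_dist, _["nonfinite"] = nonfinite);
}
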