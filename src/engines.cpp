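#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// spring restoring force laws; code: 1 hookean, 2 inverse-density, 3 inverse-density-squared
static inline double force(double ell, double k, double a, int code) {
  switch (code) {
    case 1: return k * (ell - a);
    case 2: return k * a * a * (1.0 / a - 1.0 / ell);
    default: return 0.5 * k * a * a * a * (1.0 / (a * a) - 1.0 / (ell * ell));
  }
}

// Forward Euler for the curved-spring chain in arc-length coordinates.
// s0: node coordinates (fixed: M+1 incl. pinned ends; periodic: M in [0, L)).
// record: sorted step indices (>= 0) at which to store the state.
// [[Rcpp::export]]
NumericMatrix euler_curved_cpp(NumericVector s0, double L, bool periodic,
                               double k, double a, double eta, int code,
                               double dt, IntegerVector record) {
  const int n = s0.size();
  std::vector<double> s(s0.begin(), s0.end()), f(n + 1);
  NumericMatrix out(record.size(), n);
  int ridx = 0;
  const int n_steps = record[record.size() - 1];
  if (ridx < record.size() && record[ridx] == 0) {
    for (int j = 0; j < n; ++j) out(ridx, j) = s[j];
    ++ridx;
  }
  for (int step = 1; step <= n_steps; ++step) {
    if (periodic) {
      // spring i connects node i-1 -> i; spring 0 is the seam (node n-1 -> 0)
      f[0] = force(s[0] + L - s[n - 1], k, a, code);
      for (int i = 1; i < n; ++i) {
        double ell = s[i] - s[i - 1];
        if (ell <= 0) stop("unstable step: spring %d collapsed at step %d", i + 1, step);
        f[i] = force(ell, k, a, code);
      }
      double f_last = f[0];
      for (int i = 0; i < n; ++i) {
        double fr = (i < n - 1) ? f[i + 1] : f_last;
        s[i] += dt * (fr - f[i]) / eta;
      }
      // wrap into [0, L) and re-anchor so coordinates stay increasing
      for (int i = 0; i < n; ++i) {
        s[i] -= L * std::floor(s[i] / L);
        if (s[i] >= L) s[i] -= L;   // fp edge: tiny negatives wrap to exactly L
        if (s[i] < 0) s[i] = 0;
      }
      int kmin = 0;
      for (int i = 1; i < n; ++i) if (s[i] < s[kmin]) kmin = i;
      if (kmin != 0) {
        std::vector<double> tmp(n);
        for (int i = 0; i < n; ++i) tmp[i] = s[(kmin + i) % n];
        s.swap(tmp);
      }
      for (int i = 1; i < n; ++i)
        if (s[i] <= s[i - 1])
          stop("unstable step: node ordering violated at step %d", step);
    } else {
      for (int i = 1; i < n; ++i) {
        double ell = s[i] - s[i - 1];
        if (ell <= 0) stop("unstable step: spring %d collapsed at step %d", i, step);
        f[i] = force(ell, k, a, code);
      }
      for (int i = 1; i < n - 1; ++i) s[i] += dt * (f[i + 1] - f[i]) / eta;
      s[0] = 0.0;
      s[n - 1] = L;
    }
    if (ridx < record.size() && record[ridx] == step) {
      for (int j = 0; j < n; ++j) out(ridx, j) = s[j];
      ++ridx;
    }
  }
  return out;
}

// diffusivity D(q); code: 1 -> c/q^2 (fast diffusion), 2 -> c, 3 -> c*q
static inline double diff_q(double q, double c, int code) {
  switch (code) {
    case 1: return c / (q * q);
    case 2: return c;
    default: return c * q;
  }
}

// conservative flux-form rhs; periodic grid has J points (q_J == q_0 implied),
// no-flux grid has J+1 points with mirror ghosts
static void pde_rhs(const std::vector<double>& q, std::vector<double>& dq,
                    double ds, double c, int code, bool periodic) {
  const int n = q.size();
  const double inv = 1.0 / (ds * ds);
  if (periodic) {
    for (int j = 0; j < n; ++j) {
      double qm = q[(j + n - 1) % n], qp = q[(j + 1) % n];
      double Dp = diff_q(0.5 * (q[j] + qp), c, code);
      double Dm = diff_q(0.5 * (qm + q[j]), c, code);
      dq[j] = (Dp * (qp - q[j]) - Dm * (q[j] - qm)) * inv;
    }
  } else {
    for (int j = 0; j < n; ++j) {
      double qm = (j == 0) ? q[1] : q[j - 1];
      double qp = (j == n - 1) ? q[n - 2] : q[j + 1];
      double Dp = diff_q(0.5 * (q[j] + qp), c, code);
      double Dm = diff_q(0.5 * (qm + q[j]), c, code);
      dq[j] = (Dp * (qp - q[j]) - Dm * (q[j] - qm)) * inv;
    }
  }
}

// Adaptive Dormand-Prince 5(4) for the method-of-lines diffusion system.
// [[Rcpp::export]]
NumericMatrix pde_rk45_cpp(NumericVector q0, double ds, NumericVector t_out,
                           int code, double c, bool periodic,
                           double rtol, double atol) {
  static const double A2[] = {0.2};
  static const double A3[] = {3.0 / 40, 9.0 / 40};
  static const double A4[] = {44.0 / 45, -56.0 / 15, 32.0 / 9};
  static const double A5[] = {19372.0 / 6561, -25360.0 / 2187, 64448.0 / 6561,
                              -212.0 / 729};
  static const double A6[] = {9017.0 / 3168, -355.0 / 33, 46732.0 / 5247,
                              49.0 / 176, -5103.0 / 18656};
  static const double A7[] = {35.0 / 384, 0.0, 500.0 / 1113, 125.0 / 192,
                              -2187.0 / 6784, 11.0 / 84};
  static const double* AA[] = {A2, A3, A4, A5, A6, A7};
  static const double B5[] = {35.0 / 384, 0.0, 500.0 / 1113, 125.0 / 192,
                              -2187.0 / 6784, 11.0 / 84, 0.0};
  static const double B4[] = {5179.0 / 57600, 0.0, 7571.0 / 16695, 393.0 / 640,
                              -92097.0 / 339200, 187.0 / 2100, 1.0 / 40};
  const int n = q0.size();
  std::vector<double> q(q0.begin(), q0.end()), qs(n), q5(n);
  std::vector<std::vector<double> > kk(7, std::vector<double>(n));
  NumericMatrix out(t_out.size(), n);

  double Dmax = 0.0;
  for (int j = 0; j < n; ++j) Dmax = std::max(Dmax, diff_q(q[j], c, code));
  double t = 0.0, dt = 0.4 * ds * ds / std::max(Dmax, 1e-300);

  for (int i = 0; i < t_out.size(); ++i) {
    const double tf = t_out[i];
    while (t < tf - 1e-14 * std::max(tf, 1.0)) {
      double h = std::min(dt, tf - t);
      pde_rhs(q, kk[0], ds, c, code, periodic);
      bool positive = true;
      for (int st = 0; st < 6 && positive; ++st) {
        for (int j = 0; j < n; ++j) {
          double acc = q[j];
          for (int m = 0; m <= st; ++m) acc += h * AA[st][m] * kk[m][j];
          qs[j] = acc;
          if (acc <= 0) positive = false;
        }
        if (positive) pde_rhs(qs, kk[st + 1], ds, c, code, periodic);
      }
      if (!positive) {
        if (h < 1e-14)
          stop("solver failure: negative density; reduce tolerance or grid spacing");
        dt = h * 0.5;
        continue;
      }
      double err = 0.0;
      for (int j = 0; j < n; ++j) {
        double acc = q[j], e = 0.0;
        for (int m = 0; m < 7; ++m) {
          acc += h * B5[m] * kk[m][j];
          e += h * (B5[m] - B4[m]) * kk[m][j];
        }
        q5[j] = acc;
        double sc = atol + rtol * std::max(std::fabs(q[j]), std::fabs(acc));
        err += (e / sc) * (e / sc);
        if (acc <= 0) positive = false;
      }
      err = std::sqrt(err / n);
      if (err <= 1.0 && positive) {
        q.swap(q5);
        t += h;
        double fac = 0.9 * std::pow(std::max(err, 1e-10), -0.2);
        dt = h * std::min(5.0, std::max(0.2, fac));
      } else {
        if (h < 1e-14)
          stop("solver failure: step size underflow; reduce tolerance");
        dt = positive ? h * std::max(0.1, 0.9 * std::pow(err, -0.2)) : h * 0.5;
      }
    }
    for (int j = 0; j < n; ++j) out(i, j) = q[j];
  }
  return out;
}
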