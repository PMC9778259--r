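#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double soft_c(double z, double l) {
  if (z > l) return z - l;
  if (z < -l) return z + l;
  return 0.0;
}

// univariate SCAD rule for (1/2)(z - b)^2 + P_{a,l}(|b|), a > 2
static inline double scad_c(double z, double l, double a) {
  double az = std::fabs(z);
  if (az <= 2.0 * l) return soft_c(z, l);
  if (az <= a * l) return ((a - 1.0) * z - ((z > 0) - (z < 0)) * a * l) /
                          (a - 2.0);
  return z;
}

// firm (MCP) rule for (1/2)(z - b)^2 + P_{a,l}(|b|), a > 1
static inline double mcp_c(double z, double l, double a) {
  double az = std::fabs(z);
  if (az <= l) return 0.0;
  if (az <= a * l) return soft_c(z, l) / (1.0 - 1.0 / a);
  return z;
}

// Cyclic coordinate descent for
//   (1/(2n)) ||y - X b||^2 + l1 * sum_j w_j pen(|b_j|) + (l2/2) ||b||^2
// family: 1 = L1 (lasso / adaptive lasso / elasticnet L1 part),
//         2 = SCAD, 3 = MCP (both require unit column scale, l2 = 0).
// Returns the coefficient vector, sweeps used, convergence flag and, when
// trace is true, the penalized objective after every sweep.
// [[Rcpp::export]]
List cd_solve(NumericMatrix X, NumericVector y, NumericVector w,
              double l1, double l2, double alpha, int family,
              NumericVector init, double tol, int maxit, bool trace) {
  const int n = X.nrow(), k = X.ncol();
  std::vector<double> b(init.begin(), init.end());
  std::vector<double> v(k);
  std::vector<double> r(n);

  for (int j = 0; j < k; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    v[j] = s / n;
  }
  for (int i = 0; i < n; ++i) {
    double fit = 0.0;
    for (int j = 0; j < k; ++j) fit += X(i, j) * b[j];
    r[i] = y[i] - fit;
  }

  std::vector<double> objs;
  bool converged = false;
  int sweeps = 0;
  for (int it = 0; it < maxit; ++it) {
    double maxdel = 0.0;
    for (int j = 0; j < k; ++j) {
      if (v[j] <= 0.0) { b[j] = 0.0; continue; }
      double xr = 0.0;
      for (int i = 0; i < n; ++i) xr += X(i, j) * r[i];
      double z = xr / n + v[j] * b[j];
      double bnew;
      if (family == 2)      bnew = scad_c(z, l1 * w[j], alpha);
      else if (family == 3) bnew = mcp_c(z, l1 * w[j], alpha);
      else                  bnew = soft_c(z, l1 * w[j]) / (v[j] + l2);
      double del = bnew - b[j];
      if (del != 0.0) {
        for (int i = 0; i < n; ++i) r[i] -= del * X(i, j);
        b[j] = bnew;
        double ad = std::fabs(del);
        if (ad > maxdel) maxdel = ad;
      }
    }
    ++sweeps;
    if (trace) {
      double rss = 0.0;
      for (int i = 0; i < n; ++i) rss += r[i] * r[i];
      double pen = 0.0;
      for (int j = 0; j < k; ++j) {
        pen += l1 * w[j] * std::fabs(b[j]) + 0.5 * l2 * b[j] * b[j];
      }
      objs.push_back(rss / (2.0 * n) + pen);
    }
    if (maxdel < tol) { converged = true; break; }
  }

  return List::create(_["beta"] = NumericVector(b.begin(), b.end()),
                      _["n_iter"] = sweeps,
                      _["converged"] = converged,
                      _["obj_trace"] = NumericVector(objs.begin(),
                                                     objs.end()));
}
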