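// Exact single-covariate quantile regression via subgradient bisection on
// the profiled (convex, piecewise-linear) objective in the slope.
// Mirrors the R reference implementation in R/quantreg.R.
#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

// tau-th order statistic of r (lower endpoint of the minimising interval
// for the intercept at fixed slope)
double tau_intercept(std::vector<double> r, double tau) {
  const int n = r.size();
  int k = (int)std::ceil(tau * n);
  if (k < 1) k = 1;
  if (k > n) k = n;
  std::nth_element(r.begin(), r.begin() + (k - 1), r.end());
  return r[k - 1];
}

// subgradient interval [lo, hi] of G(b) = min_a sum rho_tau(y - a - b x)
void profile_subgradient(const NumericVector& x, const NumericVector& y,
                         double b, double tau, double& lo, double& hi) {
  const int n = x.size();
  std::vector<double> r(n);
  double rmax = 0.0;
  for (int i = 0; i < n; ++i) {
    r[i] = y[i] - b * x[i];
    rmax = std::max(rmax, std::fabs(r[i]));
  }
  const double a = tau_intercept(r, tau);
  const double tol = 1e-10 * (rmax + 1.0);

  double Fs = 0.0, Fx = 0.0;
  std::vector<double> xz;
  for (int i = 0; i < n; ++i) {
    const double e = r[i] - a;
    if (std::fabs(e) <= tol) {
      xz.push_back(x[i]);
    } else {
      const double s = (e > 0) ? tau : (tau - 1.0);
      Fs += s;
      Fx += x[i] * s;
    }
  }
  const int nz = xz.size();
  if (nz == 0) {
    lo = hi = -Fx;
    return;
  }
  double U = -Fs - nz * (tau - 1.0);
  if (U < 0.0) U = 0.0;
  if (U > nz) U = nz;
  double base = 0.0;
  for (double v : xz) base += v;
  base *= (tau - 1.0);

  std::sort(xz.begin(), xz.end()); // ascending
  double left, smin = 0.0, smax = 0.0;
  left = U;
  for (int i = 0; i < nz && left > 0; ++i) { // smallest x first -> min
    const double take = std::min(1.0, left);
    smin += xz[i] * take;
    left -= take;
  }
  left = U;
  for (int i = nz - 1; i >= 0 && left > 0; --i) { // largest x first -> max
    const double take = std::min(1.0, left);
    smax += xz[i] * take;
    left -= take;
  }
  lo = -(Fx + base + smax);
  hi = -(Fx + base + smin);
}

int sgn_at(const NumericVector& x, const NumericVector& y, double b, double tau) {
  double lo, hi;
  profile_subgradient(x, y, b, tau, lo, hi);
  if (hi < 0) return -1;
  if (lo > 0) return 1;
  return 0;
}

} // namespace

// [[Rcpp::export]]
List qfit_cpp(NumericVector x, NumericVector y, double tau) {
  const int n = x.size();
  if (n < 3) stop("quantile_fit needs at least 3 complete observations.");
  double xmin = x[0], xmax = x[0];
  for (int i = 1; i < n; ++i) {
    xmin = std::min(xmin, x[i]);
    xmax = std::max(xmax, x[i]);
  }
  if ((xmax - xmin) <= 1e-10 * std::max(1.0, std::max(std::fabs(xmax), std::fabs(xmin)))) {
    stop("`x` is constant; the slope is unidentified.");
  }

  // least-squares start
  double mx = 0, my = 0;
  for (int i = 0; i < n; ++i) { mx += x[i]; my += y[i]; }
  mx /= n; my /= n;
  double sxx = 0, sxy = 0, syy = 0;
  for (int i = 0; i < n; ++i) {
    sxx += (x[i] - mx) * (x[i] - mx);
    sxy += (x[i] - mx) * (y[i] - my);
    syy += (y[i] - my) * (y[i] - my);
  }
  double b0 = sxy / sxx;
  double step = std::max(1.0, 4.0 * (std::sqrt(syy / (n - 1)) + 1e-12) /
                                  (std::sqrt(sxx / (n - 1)) + 1e-12));

  double b_opt;
  int s0 = sgn_at(x, y, b0, tau);
  if (s0 == 0) {
    b_opt = b0;
  } else {
    double lo = b0, hi = b0;
    int guard = 0;
    if (s0 < 0) {
      hi = b0 + step;
      while (sgn_at(x, y, hi, tau) < 0) {
        lo = hi; hi += step; step *= 2;
        if (++guard > 200) stop("quantile_fit: slope bracket failed to close (data may be degenerate).");
      }
    } else {
      lo = b0 - step;
      while (sgn_at(x, y, lo, tau) > 0) {
        hi = lo; lo -= step; step *= 2;
        if (++guard > 200) stop("quantile_fit: slope bracket failed to close (data may be degenerate).");
      }
    }
    b_opt = 0.5 * (lo + hi);
    for (int it = 0; it < 200; ++it) {
      const double mid = 0.5 * (lo + hi);
      const int sm = sgn_at(x, y, mid, tau);
      if (sm == 0) { b_opt = mid; break; }
      if (sm < 0) lo = mid; else hi = mid;
      b_opt = 0.5 * (lo + hi);
      if (hi - lo < 1e-12 * (1.0 + std::fabs(lo) + std::fabs(hi))) break;
    }
  }

  std::vector<double> r(n);
  for (int i = 0; i < n; ++i) r[i] = y[i] - b_opt * x[i];
  const double a_opt = tau_intercept(r, tau);
  double obj = 0.0;
  for (int i = 0; i < n; ++i) {
    const double e = r[i] - a_opt;
    obj += e * (tau - (e < 0 ? 1.0 : 0.0));
  }
  return List::create(
    _["intercept"] = a_opt, _["slope"] = b_opt,
    _["objective"] = obj, _["tau"] = tau, _["n"] = n
  );
}
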