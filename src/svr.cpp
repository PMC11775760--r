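// Epsilon-SVR with RBF kernel, solved by SMO on the 2n-variable dual
// (maximal-violating-pair working-set selection, LIBSVM-style).  Inputs are
// expected pre-standardized by the R wrapper; n is small (tens), so the
// full kernel matrix is precomputed.
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
List cpp_svr_fit(NumericMatrix X, NumericVector y, double cost, double gamma,
                 double epsilon, double tol, int max_iter) {
  int n = X.nrow(), p = X.ncol();
  // kernel matrix
  NumericMatrix K(n, n);
  for (int i = 0; i < n; ++i) {
    K(i, i) = 1.0;
    for (int j = i + 1; j < n; ++j) {
      double s = 0.0;
      for (int f = 0; f < p; ++f) {
        double d = X(i, f) - X(j, f);
        s += d * d;
      }
      double k = std::exp(-gamma * s);
      K(i, j) = k;
      K(j, i) = k;
    }
  }
  // 2n variables: a[t] in [0, C]; z[t] = +1 (t<n, alpha), -1 (t>=n, alpha*)
  int m = 2 * n;
  std::vector<double> a(m, 0.0), G(m), z(m), lin(m);
  for (int t = 0; t < m; ++t) {
    int i = t % n;
    z[t] = t < n ? 1.0 : -1.0;
    lin[t] = t < n ? (epsilon - y[i]) : (epsilon + y[i]);
    G[t] = lin[t]; // all a start at 0
  }
  auto Q = [&](int s, int t) { return z[s] * z[t] * K(s % n, t % n); };
  int iter = 0;
  double gmax = 0.0, gmin = 0.0;
  for (; iter < max_iter; ++iter) {
    // working-set selection: maximal violator i, then second-order j
    // (largest guaranteed objective decrease), LIBSVM WSS2
    int i = -1, j = -1;
    gmax = -1e300;
    gmin = 1e300;
    for (int t = 0; t < m; ++t) {
      bool up = (z[t] > 0) ? (a[t] < cost) : (a[t] > 0);
      double v = -z[t] * G[t];
      if (up && v > gmax) { gmax = v; i = t; }
    }
    double best_gain = -1.0;
    for (int t = 0; t < m; ++t) {
      bool low = (z[t] > 0) ? (a[t] > 0) : (a[t] < cost);
      if (!low) continue;
      double v = -z[t] * G[t];
      if (v < gmin) gmin = v;
      if (i >= 0 && v < gmax) {
        double b2 = gmax - v;
        double eta2 = K(i % n, i % n) + K(t % n, t % n) -
                      2.0 * K(i % n, t % n);
        if (eta2 < 1e-12) eta2 = 1e-12;
        double gain = b2 * b2 / eta2;
        if (gain > best_gain) { best_gain = gain; j = t; }
      }
    }
    if (i < 0 || j < 0 || gmax - gmin < tol) break;
    // step s along (da_i, da_j) = (z_i s, -z_j s)
    double eta = K(i % n, i % n) + K(j % n, j % n) - 2.0 * K(i % n, j % n);
    if (eta < 1e-12) eta = 1e-12;
    double s = (gmax - gmin) / eta; // = -(z_i G_i - z_j G_j)/eta
    // box constraints on s
    double lo = -1e300, hi = 1e300;
    if (z[i] > 0) { lo = std::max(lo, -a[i]); hi = std::min(hi, cost - a[i]); }
    else          { lo = std::max(lo, a[i] - cost); hi = std::min(hi, a[i]); }
    if (z[j] > 0) { lo = std::max(lo, a[j] - cost); hi = std::min(hi, a[j]); }
    else          { lo = std::max(lo, -a[j]); hi = std::min(hi, cost - a[j]); }
    if (s < lo) s = lo;
    if (s > hi) s = hi;
    double dai = z[i] * s, daj = -z[j] * s;
    a[i] += dai;
    a[j] += daj;
    for (int t = 0; t < m; ++t) G[t] += Q(t, i) * dai + Q(t, j) * daj;
  }
  if (gmax < -1e299) gmax = gmin;
  if (gmin > 1e299) gmin = gmax;
  double b = (gmax + gmin) / 2.0;
  NumericVector beta(n);
  for (int i = 0; i < n; ++i) beta[i] = a[i] - a[n + i];
  return List::create(_["beta"] = beta, _["b"] = b, _["iterations"] = iter,
                      _["gap"] = gmax - gmin);
}

// [[Rcpp::export]]
NumericVector cpp_svr_predict(NumericMatrix Xtrain, NumericVector beta,
                              double b, double gamma, NumericMatrix Xnew) {
  int n = Xtrain.nrow(), p = Xtrain.ncol(), nn = Xnew.nrow();
  NumericVector out(nn);
  for (int i = 0; i < nn; ++i) {
    double f = b;
    for (int j = 0; j < n; ++j) {
      if (beta[j] == 0.0) continue;
      double s = 0.0;
      for (int ff = 0; ff < p; ++ff) {
        double d = Xnew(i, ff) - Xtrain(j, ff);
        s += d * d;
      }
      f += beta[j] * std::exp(-gamma * s);
    }
    out[i] = f;
  }
  return out;
}
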