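// Simple kriging and sequential Gaussian simulation kernels.
// Covariance convention: C(0) = nugget + psill, C(h>0) = psill * rho(h),
// i.e. gamma(h) = sill - C(h) with the nugget discontinuity at the origin.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

// structural correlation (without partial sill), effective-range forms
inline double rho_struct(double h, double range_a, int kind) {
  if (h <= 0.0) return 1.0;
  double u = h / range_a;
  switch (kind) {
  case 1: // spherical
    if (u >= 1.0) return 0.0;
    return 1.0 - (1.5 * u - 0.5 * u * u * u);
  case 2: // exponential, effective range = 3 * (a/3)
    return std::exp(-3.0 * u);
  default: // gaussian
    return std::exp(-3.0 * u * u);
  }
}

inline double cov_fun(double h, double nugget, double psill, double range_a,
                      int kind) {
  if (h <= 0.0) return nugget + psill;
  return psill * rho_struct(h, range_a, kind);
}

// indices of the k smallest entries of d among m candidates (partial sort)
void k_nearest(const std::vector<double>& d, int k, std::vector<int>& out) {
  int m = (int)d.size();
  out.resize(m);
  for (int i = 0; i < m; ++i) out[i] = i;
  if (k < m) {
    std::nth_element(out.begin(), out.begin() + k, out.end(),
                     [&](int a, int b) { return d[a] < d[b]; });
    out.resize(k);
  }
  std::sort(out.begin(), out.end(),
            [&](int a, int b) { return d[a] < d[b]; });
}

// solve SK system for one target; returns estimate/variance, jitter count
void sk_solve(const std::vector<double>& nx, const std::vector<double>& ny,
              const std::vector<double>& nz, double tx, double ty,
              double nugget, double psill, double range_a, int kind,
              double& est, double& var, long& n_jitter) {
  int k = (int)nx.size();
  double sill = nugget + psill;
  if (k == 0) { est = 0.0; var = sill; return; }
  arma::mat A(k, k);
  arma::vec b(k);
  for (int i = 0; i < k; ++i) {
    for (int j = i; j < k; ++j) {
      double dx = nx[i] - nx[j], dy = ny[i] - ny[j];
      double c = cov_fun(std::sqrt(dx * dx + dy * dy), nugget, psill,
                         range_a, kind);
      A(i, j) = c;
      A(j, i) = c;
    }
    double dx = nx[i] - tx, dy = ny[i] - ty;
    b(i) = cov_fun(std::sqrt(dx * dx + dy * dy), nugget, psill, range_a, kind);
  }
  arma::vec lambda;
  bool ok = arma::solve(lambda, A, b, arma::solve_opts::no_approx);
  if (!ok) {
    ++n_jitter;
    A.diag() += 1e-10 * sill;
    ok = arma::solve(lambda, A, b, arma::solve_opts::no_approx);
    if (!ok) { // last resort: heavier ridge
      A.diag() += 1e-6 * sill;
      lambda = arma::solve(A, b);
    }
  }
  est = 0.0;
  var = sill;
  for (int i = 0; i < k; ++i) {
    est += lambda(i) * nz[i];
    var -= lambda(i) * b(i);
  }
  if (var < 0.0) var = 0.0;
  if (var > sill) var = sill;
}

} // namespace

// [[Rcpp::export]]
List cpp_sk_grid(NumericVector dx, NumericVector dy, NumericVector dz,
                 int nrow, int ncol, double pixel_size, double nugget,
                 double psill, double range_a, int kind, int neighbors) {
  int n = dx.size();
  NumericMatrix est(nrow, ncol), var(nrow, ncol);
  long n_jitter = 0;
  std::vector<double> d(n);
  std::vector<int> idx;
  std::vector<double> nx, ny, nz;
  for (int r = 0; r < nrow; ++r) {
    double ty = (r + 0.5) * pixel_size;
    for (int c = 0; c < ncol; ++c) {
      double tx = (c + 0.5) * pixel_size;
      for (int i = 0; i < n; ++i) {
        double ddx = dx[i] - tx, ddy = dy[i] - ty;
        d[i] = ddx * ddx + ddy * ddy;
      }
      k_nearest(d, neighbors, idx);
      int k = (int)idx.size();
      nx.resize(k); ny.resize(k); nz.resize(k);
      for (int i = 0; i < k; ++i) {
        nx[i] = dx[idx[i]]; ny[i] = dy[idx[i]]; nz[i] = dz[idx[i]];
      }
      double e, v;
      sk_solve(nx, ny, nz, tx, ty, nugget, psill, range_a, kind, e, v,
               n_jitter);
      est(r, c) = e;
      var(r, c) = v;
    }
  }
  return List::create(_["estimate"] = est, _["variance"] = var,
                      _["n_jitter"] = n_jitter);
}

namespace {

// bucket-grid spatial index over a growing point set (expanding-ring
// k-nearest queries; the sequential simulation pool grows to the full
// grid, so brute-force scans are quadratic and dominate runtime)
struct BucketIndex {
  double cell, x0, y0;
  int ncx, ncy;
  std::vector<std::vector<int>> cells;
  const std::vector<double>* px;
  const std::vector<double>* py;

  void init(double xmin, double ymin, double xmax, double ymax,
            int expected, const std::vector<double>* xs,
            const std::vector<double>* ys) {
    px = xs;
    py = ys;
    double area = std::max(xmax - xmin, 1e-9) *
                  std::max(ymax - ymin, 1e-9);
    cell = std::sqrt(area / std::max(expected, 1)) * 1.5;
    if (cell <= 0) cell = 1.0;
    x0 = xmin; y0 = ymin;
    ncx = std::max(1, (int)std::ceil((xmax - xmin) / cell));
    ncy = std::max(1, (int)std::ceil((ymax - ymin) / cell));
    cells.assign((size_t)ncx * ncy, {});
  }
  inline int cell_of(double x, double y) const {
    int cx = (int)((x - x0) / cell);
    int cy = (int)((y - y0) / cell);
    cx = std::min(std::max(cx, 0), ncx - 1);
    cy = std::min(std::max(cy, 0), ncy - 1);
    return cy * ncx + cx;
  }
  void insert(int id) { cells[cell_of((*px)[id], (*py)[id])].push_back(id); }

  // k nearest point ids to (x, y), sorted by distance
  void query(double x, double y, int k, std::vector<int>& out) const {
    int cx = std::min(std::max((int)((x - x0) / cell), 0), ncx - 1);
    int cy = std::min(std::max((int)((y - y0) / cell), 0), ncy - 1);
    // max-heap of the k best (squared distance, id)
    std::vector<std::pair<double, int>> heap;
    heap.reserve(k + 1);
    int max_ring = std::max(ncx, ncy);
    for (int ring = 0; ring <= max_ring; ++ring) {
      if ((int)heap.size() == k) {
        double reach = (double)(ring - 1) * cell; // closest possible point
        if (reach > 0 && reach * reach > heap.front().first) break;
      }
      int xlo = cx - ring, xhi = cx + ring;
      int ylo = cy - ring, yhi = cy + ring;
      for (int gy = ylo; gy <= yhi; ++gy) {
        if (gy < 0 || gy >= ncy) continue;
        bool edge_row = (gy == ylo || gy == yhi);
        for (int gx = xlo; gx <= xhi; ++gx) {
          if (gx < 0 || gx >= ncx) continue;
          if (!edge_row && gx != xlo && gx != xhi) continue; // ring only
          const std::vector<int>& bucket = cells[(size_t)gy * ncx + gx];
          for (int id : bucket) {
            double ddx = (*px)[id] - x, ddy = (*py)[id] - y;
            double d2 = ddx * ddx + ddy * ddy;
            if ((int)heap.size() < k) {
              heap.emplace_back(d2, id);
              std::push_heap(heap.begin(), heap.end());
            } else if (d2 < heap.front().first) {
              std::pop_heap(heap.begin(), heap.end());
              heap.back() = std::make_pair(d2, id);
              std::push_heap(heap.begin(), heap.end());
            }
          }
        }
      }
    }
    std::sort_heap(heap.begin(), heap.end());
    out.resize(heap.size());
    for (size_t i = 0; i < heap.size(); ++i) out[i] = heap[i].second;
  }
};

} // namespace

// One SGS realization on the node centers of a regular grid.
// fixed: length nrow*ncol (column-major), NaN = free node, else the node is
// pinned at that (normal-score) value.  path: 0-based column-major indices
// of the free nodes in visit order.  noise: standard-normal draw per free
// node (consumed in path order) so all randomness stays with the caller.
// [[Rcpp::export]]
NumericMatrix cpp_sgcs_realization(NumericVector dx, NumericVector dy,
                                   NumericVector dz, int nrow, int ncol,
                                   double pixel_size, NumericVector fixed,
                                   IntegerVector path, NumericVector noise,
                                   double nugget, double psill,
                                   double range_a, int kind, int neighbors) {
  int n = dx.size();
  NumericMatrix sim(nrow, ncol);
  // conditioning pool: original data first, then pinned + simulated nodes
  std::vector<double> px(dx.begin(), dx.end());
  std::vector<double> py(dy.begin(), dy.end());
  std::vector<double> pz(dz.begin(), dz.end());
  int total = n + nrow * ncol;
  px.reserve(total);
  py.reserve(total);
  pz.reserve(total);
  BucketIndex bix;
  {
    double xmin = 0, ymin = 0;
    double xmax = ncol * pixel_size, ymax = nrow * pixel_size;
    for (int i = 0; i < n; ++i) {
      xmin = std::min(xmin, dx[i]); xmax = std::max(xmax, dx[i]);
      ymin = std::min(ymin, dy[i]); ymax = std::max(ymax, dy[i]);
    }
    bix.init(xmin, ymin, xmax, ymax, total, &px, &py);
  }
  for (int i = 0; i < n; ++i) bix.insert(i);
  for (int j = 0; j < nrow * ncol; ++j) {
    double f = fixed[j];
    int r = j % nrow, c = j / nrow;
    if (!ISNAN(f)) {
      sim(r, c) = f;
      px.push_back((c + 0.5) * pixel_size);
      py.push_back((r + 0.5) * pixel_size);
      pz.push_back(f);
      bix.insert((int)px.size() - 1);
    }
  }
  long n_jitter = 0;
  std::vector<int> idx;
  std::vector<double> nx, ny, nz;
  int nfree = path.size();
  for (int t = 0; t < nfree; ++t) {
    int j = path[t];
    int r = j % nrow, c = j / nrow;
    double tx = (c + 0.5) * pixel_size, ty = (r + 0.5) * pixel_size;
    bix.query(tx, ty, neighbors, idx);
    int k = (int)idx.size();
    nx.resize(k); ny.resize(k); nz.resize(k);
    for (int i = 0; i < k; ++i) {
      nx[i] = px[idx[i]]; ny[i] = py[idx[i]]; nz[i] = pz[idx[i]];
    }
    double e, v;
    sk_solve(nx, ny, nz, tx, ty, nugget, psill, range_a, kind, e, v,
             n_jitter);
    double val = e + std::sqrt(v) * noise[t];
    sim(r, c) = val;
    px.push_back(tx);
    py.push_back(ty);
    pz.push_back(val);
    bix.insert((int)px.size() - 1);
  }
  return sim;
}

// Exhaustive pairwise semivariance binned by Euclidean distance.
// Bin k (1-based in R) covers [k*lag_width, (k+1)*lag_width) with k from 0.
// [[Rcpp::export]]
List cpp_empirical_variogram(NumericVector x, NumericVector y,
                             NumericVector z, double lag_width,
                             double max_lag) {
  int n = x.size();
  int nbin = (int)std::ceil(max_lag / lag_width);
  std::vector<double> gsum(nbin, 0.0), hsum(nbin, 0.0);
  std::vector<double> cnt(nbin, 0.0);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double ddx = x[i] - x[j], ddy = y[i] - y[j];
      double h = std::sqrt(ddx * ddx + ddy * ddy);
      if (h >= max_lag) continue;
      int b = (int)std::floor(h / lag_width);
      if (b < 0 || b >= nbin) continue;
      double dz = z[i] - z[j];
      gsum[b] += dz * dz;
      hsum[b] += h;
      cnt[b] += 1.0;
    }
  }
  NumericVector gamma(nbin), lag(nbin), npairs(nbin);
  for (int b = 0; b < nbin; ++b) {
    npairs[b] = cnt[b];
    lag[b] = cnt[b] > 0 ? hsum[b] / cnt[b] : (b + 0.5) * lag_width;
    gamma[b] = cnt[b] > 0 ? gsum[b] / (2.0 * cnt[b]) : NA_REAL;
  }
  return List::create(_["lag"] = lag, _["gamma"] = gamma,
                      _["n_pairs"] = npairs);
}
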