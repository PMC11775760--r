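// Sliding-window gray-level co-occurrence textures.
// Input is already quantized to integer levels 0..L-1; edges are handled by
// mirror (symmetric) padding; per window the co-occurrence counts of the
// requested orientations are accumulated symmetrically, the orientation
// matrices averaged, normalized to probabilities, and the eight classic
// statistics evaluated.
#include <Rcpp.h>
using namespace Rcpp;

namespace {
inline int reflect(int i, int n) {
  // symmetric padding: -1 -> 0, n -> n-1
  while (i < 0 || i >= n) {
    if (i < 0) i = -1 - i;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}
} // namespace

// [[Rcpp::export]]
List cpp_glcm_textures(IntegerMatrix q, int levels, int window,
                       IntegerMatrix offsets, bool symmetric) {
  int nr = q.nrow(), nc = q.ncol();
  int half = window / 2;
  int no = offsets.nrow();
  NumericMatrix f_mean(nr, nc), f_var(nr, nc), f_hom(nr, nc), f_con(nr, nc),
      f_dis(nr, nc), f_ent(nr, nc), f_sm(nr, nc), f_cor(nr, nc);
  LogicalMatrix flat(nr, nc);
  std::vector<double> buf((size_t)levels * levels, 0.0);
  std::vector<int> touched;
  touched.reserve(2 * window * window * no);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      // reset touched cells
      for (size_t t = 0; t < touched.size(); ++t) buf[touched[t]] = 0.0;
      touched.clear();
      double total = 0.0;
      for (int o = 0; o < no; ++o) {
        int dr = offsets(o, 0), dc = offsets(o, 1);
        for (int wr = -half; wr <= half; ++wr) {
          for (int wc = -half; wc <= half; ++wc) {
            // both pixels of the pair must lie inside the window
            int wr2 = wr + dr, wc2 = wc + dc;
            if (wr2 < -half || wr2 > half || wc2 < -half || wc2 > half)
              continue;
            int a = q(reflect(r + wr, nr), reflect(c + wc, nc));
            int b = q(reflect(r + wr2, nr), reflect(c + wc2, nc));
            size_t k1 = (size_t)a * levels + b;
            if (buf[k1] == 0.0) touched.push_back((int)k1);
            buf[k1] += 1.0;
            total += 1.0;
            if (symmetric) {
              size_t k2 = (size_t)b * levels + a;
              if (buf[k2] == 0.0) touched.push_back((int)k2);
              buf[k2] += 1.0;
              total += 1.0;
            }
          }
        }
      }
      double mean = 0, varr = 0, hom = 0, con = 0, dis = 0, ent = 0, sm = 0;
      double mi = 0, mj = 0;
      if (total > 0) {
        for (size_t t = 0; t < touched.size(); ++t) {
          int k = touched[t];
          double p = buf[k] / total;
          int i = k / levels, j = k % levels;
          mi += i * p;
          mj += j * p;
          hom += p / (1.0 + (i - j) * (i - j));
          con += p * (i - j) * (i - j);
          dis += p * std::abs(i - j);
          ent -= p * std::log(p); // p>0 on touched cells; 0*log0 := 0
          sm += p * p;
        }
        double vi = 0, vj = 0, cov = 0;
        for (size_t t = 0; t < touched.size(); ++t) {
          int k = touched[t];
          double p = buf[k] / total;
          int i = k / levels, j = k % levels;
          vi += p * (i - mi) * (i - mi);
          vj += p * (j - mj) * (j - mj);
          cov += p * (i - mi) * (j - mj);
        }
        mean = mi; // symmetric GLCM: row mean == col mean
        varr = vi;
        if (vi > 0 && vj > 0) {
          f_cor(r, c) = cov / std::sqrt(vi * vj);
        } else {
          f_cor(r, c) = 0.0; // zero-variance window, flagged
          flat(r, c) = true;
        }
      }
      f_mean(r, c) = mean;
      f_var(r, c) = varr;
      f_hom(r, c) = hom;
      f_con(r, c) = con;
      f_dis(r, c) = dis;
      f_ent(r, c) = ent;
      f_sm(r, c) = sm;
    }
  }
  return List::create(
      _["Mean"] = f_mean, _["Variance"] = f_var, _["Homogeneity"] = f_hom,
      _["Contrast"] = f_con, _["Dissimilarity"] = f_dis, _["Entropy"] = f_ent,
      _["SecondMoment"] = f_sm, _["Correlation"] = f_cor,
      _["flat_flag"] = flat);
}
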