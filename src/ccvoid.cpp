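#include <Rcpp.h>
using namespace Rcpp;

// Difference between the distances to the second-nearest and nearest seed,
// evaluated at every pixel centre of an nrow x ncol grid (units: pixels).
// Thresholding this field yields a band around the Voronoi edges of the seed
// set, which is the synthetic capillary meshwork. Brute force over seeds is
// fine at the problem sizes used (<= ~2e3 seeds on a 300 px grid).
// [[Rcpp::export]]
NumericMatrix nearest_two_diff(int nrow, int ncol, NumericVector sx, NumericVector sy) {
  const int ns = sx.size();
  if (ns < 2) stop("need at least two seeds");
  NumericMatrix out(nrow, ncol);
  for (int j = 0; j < ncol; ++j) {
    const double px = j + 1.0;
    for (int i = 0; i < nrow; ++i) {
      const double py = i + 1.0;
      double d1 = R_PosInf, d2 = R_PosInf;
      for (int s = 0; s < ns; ++s) {
        const double dx = sx[s] - px, dy = sy[s] - py;
        const double d = dx * dx + dy * dy;
        if (d < d1) { d2 = d1; d1 = d; } else if (d < d2) { d2 = d; }
      }
      out(i, j) = std::sqrt(d2) - std::sqrt(d1);
    }
  }
  return out;
}

static inline int nb(const IntegerMatrix &m, int i, int j) {
  if (i < 0 || j < 0 || i >= m.nrow() || j >= m.ncol()) return 0;
  return m(i, j);
}

// Zhang-Suen topology-preserving thinning of a binary image down to a
// one-pixel-wide skeleton.
// [[Rcpp::export]]
LogicalMatrix zhang_suen_thin(LogicalMatrix img) {
  const int nr = img.nrow(), nc = img.ncol();
  IntegerMatrix m(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) m(i, j) = img(i, j) ? 1 : 0;

  bool changed = true;
  std::vector<int> di, dj;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      di.clear(); dj.clear();
      for (int j = 0; j < nc; ++j) {
        for (int i = 0; i < nr; ++i) {
          if (!m(i, j)) continue;
          // neighbours clockwise from north: P2..P9
          int p2 = nb(m, i - 1, j),     p3 = nb(m, i - 1, j + 1);
          int p4 = nb(m, i,     j + 1), p5 = nb(m, i + 1, j + 1);
          int p6 = nb(m, i + 1, j),     p7 = nb(m, i + 1, j - 1);
          int p8 = nb(m, i,     j - 1), p9 = nb(m, i - 1, j - 1);
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int A = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                  (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                  (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                  (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (A != 1) continue;
          if (pass == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          di.push_back(i); dj.push_back(j);
        }
      }
      if (!di.empty()) {
        changed = true;
        for (size_t k = 0; k < di.size(); ++k) m(di[k], dj[k]) = 0;
      }
    }
  }
  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) out(i, j) = m(i, j) == 1;
  return out;
}
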