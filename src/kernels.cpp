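#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Fold an arbitrary integer index into [0, n) by symmetric (edge
// repeating) reflection with period 2n.
static inline int fold_idx(int i, int n) {
  int j = i % (2 * n);
  if (j < 0) j += 2 * n;
  return (j < n) ? j : 2 * n - 1 - j;
}

// Column filtering (along rows) with symmetric extension; optionally
// decimate by two (keep even output rows). Correlation convention with
// front offset floor(L/2), matching the pure definition used by the
// transform.
// [[Rcpp::export]]
NumericMatrix cpp_filt_cols(NumericMatrix X, NumericVector h,
                            bool decimate) {
  const int n = X.nrow(), p = X.ncol(), L = h.size();
  const int q = L / 2;
  const int step = decimate ? 2 : 1;
  const int nout = decimate ? (n + 1) / 2 : n;
  NumericMatrix Y(nout, p);
  std::vector<int> idx(n + L);
  for (int i = 0; i < n + L; ++i) idx[i] = fold_idx(i - q, n);
  for (int c = 0; c < p; ++c) {
    const double* x = &X(0, c);
    double* y = &Y(0, c);
    for (int i = 0, o = 0; i < n; i += step, ++o) {
      double acc = 0.0;
      for (int k = 0; k < L; ++k) acc += h[k] * x[idx[i + k]];
      y[o] = acc;
    }
  }
  return Y;
}

// Filtering along the second axis (each row vector), same conventions as
// cpp_filt_cols.
// [[Rcpp::export]]
NumericMatrix cpp_filt_rows(NumericMatrix X, NumericVector h,
                            bool decimate) {
  const int n = X.nrow(), w = X.ncol(), L = h.size();
  const int q = L / 2;
  const int step = decimate ? 2 : 1;
  const int wout = decimate ? (w + 1) / 2 : w;
  NumericMatrix Y(n, wout);
  std::vector<int> idx(w + L);
  for (int i = 0; i < w + L; ++i) idx[i] = fold_idx(i - q, w);
  for (int c = 0, o = 0; c < w; c += step, ++o) {
    double* y = &Y(0, o);
    for (int k = 0; k < L; ++k) {
      const double hk = h[k];
      const double* x = &X(0, idx[c + k]);
      for (int r = 0; r < n; ++r) y[r] += hk * x[r];
    }
  }
  return Y;
}

// Directional (non-symmetric) grey-level co-occurrence counts.
// [[Rcpp::export]]
IntegerMatrix cpp_glcm_counts(IntegerMatrix lev, int L, int dr, int dc) {
  const int H = lev.nrow(), W = lev.ncol();
  IntegerMatrix G(L, L);
  const int r0 = dr >= 0 ? 0 : -dr, r1 = dr >= 0 ? H - dr : H;
  const int c0 = dc >= 0 ? 0 : -dc, c1 = dc >= 0 ? W - dc : W;
  for (int c = c0; c < c1; ++c)
    for (int r = r0; r < r1; ++r)
      G(lev(r, c) - 1, lev(r + dr, c + dc) - 1)++;
  return G;
}

// Maximal runs of equal grey level along all parallel lines of a
// direction (0, 45, 90, 135 degrees). Returns grey levels and lengths.
// [[Rcpp::export]]
List cpp_runs(IntegerMatrix lev, int direction) {
  const int H = lev.nrow(), W = lev.ncol();
  std::vector<int> vals, lens;
  vals.reserve(H * W / 2);
  lens.reserve(H * W / 2);
  auto scan = [&](int r, int c, int dr, int dc) {
    int cur = lev(r, c), len = 1;
    r += dr; c += dc;
    while (r >= 0 && r < H && c >= 0 && c < W) {
      if (lev(r, c) == cur) {
        ++len;
      } else {
        vals.push_back(cur); lens.push_back(len);
        cur = lev(r, c); len = 1;
      }
      r += dr; c += dc;
    }
    vals.push_back(cur); lens.push_back(len);
  };
  if (direction == 0) {
    for (int r = 0; r < H; ++r) scan(r, 0, 0, 1);
  } else if (direction == 90) {
    for (int c = 0; c < W; ++c) scan(0, c, 1, 0);
  } else if (direction == 45) {
    // up-right: start on the left column and the bottom row
    for (int r = 0; r < H; ++r) scan(r, 0, -1, 1);
    for (int c = 1; c < W; ++c) scan(H - 1, c, -1, 1);
  } else if (direction == 135) {
    // down-right: start on the top row and the left column
    for (int c = 0; c < W; ++c) scan(0, c, 1, 1);
    for (int r = 1; r < H; ++r) scan(r, 0, 1, 1);
  } else {
    stop("direction must be one of 0, 45, 90, 135");
  }
  return List::create(_["vals"] = wrap(vals), _["lens"] = wrap(lens));
}

// 10-bin rotation-invariant uniform LBP histogram (8 neighbours,
// radius 1, neighbour >= centre). `lut` maps code 0..255 to bin 1..10.
// [[Rcpp::export]]
IntegerVector cpp_lbp_hist(NumericMatrix roi, IntegerVector lut) {
  const int H = roi.nrow(), W = roi.ncol();
  static const int DR[8] = {0, -1, -1, -1, 0, 1, 1, 1};
  static const int DC[8] = {1, 1, 0, -1, -1, -1, 0, 1};
  IntegerVector bins(10);
  for (int c = 1; c < W - 1; ++c)
    for (int r = 1; r < H - 1; ++r) {
      const double ctr = roi(r, c);
      int code = 0;
      for (int b = 0; b < 8; ++b)
        if (roi(r + DR[b], c + DC[b]) >= ctr) code |= (1 << b);
      bins[lut[code] - 1]++;
    }
  return bins;
}

// All five co-occurrence features for a batch of offsets. Correlation
// uses the mean/population variance of the quantized region itself when
// corr_image is true, the marginal form otherwise. Entropy in bits with
// 0 log 0 := 0. Rows: contrast, correlation, energy, homogeneity,
// entropy.
// [[Rcpp::export]]
NumericMatrix cpp_glcm_feats(IntegerMatrix lev, int L, IntegerVector drs,
                             IntegerVector dcs, bool corr_image) {
  const int H = lev.nrow(), W = lev.ncol(), no = drs.size();
  NumericMatrix out(5, no);
  double u = 0.0, s2 = 0.0;
  if (corr_image) {
    const double nn = double(H) * W;
    for (int c = 0; c < W; ++c)
      for (int r = 0; r < H; ++r) u += lev(r, c);
    u /= nn;
    for (int c = 0; c < W; ++c)
      for (int r = 0; r < H; ++r) {
        const double d = lev(r, c) - u;
        s2 += d * d;
      }
    s2 /= nn;
  }
  std::vector<double> G(L * L);
  const double log2e = 1.0 / std::log(2.0);
  for (int o = 0; o < no; ++o) {
    const int dr = drs[o], dc = dcs[o];
    std::fill(G.begin(), G.end(), 0.0);
    const int r0 = dr >= 0 ? 0 : -dr, r1 = dr >= 0 ? H - dr : H;
    const int c0 = dc >= 0 ? 0 : -dc, c1 = dc >= 0 ? W - dc : W;
    double tot = 0.0;
    for (int c = c0; c < c1; ++c)
      for (int r = r0; r < r1; ++r) {
        G[(lev(r, c) - 1) * L + (lev(r + dr, c + dc) - 1)] += 1.0;
        tot += 1.0;
      }
    double contrast = 0, corr = 0, energy = 0, homog = 0, ent = 0;
    double ui = 0, uj = 0, si = 0, sj = 0, cij = 0;
    for (int i = 0; i < L; ++i)
      for (int j = 0; j < L; ++j) {
        const double p = G[i * L + j] / tot;
        if (p == 0.0) continue;
        const int d = i - j;
        contrast += d * d * p;
        energy += p * p;
        homog += p / (1.0 + d * d);
        ent -= p * std::log(p) * log2e;
        if (corr_image) {
          corr += (i + 1 - u) * (j + 1 - u) * p;
        } else {
          ui += (i + 1) * p; uj += (j + 1) * p;
        }
      }
    if (corr_image) {
      corr = (s2 > 0) ? corr / s2 : 0.0;
    } else {
      for (int i = 0; i < L; ++i)
        for (int j = 0; j < L; ++j) {
          const double p = G[i * L + j] / tot;
          if (p == 0.0) continue;
          si += (i + 1 - ui) * (i + 1 - ui) * p;
          sj += (j + 1 - uj) * (j + 1 - uj) * p;
          cij += (i + 1 - ui) * (j + 1 - uj) * p;
        }
      corr = (si > 0 && sj > 0) ? cij / std::sqrt(si * sj) : 0.0;
    }
    out(0, o) = contrast; out(1, o) = corr; out(2, o) = energy;
    out(3, o) = homog; out(4, o) = ent;
  }
  return out;
}

// The eleven run-length features for a batch of directions. Rows follow
// the order: SRE, LRE, GLN, RLN, RP, LGRE, HGRE, SRLGE, SRHGE, LRLGE,
// LRHGE.
// [[Rcpp::export]]
NumericMatrix cpp_glrlm_feats(IntegerMatrix lev, int L,
                              IntegerVector dirs) {
  const int H = lev.nrow(), W = lev.ncol(), nd = dirs.size();
  const double N = double(H) * W;
  NumericMatrix out(11, nd);
  const int maxlen = std::max(H, W);
  std::vector<double> gl(L), rl(maxlen + 1);
  for (int d = 0; d < nd; ++d) {
    std::fill(gl.begin(), gl.end(), 0.0);
    std::fill(rl.begin(), rl.end(), 0.0);
    double nr = 0, sre = 0, lre = 0, lgre = 0, hgre = 0;
    double srlge = 0, srhge = 0, lrlge = 0, lrhge = 0;
    auto take = [&](int val, int len) {
      const double v2 = double(val) * val, l2 = double(len) * len;
      nr += 1.0; gl[val - 1] += 1.0; rl[len] += 1.0;
      sre += 1.0 / l2; lre += l2; lgre += 1.0 / v2; hgre += v2;
      srlge += 1.0 / (v2 * l2); srhge += v2 / l2;
      lrlge += l2 / v2; lrhge += v2 * l2;
    };
    auto scan = [&](int r, int c, int dr, int dc) {
      int cur = lev(r, c), len = 1;
      r += dr; c += dc;
      while (r >= 0 && r < H && c >= 0 && c < W) {
        if (lev(r, c) == cur) {
          ++len;
        } else {
          take(cur, len);
          cur = lev(r, c); len = 1;
        }
        r += dr; c += dc;
      }
      take(cur, len);
    };
    const int dir = dirs[d];
    if (dir == 0) {
      for (int r = 0; r < H; ++r) scan(r, 0, 0, 1);
    } else if (dir == 90) {
      for (int c = 0; c < W; ++c) scan(0, c, 1, 0);
    } else if (dir == 45) {
      for (int r = 0; r < H; ++r) scan(r, 0, -1, 1);
      for (int c = 1; c < W; ++c) scan(H - 1, c, -1, 1);
    } else if (dir == 135) {
      for (int c = 0; c < W; ++c) scan(0, c, 1, 1);
      for (int r = 1; r < H; ++r) scan(r, 0, 1, 1);
    } else {
      stop("direction must be one of 0, 45, 90, 135");
    }
    double gln = 0, rln = 0;
    for (int i = 0; i < L; ++i) gln += gl[i] * gl[i];
    for (int j = 0; j <= maxlen; ++j) rln += rl[j] * rl[j];
    out(0, d) = sre / nr; out(1, d) = lre / nr; out(2, d) = gln / nr;
    out(3, d) = rln / nr; out(4, d) = nr / N; out(5, d) = lgre / nr;
    out(6, d) = hgre / nr; out(7, d) = srlge / nr;
    out(8, d) = srhge / nr; out(9, d) = lrlge / nr;
    out(10, d) = lrhge / nr;
  }
  return out;
}

// Per-fold chi-square scan. For every column of X: walk the global
// sorted order `ord` (1-based) restricted to `train` rows, compute
// type-7 quantile bin edges on the training values, assign quantile
// bins (findInterval convention: bin = 1 + #edges <= value) and build
// the class-by-bin contingency table; return the Pearson statistic and
// degrees of freedom per column.
// [[Rcpp::export]]
List cpp_chi2_scan(NumericMatrix X, IntegerMatrix ord, IntegerVector y,
                   LogicalVector train, int n_bins, int g) {
  const int n = X.nrow(), p = X.ncol();
  int m = 0;
  for (int i = 0; i < n; ++i) if (train[i]) ++m;
  if (m < 2) stop("need at least two training rows");
  NumericVector stat(p);
  IntegerVector df(p);
  std::vector<double> sorted(m);
  std::vector<int> ysorted(m);
  std::vector<double> edges(n_bins - 1);
  std::vector<double> nc(g), csum(g);
  std::vector<double> O(g * n_bins);
  std::fill(nc.begin(), nc.end(), 0.0);
  for (int i = 0; i < n; ++i) if (train[i]) nc[y[i] - 1] += 1.0;
  int gu = 0;
  for (int c0 = 0; c0 < g; ++c0) if (nc[c0] > 0) ++gu;
  for (int c = 0; c < p; ++c) {
    int t = 0;
    for (int i = 0; i < n; ++i) {
      const int r = ord(i, c) - 1;
      if (train[r]) {
        sorted[t] = X(r, c);
        ysorted[t] = y[r] - 1;
        ++t;
      }
    }
    // type-7 quantile edges at probs k / n_bins
    int ne = 0;
    for (int k = 1; k < n_bins; ++k) {
      const double h = (m - 1) * (double(k) / n_bins);
      const int lo = int(h);
      const double fr = h - lo;
      double e = sorted[lo] * (1 - fr) +
        sorted[std::min(lo + 1, m - 1)] * fr;
      if (ne == 0 || e > edges[ne - 1]) edges[ne++] = e;  // unique edges
    }
    std::fill(O.begin(), O.end(), 0.0);
    int b = 0;
    std::vector<double> bt(n_bins, 0.0);
    for (int i = 0; i < m; ++i) {
      while (b < ne && edges[b] <= sorted[i]) ++b;
      O[ysorted[i] * n_bins + b] += 1.0;
      bt[b] += 1.0;
    }
    int used = 0;
    for (int k = 0; k <= ne; ++k) if (bt[k] > 0) ++used;
    double s = 0.0;
    for (int cl = 0; cl < g; ++cl) {
      if (nc[cl] == 0) continue;
      for (int k = 0; k <= ne; ++k) {
        const double E = nc[cl] * bt[k] / m;
        if (E > 0) {
          const double d = O[cl * n_bins + k] - E;
          s += d * d / E;
        }
      }
    }
    stat[c] = s;
    df[c] = (std::max(used, 1) - 1) * (gu - 1);
  }
  return List::create(_["stat"] = stat, _["df"] = df);
}
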