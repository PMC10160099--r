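#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Chi-square critical value, df = 3, alpha = 0.05. A cell is split into
// quadrants while the uniformity test over its four quadrant counts rejects.
static const double CHI2_CRIT = 7.814727903251179;
// Cells smaller than this are never split.
static const int MIN_CELL = 8;

// Copy an Rcpp integer matrix into row-contiguous storage (the bootstrap
// loop reads whole rows; column-major access would cache-miss per element).
static std::vector<std::vector<int> > to_rows(const IntegerMatrix &m) {
  const int g = m.nrow(), n = m.ncol();
  std::vector<std::vector<int> > rows(g, std::vector<int>(n));
  for (int j = 0; j < n; ++j)
    for (int r = 0; r < g; ++r)
      rows[r][j] = m(r, j);
  return rows;
}

// ---------------------------------------------------------------------------
// Adaptive recursive-partitioning MI estimator on rank data.
//
// Points carry integer ranks in 0..n-1 on each axis (distinct by
// construction: ties are broken by sample index upstream).  A cell is split
// at the marginal medians of the points it contains; the split is accepted
// while a chi-square uniformity test on the four quadrant counts rejects at
// alpha = 0.05.  Each leaf cell contributes
//     (nc/n) * log( (nc/n) / (ax * ay) )
// where ax, ay are the leaf's rank-interval widths as fractions of n (the
// global marginals are uniform on ranks, so interval width is the marginal
// probability mass).  The leaves tile the rank square, so the sum is a
// Kullback-Leibler divergence and hence >= 0.
// ---------------------------------------------------------------------------

struct MiWork {
  std::vector<int> xr, yr, scratch_x, scratch_y, hist;
  std::vector<double> logtab; // logtab[i] = log(i), i in 1..n

  void ensure_logtab(int n) {
    if ((int)logtab.size() < n + 1) {
      logtab.resize(n + 1);
      logtab[0] = 0.0;
      for (int i = 1; i <= n; ++i) logtab[i] = std::log((double)i);
    }
    if ((int)hist.size() < n) hist.assign(n, 0);
  }
};

// median of the nc distinct integers w.*r[lo..hi) lying in [v0, v1):
// the (nc/2)-th smallest (0-based), by counting into a shared histogram.
static inline int counting_median(const std::vector<int> &v, int lo, int hi,
                                  int v0, int v1, std::vector<int> &hist) {
  for (int i = lo; i < hi; ++i) ++hist[v[i]];
  const int want = (hi - lo) / 2; // index of the lower median
  int seen = 0, med = v1 - 1;
  for (int x = v0; x < v1; ++x) {
    seen += hist[x];
    if (seen > want) { med = x; break; }
  }
  for (int i = lo; i < hi; ++i) hist[v[i]] = 0;
  return med;
}

// leaf contribution (nc/n) * log( nc * n / (wx * wy) ) via the log table
static inline double leaf_term(const MiWork &w, int nc, int wx, int wy, int n) {
  return (nc / (double)n) *
    (w.logtab[nc] + w.logtab[n] - w.logtab[wx] - w.logtab[wy]);
}

static double mi_adaptive_rec(MiWork &w, int lo, int hi,
                              int x0, int x1, int y0, int y1, int n) {
  const int nc = hi - lo;
  if (nc < MIN_CELL || (x1 - x0) < 2 || (y1 - y0) < 2)
    return leaf_term(w, nc, x1 - x0, y1 - y0, n);

  // marginal medians of the ranks inside the cell
  const int sx = counting_median(w.xr, lo, hi, x0, x1, w.hist);
  const int sy = counting_median(w.yr, lo, hi, y0, y1, w.hist);
  if (sx <= x0 || sx >= x1 || sy <= y0 || sy >= y1)
    return leaf_term(w, nc, x1 - x0, y1 - y0, n);

  int cnt[4] = {0, 0, 0, 0}; // (x<sx,y<sy), (x<sx,y>=sy), (x>=sx,y<sy), (x>=sx,y>=sy)
  for (int i = lo; i < hi; ++i) {
    int q = (w.xr[i] >= sx ? 2 : 0) + (w.yr[i] >= sy ? 1 : 0);
    ++cnt[q];
  }
  const double e = nc / 4.0;
  double chi2 = 0.0;
  for (int q = 0; q < 4; ++q) {
    const double d = cnt[q] - e;
    chi2 += d * d / e;
  }
  if (chi2 < CHI2_CRIT) return leaf_term(w, nc, x1 - x0, y1 - y0, n);

  // partition points into the four quadrants (stable two-key bucket pass)
  if ((int)w.scratch_x.size() < nc) {
    w.scratch_x.resize(nc);
    w.scratch_y.resize(nc);
  }
  std::vector<int> &tx = w.scratch_x, &ty = w.scratch_y;
  int pos[4];
  pos[0] = lo;
  pos[1] = lo + cnt[0];
  pos[2] = lo + cnt[0] + cnt[1];
  pos[3] = lo + cnt[0] + cnt[1] + cnt[2];
  int fill[4] = {pos[0], pos[1], pos[2], pos[3]};
  for (int i = lo; i < hi; ++i) {
    int q = (w.xr[i] >= sx ? 2 : 0) + (w.yr[i] >= sy ? 1 : 0);
    tx[fill[q] - lo] = w.xr[i];
    ty[fill[q] - lo] = w.yr[i];
    ++fill[q];
  }
  std::copy(tx.begin(), tx.begin() + nc, w.xr.begin() + lo);
  std::copy(ty.begin(), ty.begin() + nc, w.yr.begin() + lo);

  double s = 0.0;
  s += mi_adaptive_rec(w, pos[0], pos[0] + cnt[0], x0, sx, y0, sy, n);
  s += mi_adaptive_rec(w, pos[1], pos[1] + cnt[1], x0, sx, sy, y1, n);
  s += mi_adaptive_rec(w, pos[2], pos[2] + cnt[2], sx, x1, y0, sy, n);
  s += mi_adaptive_rec(w, pos[3], pos[3] + cnt[3], sx, x1, sy, y1, n);
  return s;
}

// Fast path for the root cell: the marginals there are the complete rank
// sets 0..n-1, so both medians equal n/2 and no selection is needed. When
// the root uniformity test does not reject, the whole square is one leaf
// and the MI estimate is exactly 0 — the overwhelmingly common case for
// null pairs in a network scan. Only on rejection are the rank vectors
// copied into mutable work arrays for the recursive partition.
static double mi_adaptive_root_ptr(const int *xr, const int *yr, int n,
                                   MiWork &w) {
  const int h = n / 2;
  int cnt[4] = {0, 0, 0, 0};
  for (int i = 0; i < n; ++i) {
    int q = (xr[i] >= h ? 2 : 0) + (yr[i] >= h ? 1 : 0);
    ++cnt[q];
  }
  const double e = n / 4.0;
  double chi2 = 0.0;
  for (int q = 0; q < 4; ++q) {
    const double d = cnt[q] - e;
    chi2 += d * d / e;
  }
  if (chi2 < CHI2_CRIT || n < MIN_CELL || h < 1) return 0.0;
  w.ensure_logtab(n);
  w.xr.assign(xr, xr + n);
  w.yr.assign(yr, yr + n);
  double mi = mi_adaptive_rec(w, 0, n, 0, n, 0, n, n);
  return mi > 0.0 ? mi : 0.0;
}

static double mi_adaptive_ranks(const int *xr, const int *yr, int n, MiWork &w) {
  return mi_adaptive_root_ptr(xr, yr, n, w);
}

// [[Rcpp::export(name = ".mi_adaptive_ranks")]]
double mi_adaptive_ranks_r(IntegerVector xr, IntegerVector yr) {
  int n = xr.size();
  MiWork w;
  w.ensure_logtab(n);
  return mi_adaptive_ranks(INTEGER(xr), INTEGER(yr), n, w);
}

// ---------------------------------------------------------------------------
// Fixed-bin equal-frequency plug-in MI from bin labels (0-based).
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".mi_plugin_bins")]]
double mi_plugin_bins_r(IntegerVector bx, IntegerVector by, int kx, int ky) {
  const int n = bx.size();
  std::vector<double> joint(kx * ky, 0.0), mx(kx, 0.0), my(ky, 0.0);
  for (int i = 0; i < n; ++i) {
    joint[bx[i] * ky + by[i]] += 1.0;
    mx[bx[i]] += 1.0;
    my[by[i]] += 1.0;
  }
  double mi = 0.0;
  const double nn = n;
  auto term = [&](int a, int b) -> double {
    const double pj = joint[a * ky + b] / nn;
    return pj > 0.0 ? pj * std::log(pj * nn * nn / (mx[a] * my[b])) : 0.0;
  };
  if (kx == ky) {
    // symmetric accumulation order, so that swapping the arguments (which
    // transposes the joint table) gives a bit-identical result
    for (int a = 0; a < kx; ++a) {
      mi += term(a, a);
      for (int b = a + 1; b < ky; ++b) mi += term(a, b) + term(b, a);
    }
  } else {
    for (int a = 0; a < kx; ++a)
      for (int b = 0; b < ky; ++b) mi += term(a, b);
  }
  return mi > 0.0 ? mi : 0.0;
}

// ---------------------------------------------------------------------------
// Row-wise integer ranks (0..n-1), ties broken by column index (stable).
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".row_ranks")]]
IntegerMatrix row_ranks_r(NumericMatrix x) {
  const int g = x.nrow(), n = x.ncol();
  IntegerMatrix out(g, n);
  std::vector<int> ord(n);
  std::vector<double> row(n);
  for (int r = 0; r < g; ++r) {
    for (int j = 0; j < n; ++j) {
      ord[j] = j;
      row[j] = x(r, j);
    }
    std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
      return row[a] < row[b];
    });
    for (int j = 0; j < n; ++j) out(r, ord[j]) = j;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Batch adaptive MI: all driver-row x gene-row pairs of a rank matrix.
// rank_mat: genes x samples integer ranks; driver_idx: 0-based row indices.
// Returns |driver_idx| x genes matrix; self pairs set to NA.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".mi_cross_ranks")]]
NumericMatrix mi_cross_ranks_r(IntegerMatrix rank_mat, IntegerVector driver_idx) {
  const int g = rank_mat.nrow(), n = rank_mat.ncol(), d = driver_idx.size();
  NumericMatrix out(d, g);
  MiWork w;
  const std::vector<std::vector<int> > rows = to_rows(rank_mat);

  // Root-test screen on bitmasks: bit j of a row's mask is set when
  // rank_j >= n/2. The root quadrant counts follow from one AND+popcount
  // pass, and the root chi-square decides whether the expensive recursive
  // partition runs at all (it does not for the vast majority of null
  // pairs, whose MI is exactly 0).
  const int h = n / 2, nw = (n + 63) / 64;
  const int n_hi = n - h; // ones per mask (ranks are a permutation)
  std::vector<uint64_t> masks((size_t)g * nw, 0u);
  for (int r = 0; r < g; ++r) {
    uint64_t *mk = &masks[(size_t)r * nw];
    const int *rr = rows[r].data();
    for (int j = 0; j < n; ++j)
      if (rr[j] >= h) mk[j >> 6] |= (uint64_t)1 << (j & 63);
  }
  const double e = n / 4.0;
  for (int di = 0; di < d; ++di) {
    const int dr = driver_idx[di];
    const uint64_t *xm = &masks[(size_t)dr * nw];
    for (int t = 0; t < g; ++t) {
      if (t == dr) { out(di, t) = NA_REAL; continue; }
      const uint64_t *ym = &masks[(size_t)t * nw];
      int n11 = 0;
      for (int wd = 0; wd < nw; ++wd)
        n11 += __builtin_popcountll(xm[wd] & ym[wd]);
      const int n10 = n_hi - n11, n01 = n_hi - n11,
        n00 = n - 2 * n_hi + n11;
      double chi2 = (n11 - e) * (n11 - e) / e + (n10 - e) * (n10 - e) / e +
        (n01 - e) * (n01 - e) / e + (n00 - e) * (n00 - e) / e;
      if (chi2 < CHI2_CRIT || n < MIN_CELL || h < 1) {
        out(di, t) = 0.0;
      } else {
        w.ensure_logtab(n);
        w.xr = rows[dr];
        w.yr = rows[t];
        double mi = mi_adaptive_rec(w, 0, n, 0, n, 0, n, n);
        out(di, t) = mi > 0.0 ? mi : 0.0;
      }
    }
  }
  return out;
}

// Batch adaptive MI over paired rows of two rank matrices (for the
// permutation null: row i of X against row i of Y).

// [[Rcpp::export(name = ".mi_paired_ranks")]]
NumericVector mi_paired_ranks_r(IntegerMatrix xr_mat, IntegerMatrix yr_mat) {
  const int m = xr_mat.nrow(), n = xr_mat.ncol();
  NumericVector out(m);
  MiWork w;
  const std::vector<std::vector<int> > xrows = to_rows(xr_mat),
    yrows = to_rows(yr_mat);
  for (int i = 0; i < m; ++i) {
    out[i] = mi_adaptive_root_ptr(xrows[i].data(), yrows[i].data(), n, w);
  }
  return out;
}
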