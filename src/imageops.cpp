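#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <limits>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// 1D squared-distance transform (lower envelope of parabolas).
// All values are integers stored in doubles, so arithmetic is exact.
static void dt1d(const std::vector<double>& f, int n, std::vector<double>& d) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (double)(q - v[k]) * (q - v[k]) + f[v[k]];
  }
}

// Exact squared Euclidean distance of every pixel to the nearest `seed`
// (true) pixel. Pixels outside the image never act as seeds. Uses a large
// finite sentinel instead of infinity: with at least one seed present the
// true squared distance never exceeds nr^2 + nc^2, so sentinel-derived
// parabolas can never win.
static void edt_from_seeds(const LogicalMatrix& seed, NumericMatrix& out) {
  int nr = seed.nrow(), nc = seed.ncol();
  const double BIG =
      (double)nr * nr + (double)nc * nc + 1.0;
  std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));
  NumericMatrix tmp(nr, nc);
  // pass 1: along columns
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) f[i] = seed(i, j) ? 0.0 : BIG;
    dt1d(f, nr, d);
    for (int i = 0; i < nr; ++i) tmp(i, j) = d[i];
  }
  // pass 2: along rows
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) f[j] = tmp(i, j);
    dt1d(f, nc, d);
    for (int j = 0; j < nc; ++j) out(i, j) = d[j] >= BIG ? INF : d[j];
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_edt_sq(LogicalMatrix fg) {
  // squared distance of each foreground pixel to the nearest background
  // pixel centre; 0 on background; the image border is not background.
  int nr = fg.nrow(), nc = fg.ncol();
  LogicalMatrix bg(nr, nc);
  bool any_bg = false;
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j) {
      bg(i, j) = !fg(i, j);
      if (bg(i, j)) any_bg = true;
    }
  if (!any_bg) stop("distance map undefined: mask has no background pixel");
  NumericMatrix out(nr, nc);
  edt_from_seeds(bg, out);
  return out;
}

// [[Rcpp::export]]
List cpp_nearest_label(IntegerMatrix labels) {
  // full Voronoi partition by nearest labelled pixel (centre-to-centre
  // Euclidean); ties broken toward the smaller label by ascending sweep
  // with strict improvement. Returns the partition and squared distances.
  int nr = labels.nrow(), nc = labels.ncol();
  int maxlab = 0;
  for (int i = 0; i < nr * nc; ++i) maxlab = std::max(maxlab, labels[i]);
  if (maxlab < 1) stop("no labelled particles");
  NumericMatrix best(nr, nc), d2(nr, nc);
  IntegerMatrix out(nr, nc);
  std::fill(best.begin(), best.end(), INF);
  LogicalMatrix seed(nr, nc);
  for (int k = 1; k <= maxlab; ++k) {
    bool any = false;
    for (int i = 0; i < nr * nc; ++i) {
      seed[i] = (labels[i] == k);
      if (seed[i]) any = true;
    }
    if (!any) continue;
    edt_from_seeds(seed, d2);
    for (int i = 0; i < nr * nc; ++i) {
      if (d2[i] < best[i]) {  // strict: earlier (smaller) label keeps ties
        best[i] = d2[i];
        out[i] = k;
      }
    }
  }
  return List::create(_["labels"] = out, _["dist_sq"] = best);
}

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// [[Rcpp::export]]
NumericMatrix cpp_median3(NumericMatrix x, int repeats) {
  // 3x3 median filter, `repeats` passes, edge replication at borders
  int nr = x.nrow(), nc = x.ncol();
  NumericMatrix cur = clone(x);
  double win[9];
  for (int r = 0; r < repeats; ++r) {
    NumericMatrix nxt(nr, nc);
    for (int j = 0; j < nc; ++j)
      for (int i = 0; i < nr; ++i) {
        int n = 0;
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di)
            win[n++] = cur(clampi(i + di, 0, nr - 1), clampi(j + dj, 0, nc - 1));
        std::nth_element(win, win + 4, win + 9);
        nxt(i, j) = win[4];
      }
    cur = nxt;
  }
  return cur;
}

// [[Rcpp::export]]
NumericMatrix cpp_conv3(NumericMatrix x, NumericMatrix kernel) {
  // 3x3 correlation with edge replication (kernel symmetric in practice)
  int nr = x.nrow(), nc = x.ncol();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di)
          acc += kernel(di + 1, dj + 1) *
                 x(clampi(i + di, 0, nr - 1), clampi(j + dj, 0, nc - 1));
      out(i, j) = acc;
    }
  return out;
}

// [[Rcpp::export]]
LogicalMatrix cpp_thin(LogicalMatrix mask, LogicalMatrix protect) {
  // Zhang-Suen morphological thinning to a unit-width, 8-connected skeleton;
  // `protect` pixels are never deleted (used to keep boundary curves
  // attached to the image frame)
  int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix cur = clone(mask);
  auto at = [&](const LogicalMatrix& m, int i, int j) -> int {
    if (i < 0 || j < 0 || i >= nr || j >= nc) return 0;
    return m(i, j) ? 1 : 0;
  };
  bool changed = true;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      std::vector<std::pair<int, int>> kill;
      for (int j = 0; j < nc; ++j)
        for (int i = 0; i < nr; ++i) {
          if (!cur(i, j) || protect(i, j)) continue;
          // neighbours clockwise from north: p2..p9
          int p2 = at(cur, i - 1, j), p3 = at(cur, i - 1, j + 1),
              p4 = at(cur, i, j + 1), p5 = at(cur, i + 1, j + 1),
              p6 = at(cur, i + 1, j), p7 = at(cur, i + 1, j - 1),
              p8 = at(cur, i, j - 1), p9 = at(cur, i - 1, j - 1);
          int b = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (b < 2 || b > 6) continue;
          int p[9] = {p2, p3, p4, p5, p6, p7, p8, p9, p2};
          int a = 0;
          for (int t = 0; t < 8; ++t)
            if (p[t] == 0 && p[t + 1] == 1) ++a;
          if (a != 1) continue;
          if (pass == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          kill.push_back({i, j});
        }
      for (auto& ij : kill) cur(ij.first, ij.second) = false;
      if (!kill.empty()) changed = true;
    }
  }
  return cur;
}

// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix fg, int connectivity) {
  // connected components of `fg`, labelled 1..N in raster-scan order
  // (row-major, top row first) of each component's first pixel
  if (connectivity != 4 && connectivity != 8) stop("connectivity must be 4 or 8");
  int nr = fg.nrow(), nc = fg.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  int next = 0;
  std::vector<std::pair<int, int>> stack;
  const int d4i[] = {-1, 1, 0, 0}, d4j[] = {0, 0, -1, 1};
  const int d8i[] = {-1, 1, 0, 0, -1, -1, 1, 1}, d8j[] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int* di = connectivity == 4 ? d4i : d8i;
  const int* dj = connectivity == 4 ? d4j : d8j;
  int nd = connectivity;
  // raster order: row-major
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j) {
      if (!fg(i, j) || lab(i, j) != 0) continue;
      ++next;
      stack.push_back({i, j});
      lab(i, j) = next;
      while (!stack.empty()) {
        auto ij = stack.back();
        stack.pop_back();
        for (int t = 0; t < nd; ++t) {
          int ni = ij.first + di[t], nj = ij.second + dj[t];
          if (ni < 0 || nj < 0 || ni >= nr || nj >= nc) continue;
          if (fg(ni, nj) && lab(ni, nj) == 0) {
            lab(ni, nj) = next;
            stack.push_back({ni, nj});
          }
        }
      }
    }
  return lab;
}
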