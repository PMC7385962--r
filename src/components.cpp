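#include <Rcpp.h>
#include <vector>
#include <queue>
#include <limits>
using namespace Rcpp;

// Shared connected-component labelling. 8-connectivity is the package-wide
// convention (ensemble, evaluation and spatial modules all call this routine
// so the adjacency convention cannot drift between them).

static inline bool in_bounds(int r, int c, int H, int W) {
  return r >= 0 && r < H && c >= 0 && c < W;
}

// [[Rcpp::export(name = ".label_mask_cpp")]]
IntegerMatrix label_mask_cpp(LogicalMatrix mask, int connectivity = 8) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int n_off = (connectivity == 8) ? 8 : 4;
  static const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  static const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  static const int dr4[4] = {-1, 0, 0, 1};
  static const int dc4[4] = {0, -1, 1, 0};
  const int* dr = (connectivity == 8) ? dr8 : dr4;
  const int* dc = (connectivity == 8) ? dc8 : dc4;
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      lab(r, c) = ++next;
      q.push(std::make_pair(r, c));
      while (!q.empty()) {
        std::pair<int, int> p = q.front();
        q.pop();
        for (int k = 0; k < n_off; ++k) {
          int rr = p.first + dr[k], cc = p.second + dc[k];
          if (in_bounds(rr, cc, H, W) && mask(rr, cc) && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            q.push(std::make_pair(rr, cc));
          }
        }
      }
    }
  }
  return lab;
}

// Label maximal connected regions of equal value (used to enforce superpixel
// connectivity); every pixel receives a label >= 1.
// [[Rcpp::export(name = ".label_partition_cpp")]]
IntegerMatrix label_partition_cpp(IntegerMatrix values, int connectivity = 4) {
  int H = values.nrow(), W = values.ncol();
  IntegerMatrix lab(H, W);
  int n_off = (connectivity == 8) ? 8 : 4;
  static const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  static const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  static const int dr4[4] = {-1, 0, 0, 1};
  static const int dc4[4] = {0, -1, 1, 0};
  const int* dr = (connectivity == 8) ? dr8 : dr4;
  const int* dc = (connectivity == 8) ? dc8 : dc4;
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (lab(r, c) != 0) continue;
      int v = values(r, c);
      lab(r, c) = ++next;
      q.push(std::make_pair(r, c));
      while (!q.empty()) {
        std::pair<int, int> p = q.front();
        q.pop();
        for (int k = 0; k < n_off; ++k) {
          int rr = p.first + dr[k], cc = p.second + dc[k];
          if (in_bounds(rr, cc, H, W) && lab(rr, cc) == 0 &&
              values(rr, cc) == v) {
            lab(rr, cc) = next;
            q.push(std::make_pair(rr, cc));
          }
        }
      }
    }
  }
  return lab;
}

// Exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher):
// distance in pixels from every pixel centre to the nearest true pixel centre.
// Pixels of the target set get 0; if the set is empty all entries are +Inf.

static void dt1d(const std::vector<double>& f, std::vector<double>& d) {
  int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export(name = ".edt_sq_cpp")]]
NumericMatrix edt_sq_cpp(LogicalMatrix target) {
  int H = target.nrow(), W = target.ncol();
  const double INF = std::numeric_limits<double>::infinity();
  NumericMatrix d(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r)
      d(r, c) = target(r, c) ? 0.0 : INF;
  std::vector<double> f(std::max(H, W)), out(std::max(H, W));
  // columns first
  for (int c = 0; c < W; ++c) {
    bool any_finite = false;
    for (int r = 0; r < H; ++r) {
      f[r] = d(r, c);
      if (f[r] < INF) any_finite = true;
    }
    if (!any_finite) continue;
    // replace INF with a large finite value so the parabola envelope works
    double big = 1.0 * (H + W) * (H + W) * 4.0;
    for (int r = 0; r < H; ++r) if (f[r] == INF) f[r] = big;
    f.resize(H); out.resize(H);
    dt1d(f, out);
    for (int r = 0; r < H; ++r) d(r, c) = out[r];
    f.resize(std::max(H, W)); out.resize(std::max(H, W));
  }
  // then rows
  bool all_inf = true;
  for (int c = 0; c < W && all_inf; ++c)
    for (int r = 0; r < H; ++r)
      if (d(r, c) < INF) { all_inf = false; break; }
  if (all_inf) return d;
  double big = 1.0 * (H + W) * (H + W) * 4.0;
  for (int r = 0; r < H; ++r) {
    f.resize(W); out.resize(W);
    for (int c = 0; c < W; ++c) f[c] = (d(r, c) == INF) ? big : d(r, c);
    dt1d(f, out);
    for (int c = 0; c < W; ++c) d(r, c) = out[c];
  }
  return d;
}
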