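#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// SLIC-style k-means in colour+space. Colour channels are scaled to 0..100
// before distances are taken so that the conventional compactness value of 10
// balances a full-range colour difference against one grid-step of spatial
// distance. Returns a 1-based cluster assignment; connectivity enforcement is
// done by the caller.
// [[Rcpp::export(name = ".slic_assign_cpp")]]
IntegerMatrix slic_assign_cpp(NumericVector img, int H, int W,
                              double step, double compactness, int iters) {
  const double cs = 100.0;  // colour scale
  // img is an H x W x 3 array in [0,1], column-major
  std::vector<double> R(H * W), G(H * W), B(H * W);
  for (int i = 0; i < H * W; ++i) {
    R[i] = img[i] * cs;
    G[i] = img[i + H * W] * cs;
    B[i] = img[i + 2 * H * W] * cs;
  }
  // grid-initialised centres
  int nr = std::max(1, (int)std::floor(H / step + 0.5));
  int nc = std::max(1, (int)std::floor(W / step + 0.5));
  int K = nr * nc;
  std::vector<double> cr(K), cc(K), cR(K), cG(K), cB(K);
  int k = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i, ++k) {
      double r0 = (i + 0.5) * H / nr, c0 = (j + 0.5) * W / nc;
      int ri = std::min(H - 1, (int)r0), ci = std::min(W - 1, (int)c0);
      cr[k] = r0; cc[k] = c0;
      cR[k] = R[ri + ci * H]; cG[k] = G[ri + ci * H]; cB[k] = B[ri + ci * H];
  }
  }
  double invS2 = (compactness * compactness) / (step * step);
  std::vector<int> assign(H * W, 0);
  std::vector<double> best(H * W);
  for (int it = 0; it < iters; ++it) {
    std::fill(best.begin(), best.end(), 1e300);
    for (int q = 0; q < K; ++q) {
      int rlo = std::max(0, (int)std::floor(cr[q] - 2 * step));
      int rhi = std::min(H - 1, (int)std::ceil(cr[q] + 2 * step));
      int clo = std::max(0, (int)std::floor(cc[q] - 2 * step));
      int chi = std::min(W - 1, (int)std::ceil(cc[q] + 2 * step));
      for (int c = clo; c <= chi; ++c) {
        for (int r = rlo; r <= rhi; ++r) {
          int idx = r + c * H;
          double dc2 = (R[idx] - cR[q]) * (R[idx] - cR[q]) +
                       (G[idx] - cG[q]) * (G[idx] - cG[q]) +
                       (B[idx] - cB[q]) * (B[idx] - cB[q]);
          double ds2 = (r - cr[q]) * (r - cr[q]) + (c - cc[q]) * (c - cc[q]);
          double D = dc2 + ds2 * invS2;
          if (D < best[idx]) { best[idx] = D; assign[idx] = q; }
        }
      }
    }
    // update centres
    std::vector<double> sr(K, 0), sc(K, 0), sR(K, 0), sG(K, 0), sB(K, 0);
    std::vector<int> n(K, 0);
    for (int c = 0; c < W; ++c) {
      for (int r = 0; r < H; ++r) {
        int idx = r + c * H;
        int q = assign[idx];
        sr[q] += r; sc[q] += c;
        sR[q] += R[idx]; sG[q] += G[idx]; sB[q] += B[idx];
        n[q]++;
      }
    }
    for (int q = 0; q < K; ++q) {
      if (n[q] == 0) continue;
      cr[q] = sr[q] / n[q]; cc[q] = sc[q] / n[q];
      cR[q] = sR[q] / n[q]; cG[q] = sG[q] / n[q]; cB[q] = sB[q] / n[q];
    }
  }
  IntegerMatrix out(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r)
      out(r, c) = assign[r + c * H] + 1;
  return out;
}
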