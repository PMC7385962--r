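// Primitives for the package's small convolutional-network engine.
// Tensors are H x W x C arrays (arma::cube), weights for a 3x3 convolution
// are (9*Cin) x Cout matrices with row index ci*9 + k, where k enumerates
// the (dr, dc) offsets in {-1,0,1}^2 column-major (dr fastest). Zero padding.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const int OFF_DR[9] = {-1, 0, 1, -1, 0, 1, -1, 0, 1};
static const int OFF_DC[9] = {-1, -1, -1, 0, 0, 0, 1, 1, 1};

static arma::mat im2col3(const arma::cube& x) {
  int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  arma::mat M(H * W, 9 * Cin, arma::fill::zeros);
  for (int ci = 0; ci < Cin; ++ci) {
    const arma::mat& xs = x.slice(ci);
    for (int k = 0; k < 9; ++k) {
      int dr = OFF_DR[k], dc = OFF_DC[k];
      int col = ci * 9 + k;
      int r0 = std::max(0, -dr), r1 = H - 1 - std::max(0, dr);
      int c0 = std::max(0, -dc), c1 = W - 1 - std::max(0, dc);
      if (r0 > r1 || c0 > c1) continue;
      for (int c = c0; c <= c1; ++c) {
        // output pixel (r, c) reads input pixel (r + dr, c + dc)
        M(arma::span(r0 + c * H, r1 + c * H), arma::span(col, col)) =
          xs(arma::span(r0 + dr, r1 + dr), arma::span(c + dc, c + dc));
      }
    }
  }
  return M;
}

static arma::cube col2im3(const arma::mat& Mg, int H, int W, int Cin) {
  arma::cube gx(H, W, Cin, arma::fill::zeros);
  for (int ci = 0; ci < Cin; ++ci) {
    arma::mat& gs = gx.slice(ci);
    for (int k = 0; k < 9; ++k) {
      int dr = OFF_DR[k], dc = OFF_DC[k];
      int col = ci * 9 + k;
      int r0 = std::max(0, -dr), r1 = H - 1 - std::max(0, dr);
      int c0 = std::max(0, -dc), c1 = W - 1 - std::max(0, dc);
      if (r0 > r1 || c0 > c1) continue;
      for (int c = c0; c <= c1; ++c) {
        gs(arma::span(r0 + dr, r1 + dr), arma::span(c + dc, c + dc)) +=
          Mg(arma::span(r0 + c * H, r1 + c * H), arma::span(col, col));
      }
    }
  }
  return gx;
}

// [[Rcpp::export(name = ".conv3_fwd_cpp")]]
arma::cube conv3_fwd_cpp(const arma::cube& x, const arma::mat& w,
                         const arma::vec& b) {
  int H = x.n_rows, W = x.n_cols;
  int Cout = w.n_cols;
  arma::mat Y = im2col3(x) * w;
  Y.each_row() += b.t();
  arma::cube out(Y.memptr(), H, W, Cout);
  return out;
}

// [[Rcpp::export(name = ".conv3_bwd_cpp")]]
List conv3_bwd_cpp(const arma::cube& x, const arma::mat& w,
                   const arma::cube& gy) {
  int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  int Cout = w.n_cols;
  arma::mat G(const_cast<double*>(gy.memptr()), H * W, Cout, false, true);
  arma::mat M = im2col3(x);
  arma::mat gw = M.t() * G;
  arma::vec gb = arma::sum(G, 0).t();
  arma::cube gx = col2im3(G * w.t(), H, W, Cin);
  return List::create(Named("gx") = gx, Named("gw") = gw, Named("gb") = gb);
}

// 2x2 max pooling, stride 2; H and W must be even.
// [[Rcpp::export(name = ".maxpool2_fwd_cpp")]]
List maxpool2_fwd_cpp(const arma::cube& x) {
  int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  int h = H / 2, w2 = W / 2;
  arma::cube y(h, w2, C);
  arma::ucube idx(h, w2, C);
  for (int ci = 0; ci < C; ++ci) {
    for (int c = 0; c < w2; ++c) {
      for (int r = 0; r < h; ++r) {
        double v[4] = {x(2 * r, 2 * c, ci), x(2 * r + 1, 2 * c, ci),
                       x(2 * r, 2 * c + 1, ci), x(2 * r + 1, 2 * c + 1, ci)};
        int a = 0;
        for (int k = 1; k < 4; ++k) if (v[k] > v[a]) a = k;
        y(r, c, ci) = v[a];
        idx(r, c, ci) = a;
      }
    }
  }
  return List::create(Named("y") = y, Named("idx") = idx);
}

// [[Rcpp::export(name = ".maxpool2_bwd_cpp")]]
arma::cube maxpool2_bwd_cpp(const arma::cube& gy, const arma::ucube& idx,
                            int H, int W) {
  int h = gy.n_rows, w2 = gy.n_cols, C = gy.n_slices;
  arma::cube gx(H, W, C, arma::fill::zeros);
  for (int ci = 0; ci < C; ++ci) {
    for (int c = 0; c < w2; ++c) {
      for (int r = 0; r < h; ++r) {
        int a = (int)idx(r, c, ci);
        int rr = 2 * r + (a % 2), cc = 2 * c + (a / 2);
        gx(rr, cc, ci) += gy(r, c, ci);
      }
    }
  }
  return gx;
}

// nearest-neighbour 2x upsampling
// [[Rcpp::export(name = ".upsample2_fwd_cpp")]]
arma::cube upsample2_fwd_cpp(const arma::cube& x) {
  int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::cube y(2 * H, 2 * W, C);
  for (int ci = 0; ci < C; ++ci)
    for (int c = 0; c < W; ++c)
      for (int r = 0; r < H; ++r) {
        double v = x(r, c, ci);
        y(2 * r, 2 * c, ci) = v;
        y(2 * r + 1, 2 * c, ci) = v;
        y(2 * r, 2 * c + 1, ci) = v;
        y(2 * r + 1, 2 * c + 1, ci) = v;
      }
  return y;
}

// [[Rcpp::export(name = ".upsample2_bwd_cpp")]]
arma::cube upsample2_bwd_cpp(const arma::cube& gy) {
  int H2 = gy.n_rows, W2 = gy.n_cols, C = gy.n_slices;
  int H = H2 / 2, W = W2 / 2;
  arma::cube gx(H, W, C);
  for (int ci = 0; ci < C; ++ci)
    for (int c = 0; c < W; ++c)
      for (int r = 0; r < H; ++r)
        gx(r, c, ci) = gy(2 * r, 2 * c, ci) + gy(2 * r + 1, 2 * c, ci) +
                       gy(2 * r, 2 * c + 1, ci) + gy(2 * r + 1, 2 * c + 1, ci);
  return gx;
}
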