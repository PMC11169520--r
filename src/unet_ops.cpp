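// Building blocks for the compact U-net harness: 3x3 same-padding
// convolution (forward/backward as shifted-submatrix AXPY updates), 2x2
// max-pooling and nearest-neighbour 2x upsampling. Tensors are [H, W, C]
// cubes. Weight matrices are (Cout, 9*Cin) with kernel offset index
// r = cin*9 + (kj+1)*3 + (ki+1).
#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Overlap of the image with itself shifted by (ki, kj): for output pixel
// (i, j), the contributing input pixel is (i + ki, j + kj).
static inline void shift_ranges(int H, int W, int ki, int kj,
                                int &or0, int &or1, int &oc0, int &oc1,
                                int &ir0, int &ic0) {
  or0 = std::max(0, -ki); or1 = std::min(H - 1, H - 1 - ki);
  oc0 = std::max(0, -kj); oc1 = std::min(W - 1, W - 1 - kj);
  ir0 = or0 + ki; ic0 = oc0 + kj;
}

// [[Rcpp::export]]
arma::cube cpp_conv3_fw(const arma::cube &x, const arma::mat &w,
                        const arma::vec &b) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Cout = w.n_rows;
  arma::cube y(H, W, Cout);
  for (int co = 0; co < Cout; ++co) y.slice(co).fill(b[co]);
  for (int ci = 0; ci < Cin; ++ci) {
    for (int kj = -1; kj <= 1; ++kj) {
      for (int ki = -1; ki <= 1; ++ki) {
        int or0, or1, oc0, oc1, ir0, ic0;
        shift_ranges(H, W, ki, kj, or0, or1, oc0, oc1, ir0, ic0);
        if (or0 > or1 || oc0 > oc1) continue;
        const int nr = or1 - or0, nc = oc1 - oc0;
        const int r = ci * 9 + (kj + 1) * 3 + (ki + 1);
        arma::mat xin = x.slice(ci).submat(ir0, ic0, ir0 + nr, ic0 + nc);
        for (int co = 0; co < Cout; ++co)
          y.slice(co).submat(or0, oc0, or1, oc1) += w(co, r) * xin;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv3_bw(const arma::cube &x, const arma::mat &w,
                  const arma::cube &dy) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Cout = dy.n_slices;
  arma::mat dw(Cout, 9 * Cin, arma::fill::zeros);
  arma::vec db(Cout);
  for (int co = 0; co < Cout; ++co) db[co] = arma::accu(dy.slice(co));
  arma::cube dx(H, W, Cin, arma::fill::zeros);
  for (int ci = 0; ci < Cin; ++ci) {
    for (int kj = -1; kj <= 1; ++kj) {
      for (int ki = -1; ki <= 1; ++ki) {
        int or0, or1, oc0, oc1, ir0, ic0;
        shift_ranges(H, W, ki, kj, or0, or1, oc0, oc1, ir0, ic0);
        if (or0 > or1 || oc0 > oc1) continue;
        const int nr = or1 - or0, nc = oc1 - oc0;
        const int r = ci * 9 + (kj + 1) * 3 + (ki + 1);
        arma::mat xin = x.slice(ci).submat(ir0, ic0, ir0 + nr, ic0 + nc);
        for (int co = 0; co < Cout; ++co) {
          const arma::mat dys =
            dy.slice(co).submat(or0, oc0, or1, oc1);
          dw(co, r) += arma::accu(dys % xin);
          dx.slice(ci).submat(ir0, ic0, ir0 + nr, ic0 + nc) +=
            w(co, r) * dys;
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
List cpp_maxpool2_fw(const arma::cube &x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int h = H / 2, w = W / 2;
  arma::cube y(h, w, C);
  IntegerVector amax((size_t)h * w * C);
  size_t k = 0;
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < w; ++j)
      for (int i = 0; i < h; ++i) {
        double best = -1e300; int bi = 0, bj = 0;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            const double v = x(2 * i + di, 2 * j + dj, c);
            if (v > best) { best = v; bi = 2 * i + di; bj = 2 * j + dj; }
          }
        y(i, j, c) = best;
        amax[k++] = bi + bj * H + c * H * W;  // 0-based linear index into x
      }
  return List::create(_["y"] = y, _["amax"] = amax);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool2_bw(const IntegerVector &amax, const arma::cube &dy,
                           int H, int W) {
  const int C = dy.n_slices;
  arma::cube dx(H, W, C, arma::fill::zeros);
  const double *src = dy.memptr();
  double *dst = dx.memptr();
  const size_t n = dy.n_elem;
  for (size_t k = 0; k < n; ++k) dst[amax[k]] += src[k];
  return dx;
}

// [[Rcpp::export]]
arma::cube cpp_upsample2_fw(const arma::cube &x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::cube y(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        const double v = x(i, j, c);
        y(2 * i, 2 * j, c) = v;
        y(2 * i + 1, 2 * j, c) = v;
        y(2 * i, 2 * j + 1, c) = v;
        y(2 * i + 1, 2 * j + 1, c) = v;
      }
  return y;
}

// [[Rcpp::export]]
arma::cube cpp_upsample2_bw(const arma::cube &dy) {
  const int H = dy.n_rows / 2, W = dy.n_cols / 2, C = dy.n_slices;
  arma::cube dx(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        dx(i, j, c) = dy(2 * i, 2 * j, c) + dy(2 * i + 1, 2 * j, c) +
                      dy(2 * i, 2 * j + 1, c) + dy(2 * i + 1, 2 * j + 1, c);
  return dx;
}
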