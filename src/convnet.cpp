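// Convolutional primitives for the scratch-built segmentation and
// detection networks: same-padding k x k convolution (forward and
// backward via im2col), 2 x 2 max pooling, and nearest-neighbour 2 x
// upsampling. Tensors are arma::cube with dimensions (H, W, C); weights
// are (k*k*Cin) x Cout matrices so a convolution is one GEMM.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat im2col(const cube& x, int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int pad = k / 2;
  mat cols(H * W, k * k * C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int ky = 0; ky < k; ++ky) {
      for (int kx = 0; kx < k; ++kx) {
        const int col_idx = c * k * k + ky * k + kx;
        const int dy = ky - pad, dx = kx - pad;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dx;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int si = i + dy;
            if (si < 0 || si >= H) continue;
            cols(j * H + i, col_idx) = x(si, sj, c);
          }
        }
      }
    }
  }
  return cols;
}

static void col2im_acc(const mat& cols, cube& dx, int k) {
  const int H = dx.n_rows, W = dx.n_cols, C = dx.n_slices;
  const int pad = k / 2;
  for (int c = 0; c < C; ++c) {
    for (int ky = 0; ky < k; ++ky) {
      for (int kx = 0; kx < k; ++kx) {
        const int col_idx = c * k * k + ky * k + kx;
        const int dy = ky - pad, dx_ = kx - pad;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dx_;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int si = i + dy;
            if (si < 0 || si >= H) continue;
            dx(si, sj, c) += cols(j * H + i, col_idx);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
arma::cube conv2d_fwd(const arma::cube& x, const arma::mat& w,
                      const arma::vec& b, int k) {
  const int H = x.n_rows, W = x.n_cols;
  const int Cout = w.n_cols;
  mat cols = im2col(x, k);
  mat y = cols * w;
  y.each_row() += b.t();
  cube out(H, W, Cout);
  for (int c = 0; c < Cout; ++c)
    out.slice(c) = reshape(y.col(c), H, W);
  return out;
}

// [[Rcpp::export]]
Rcpp::List conv2d_bwd(const arma::cube& x, const arma::mat& w,
                      const arma::cube& dy, int k) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Cout = dy.n_slices;
  mat cols = im2col(x, k);
  mat dymat(H * W, Cout);
  for (int c = 0; c < Cout; ++c)
    dymat.col(c) = vectorise(dy.slice(c));
  mat dw = cols.t() * dymat;
  vec db = sum(dymat, 0).t();
  mat dcols = dymat * w.t();
  cube dx(H, W, Cin, fill::zeros);
  col2im_acc(dcols, dx, k);
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dw") = dw,
                            Rcpp::Named("db") = db);
}

// [[Rcpp::export]]
Rcpp::List maxpool2_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  cube y(Ho, Wo, C);
  ucube idx(Ho, Wo, C);  // linear index into the slice of the argmax
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        double best = -datum::inf;
        uword best_idx = 0;
        for (int dj = 0; dj < 2; ++dj) {
          for (int di = 0; di < 2; ++di) {
            const int si = 2 * i + di, sj = 2 * j + dj;
            const double v = x(si, sj, c);
            if (v > best) { best = v; best_idx = sj * H + si; }
          }
        }
        y(i, j, c) = best;
        idx(i, j, c) = best_idx;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube maxpool2_bwd(const arma::cube& dy, const arma::ucube& idx,
                        int H, int W) {
  const int C = dy.n_slices;
  cube dx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (uword j = 0; j < dy.n_cols; ++j) {
      for (uword i = 0; i < dy.n_rows; ++i) {
        dx.slice(c)(idx(i, j, c)) += dy(i, j, c);
      }
    }
  }
  return dx;
}

// [[Rcpp::export]]
arma::cube upsample2_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  cube y(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        const double v = x(i, j, c);
        y(2 * i, 2 * j, c) = v;
        y(2 * i + 1, 2 * j, c) = v;
        y(2 * i, 2 * j + 1, c) = v;
        y(2 * i + 1, 2 * j + 1, c) = v;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
arma::cube upsample2_bwd(const arma::cube& dy) {
  const int H = dy.n_rows / 2, W = dy.n_cols / 2, C = dy.n_slices;
  cube dx(H, W, C);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        dx(i, j, c) = dy(2 * i, 2 * j, c) + dy(2 * i + 1, 2 * j, c) +
                      dy(2 * i, 2 * j + 1, c) + dy(2 * i + 1, 2 * j + 1, c);
      }
    }
  }
  return dx;
}
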