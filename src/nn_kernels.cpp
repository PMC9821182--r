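// Minimal convolutional-network kernels used by the R layer graph.
// Layout conventions shared with R/nn-core.R:
//   activations: arma::cube H x W x C  (matches an R array dim = c(H, W, C))
//   conv weights: arma::mat Cout x (k*k*Cin), patch index = c*k*k + dj*k + di
//   tconv weights: flat vector, index = di + k*(dj + k*(c + Cin*co))
// Convolutions are stride 1 with "same" zero padding (k odd).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat im2col(const arma::cube& x, int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int p = (k - 1) / 2;
  arma::mat cols(k * k * C, H * W, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int dj = 0; dj < k; ++dj)
      for (int di = 0; di < k; ++di) {
        const int row = c * k * k + dj * k + di;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj - p;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int si = i + di - p;
            if (si < 0 || si >= H) continue;
            cols(row, j * H + i) = x(si, sj, c);
          }
        }
      }
  return cols;
}

// [[Rcpp::export]]
arma::cube conv2d_fw(const arma::cube& x, const arma::mat& w,
                     const arma::vec& b, int k) {
  const int H = x.n_rows, W = x.n_cols;
  const int Cout = w.n_rows;
  arma::mat cols = im2col(x, k);
  arma::mat y = w * cols;             // Cout x (H*W)
  y.each_col() += b;
  arma::cube out(H, W, Cout);
  for (int co = 0; co < Cout; ++co)
    out.slice(co) = arma::reshape(y.row(co).t(), H, W);
  return out;
}

// [[Rcpp::export]]
List conv2d_bw(const arma::cube& x, const arma::mat& w,
               const arma::cube& dy, int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Cout = w.n_rows;
  const int p = (k - 1) / 2;
  arma::mat dymat(Cout, H * W);
  for (int co = 0; co < Cout; ++co)
    dymat.row(co) = arma::vectorise(dy.slice(co)).t();
  arma::mat cols = im2col(x, k);
  arma::mat dw = dymat * cols.t();
  arma::vec db = arma::sum(dymat, 1);
  // dX via col2im of w^T * dY
  arma::mat dcols = w.t() * dymat;    // (k*k*C) x (H*W)
  arma::cube dx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int dj = 0; dj < k; ++dj)
      for (int di = 0; di < k; ++di) {
        const int row = c * k * k + dj * k + di;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj - p;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int si = i + di - p;
            if (si < 0 || si >= H) continue;
            dx(si, sj, c) += dcols(row, j * H + i);
          }
        }
      }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2 max pooling, stride 2; H and W must be even.
// [[Rcpp::export]]
List maxpool2_fw(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  arma::cube y(Ho, Wo, C);
  arma::icube idx(Ho, Wo, C);         // linear index into the slice
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        double best = -1e300; int bi = 0;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            const int si = 2 * i + di, sj = 2 * j + dj;
            const double v = x(si, sj, c);
            if (v > best) { best = v; bi = sj * H + si; }
          }
        y(i, j, c) = best;
        idx(i, j, c) = bi;
      }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube maxpool2_bw(const arma::cube& dy, const arma::icube& idx,
                       int H, int W) {
  const int C = dy.n_slices;
  arma::cube dx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (unsigned j = 0; j < dy.n_cols; ++j)
      for (unsigned i = 0; i < dy.n_rows; ++i) {
        const int li = idx(i, j, c);
        dx(li % H, li / H, c) += dy(i, j, c);
      }
  return dx;
}

// Transposed convolution, stride s, symmetric padding p:
//   out[(i*s - p + di), (j*s - p + dj), co] += x[i,j,c] * w[di,dj,c,co]
// Output size Ho = (Hi - 1)*s + k - 2p.
// [[Rcpp::export]]
arma::cube tconv_fw(const arma::cube& x, const arma::vec& w,
                    const arma::vec& b, int k, int s, int p, int Cout) {
  const int Hi = x.n_rows, Wi = x.n_cols, Cin = x.n_slices;
  const int Ho = (Hi - 1) * s + k - 2 * p;
  const int Wo = (Wi - 1) * s + k - 2 * p;
  arma::cube out(Ho, Wo, Cout);
  for (int co = 0; co < Cout; ++co) out.slice(co).fill(b(co));
  for (int co = 0; co < Cout; ++co)
    for (int c = 0; c < Cin; ++c)
      for (int j = 0; j < Wi; ++j)
        for (int i = 0; i < Hi; ++i) {
          const double v = x(i, j, c);
          if (v == 0.0) continue;
          const int oi0 = i * s - p, oj0 = j * s - p;
          for (int dj = 0; dj < k; ++dj) {
            const int oj = oj0 + dj;
            if (oj < 0 || oj >= Wo) continue;
            for (int di = 0; di < k; ++di) {
              const int oi = oi0 + di;
              if (oi < 0 || oi >= Ho) continue;
              out(oi, oj, co) += v * w[di + k * (dj + k * (c + Cin * co))];
            }
          }
        }
  return out;
}

// [[Rcpp::export]]
List tconv_bw(const arma::cube& x, const arma::vec& w, const arma::cube& dy,
              int k, int s, int p, int Cout) {
  const int Hi = x.n_rows, Wi = x.n_cols, Cin = x.n_slices;
  const int Ho = dy.n_rows, Wo = dy.n_cols;
  arma::cube dx(Hi, Wi, Cin, arma::fill::zeros);
  arma::vec dw(w.n_elem, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  for (int co = 0; co < Cout; ++co) db(co) = arma::accu(dy.slice(co));
  for (int co = 0; co < Cout; ++co)
    for (int c = 0; c < Cin; ++c)
      for (int j = 0; j < Wi; ++j)
        for (int i = 0; i < Hi; ++i) {
          const int oi0 = i * s - p, oj0 = j * s - p;
          const double xv = x(i, j, c);
          double acc = 0.0;
          for (int dj = 0; dj < k; ++dj) {
            const int oj = oj0 + dj;
            if (oj < 0 || oj >= Wo) continue;
            for (int di = 0; di < k; ++di) {
              const int oi = oi0 + di;
              if (oi < 0 || oi >= Ho) continue;
              const double g = dy(oi, oj, co);
              const int wi = di + k * (dj + k * (c + Cin * co));
              acc += g * w[wi];
              dw[wi] += g * xv;
            }
          }
          dx(i, j, c) += acc;
        }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}
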