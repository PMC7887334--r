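// Numerical kernels: affine warping, separable Gaussian blur, strided 2-D
// convolution (forward and backward via im2col/col2im), nearest-neighbour
// 2x upsampling, and block reductions for mask downsampling.
//
// Image convention: matrices are (rows = y, cols = x); point coordinates are
// 0-based with pixel centres at integer positions.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double sample_bilinear(const arma::mat& img, double sy, double sx,
                                     double fill) {
  const int H = img.n_rows, W = img.n_cols;
  if (sx < -1.0 || sx > W || sy < -1.0 || sy > H) return fill;
  const int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy);
  const double fx = sx - x0, fy = sy - y0;
  double v00 = fill, v01 = fill, v10 = fill, v11 = fill;
  if (y0 >= 0 && y0 < H && x0 >= 0 && x0 < W) v00 = img(y0, x0);
  if (y0 >= 0 && y0 < H && x0 + 1 >= 0 && x0 + 1 < W) v01 = img(y0, x0 + 1);
  if (y0 + 1 >= 0 && y0 + 1 < H && x0 >= 0 && x0 < W) v10 = img(y0 + 1, x0);
  if (y0 + 1 >= 0 && y0 + 1 < H && x0 + 1 >= 0 && x0 + 1 < W) v11 = img(y0 + 1, x0 + 1);
  return (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11);
}

// Output pixel (x, y) (0-based) samples the source image at
// src = M %*% c(x, y) + b, bilinearly, with constant fill outside support.
// [[Rcpp::export]]
arma::mat warp_affine_cpp(const arma::mat& img, const arma::mat& M,
                          const arma::vec& b, int out_h, int out_w, double fill) {
  arma::mat out(out_h, out_w);
  const double m00 = M(0, 0), m01 = M(0, 1), m10 = M(1, 0), m11 = M(1, 1);
  for (int c = 0; c < out_w; ++c) {
    for (int r = 0; r < out_h; ++r) {
      const double x = (double)c, y = (double)r;
      const double sx = m00 * x + m01 * y + b(0);
      const double sy = m10 * x + m11 * y + b(1);
      out(r, c) = sample_bilinear(img, sy, sx, fill);
    }
  }
  return out;
}

// [[Rcpp::export]]
arma::mat gaussian_blur_cpp(const arma::mat& img, double sigma) {
  if (sigma <= 0) return img;
  const int rad = std::max(1, (int)std::ceil(3.0 * sigma));
  arma::vec k(2 * rad + 1);
  for (int i = -rad; i <= rad; ++i)
    k(i + rad) = std::exp(-0.5 * (double)(i * i) / (sigma * sigma));
  k /= arma::accu(k);
  const int H = img.n_rows, W = img.n_cols;
  arma::mat tmp(H, W), out(H, W);
  // horizontal pass, reflected edges
  for (int r = 0; r < H; ++r)
    for (int c = 0; c < W; ++c) {
      double s = 0;
      for (int i = -rad; i <= rad; ++i) {
        int cc = c + i;
        if (cc < 0) cc = -cc - 1;
        if (cc >= W) cc = 2 * W - cc - 1;
        s += k(i + rad) * img(r, cc);
      }
      tmp(r, c) = s;
    }
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      double s = 0;
      for (int i = -rad; i <= rad; ++i) {
        int rr = r + i;
        if (rr < 0) rr = -rr - 1;
        if (rr >= H) rr = 2 * H - rr - 1;
        s += k(i + rad) * tmp(rr, c);
      }
      out(r, c) = s;
    }
  return out;
}

static arma::mat im2col(const arma::cube& x, int k, int stride, int pad,
                        int oh, int ow) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat cols(k * k * C, oh * ow, arma::fill::zeros);
  for (int ch = 0; ch < C; ++ch) {
    const arma::mat& xs = x.slice(ch);
    for (int kx = 0; kx < k; ++kx) {
      for (int ky = 0; ky < k; ++ky) {
        const int row = ch * k * k + kx * k + ky;
        for (int j = 0; j < ow; ++j) {
          const int sc = j * stride - pad + kx;
          if (sc < 0 || sc >= W) continue;
          for (int i = 0; i < oh; ++i) {
            const int sr = i * stride - pad + ky;
            if (sr < 0 || sr >= H) continue;
            cols(row, i + j * oh) = xs(sr, sc);
          }
        }
      }
    }
  }
  return cols;
}

static arma::cube col2im(const arma::mat& cols, int H, int W, int C, int k,
                         int stride, int pad, int oh, int ow) {
  arma::cube x(H, W, C, arma::fill::zeros);
  for (int ch = 0; ch < C; ++ch) {
    arma::mat& xs = x.slice(ch);
    for (int kx = 0; kx < k; ++kx) {
      for (int ky = 0; ky < k; ++ky) {
        const int row = ch * k * k + kx * k + ky;
        for (int j = 0; j < ow; ++j) {
          const int sc = j * stride - pad + kx;
          if (sc < 0 || sc >= W) continue;
          for (int i = 0; i < oh; ++i) {
            const int sr = i * stride - pad + ky;
            if (sr < 0 || sr >= H) continue;
            xs(sr, sc) += cols(row, i + j * oh);
          }
        }
      }
    }
  }
  return x;
}

// x: (H, W, Cin); W_: (k*k*Cin, Cout) with row order ch*k*k + kx*k + ky;
// returns (oh, ow, Cout) with oh = (H + 2*pad - k)/stride + 1.
// [[Rcpp::export]]
arma::cube conv2d_fwd_cpp(const arma::cube& x, const arma::mat& W_,
                          const arma::vec& b, int k, int stride, int pad) {
  const int H = x.n_rows, Wd = x.n_cols;
  const int oh = (H + 2 * pad - k) / stride + 1;
  const int ow = (Wd + 2 * pad - k) / stride + 1;
  const int Cout = W_.n_cols;
  arma::mat cols = im2col(x, k, stride, pad, oh, ow);
  arma::mat o = W_.t() * cols;   // (Cout, oh*ow)
  o.each_col() += b;
  arma::cube out(oh, ow, Cout);
  for (int co = 0; co < Cout; ++co)
    out.slice(co) = arma::reshape(o.row(co), oh, ow);
  return out;
}

// [[Rcpp::export]]
List conv2d_bwd_cpp(const arma::cube& x, const arma::mat& W_,
                    const arma::cube& gout, int k, int stride, int pad) {
  const int H = x.n_rows, Wd = x.n_cols, C = x.n_slices;
  const int oh = gout.n_rows, ow = gout.n_cols, Cout = gout.n_slices;
  arma::mat G(Cout, oh * ow);
  for (int co = 0; co < Cout; ++co)
    G.row(co) = arma::vectorise(gout.slice(co)).t();
  arma::mat cols = im2col(x, k, stride, pad, oh, ow);
  arma::mat gW = cols * G.t();
  arma::vec gb = arma::sum(G, 1);
  arma::mat gcols = W_ * G;
  arma::cube gx = col2im(gcols, H, Wd, C, k, stride, pad, oh, ow);
  return List::create(_["gx"] = gx, _["gW"] = gW, _["gb"] = gb);
}

// [[Rcpp::export]]
arma::cube upsample2_cpp(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::cube out(2 * H, 2 * W, C);
  for (int ch = 0; ch < C; ++ch)
    for (int c = 0; c < W; ++c)
      for (int r = 0; r < H; ++r) {
        const double v = x(r, c, ch);
        out(2 * r, 2 * c, ch) = v;
        out(2 * r + 1, 2 * c, ch) = v;
        out(2 * r, 2 * c + 1, ch) = v;
        out(2 * r + 1, 2 * c + 1, ch) = v;
      }
  return out;
}

// adjoint of nearest-neighbour 2x upsampling: 2x2 block sums
// [[Rcpp::export]]
arma::cube upsample2_bwd_cpp(const arma::cube& g) {
  const int H = g.n_rows / 2, W = g.n_cols / 2, C = g.n_slices;
  arma::cube out(H, W, C);
  for (int ch = 0; ch < C; ++ch)
    for (int c = 0; c < W; ++c)
      for (int r = 0; r < H; ++r)
        out(r, c, ch) = g(2 * r, 2 * c, ch) + g(2 * r + 1, 2 * c, ch) +
                        g(2 * r, 2 * c + 1, ch) + g(2 * r + 1, 2 * c + 1, ch);
  return out;
}

// block reduction of a square matrix; type 0 = max, 1 = mean
// [[Rcpp::export]]
arma::mat block_reduce_cpp(const arma::mat& m, int block, int type) {
  const int oh = m.n_rows / block, ow = m.n_cols / block;
  arma::mat out(oh, ow);
  for (int j = 0; j < ow; ++j)
    for (int i = 0; i < oh; ++i) {
      const arma::mat sub = m.submat(i * block, j * block,
                                     (i + 1) * block - 1, (j + 1) * block - 1);
      out(i, j) = (type == 0) ? sub.max() : arma::accu(sub) / (block * block);
    }
  return out;
}
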