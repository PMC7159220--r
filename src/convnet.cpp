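#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Activation layout ("matrix form"): a batch of C-channel (h x w) feature
// maps over n images is a double matrix with h*w*n rows (row index
// r = hh + h*ww + h*w*nn, i.e. hh fastest) and C columns. This keeps every
// convolution a single dense GEMM and avoids 4-D array permutations.
// im2col column index: k = c*(kh*kw) + j*kh + i (kernel row i fastest),
// matching the (kh*kw*Cin) x Cout weight matrices on the R side.
// Convolutions are "valid"; GEMMs run in single precision (arma::fmat).

// im2col for an image sub-range [n0, n1) into a preallocated fmat whose
// rows cover oh*ow*(n1-n0).
static void im2col_chunk(const double* a, int h, int w, int n, int C,
                         int kh, int kw, int n0, int n1, arma::fmat& xc) {
  const int oh = h - kh + 1, ow = w - kw + 1;
  for (int c = 0; c < C; ++c) {
    const double* ac = a + (size_t)c * h * w * n;
    for (int j = 0; j < kw; ++j)
      for (int i = 0; i < kh; ++i) {
        float* dst = xc.colptr((arma::uword)c * kh * kw + j * kh + i);
        for (int nn = n0; nn < n1; ++nn) {
          const double* an = ac + (size_t)nn * h * w;
          for (int ww = 0; ww < ow; ++ww) {
            const double* s = an + (size_t)(ww + j) * h + i;
            float* d = dst + (size_t)(nn - n0) * oh * ow + (size_t)ww * oh;
            for (int hh = 0; hh < oh; ++hh) d[hh] = (float)s[hh];
          }
        }
      }
  }
}

// Images per chunk keeping the im2col buffer around 8 MB.
static int conv_chunk(int oh, int ow, int cols, int n) {
  int per = (int)(2000000.0 / ((double)oh * ow * cols));
  if (per < 1) per = 1;
  if (per > n) per = n;
  return per;
}

// [[Rcpp::export]]
NumericMatrix cpp_conv_fwd(NumericMatrix A, IntegerVector hwn,
                           NumericMatrix W, NumericVector b,
                           int kh, int kw) {
  const int h = hwn[0], w = hwn[1], n = hwn[2], C = A.ncol();
  const int oh = h - kh + 1, ow = w - kw + 1, Cout = W.ncol();
  if (oh <= 0 || ow <= 0) stop("input smaller than kernel");
  arma::fmat Wf = arma::conv_to<arma::fmat>::from(
      arma::mat(W.begin(), W.nrow(), W.ncol(), false));
  NumericMatrix out((size_t)oh * ow * n, Cout);
  const int step = conv_chunk(oh, ow, C * kh * kw, n);
  arma::fmat xc((arma::uword)oh * ow * step, (arma::uword)C * kh * kw);
  for (int n0 = 0; n0 < n; n0 += step) {
    const int n1 = std::min(n, n0 + step);
    if (n1 - n0 != step)
      xc.set_size((arma::uword)oh * ow * (n1 - n0), (arma::uword)C * kh * kw);
    im2col_chunk(A.begin(), h, w, n, C, kh, kw, n0, n1, xc);
    arma::fmat Y = xc * Wf;
    for (int c = 0; c < Cout; ++c) {
      const float* s = Y.colptr(c);
      double* d = &out((size_t)oh * ow * n0, c);
      const double bc = b[c];
      for (arma::uword r = 0; r < Y.n_rows; ++r) d[r] = (double)s[r] + bc;
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv_bwd(NumericMatrix A, IntegerVector hwn, NumericMatrix W,
                  NumericMatrix dY, int kh, int kw, bool need_dA) {
  const int h = hwn[0], w = hwn[1], n = hwn[2], C = A.ncol();
  const int oh = h - kh + 1, ow = w - kw + 1, Cout = W.ncol();
  arma::fmat Wf = arma::conv_to<arma::fmat>::from(
      arma::mat(W.begin(), W.nrow(), W.ncol(), false));
  arma::fmat dW((arma::uword)W.nrow(), (arma::uword)Cout, arma::fill::zeros);
  NumericMatrix dA(need_dA ? (size_t)h * w * n : 1, C);
  const int step = conv_chunk(oh, ow, C * kh * kw, n);
  arma::fmat xc((arma::uword)oh * ow * step, (arma::uword)C * kh * kw);
  arma::fmat dYc((arma::uword)oh * ow * step, (arma::uword)Cout);
  for (int n0 = 0; n0 < n; n0 += step) {
    const int n1 = std::min(n, n0 + step);
    const arma::uword rows = (arma::uword)oh * ow * (n1 - n0);
    if ((arma::uword)xc.n_rows != rows) {
      xc.set_size(rows, (arma::uword)C * kh * kw);
      dYc.set_size(rows, (arma::uword)Cout);
    }
    im2col_chunk(A.begin(), h, w, n, C, kh, kw, n0, n1, xc);
    for (int c = 0; c < Cout; ++c) {
      const double* s = &dY((size_t)oh * ow * n0, c);
      float* d = dYc.colptr(c);
      for (arma::uword r = 0; r < rows; ++r) d[r] = (float)s[r];
    }
    dW += xc.t() * dYc;
    if (need_dA) {
      arma::fmat dXc = dYc * Wf.t();
      for (int c = 0; c < C; ++c) {
        double* ac = &dA(0, c);
        for (int j = 0; j < kw; ++j)
          for (int i = 0; i < kh; ++i) {
            const float* src = dXc.colptr((arma::uword)c * kh * kw + j * kh + i);
            for (int nn = n0; nn < n1; ++nn) {
              double* an = ac + (size_t)nn * h * w;
              for (int ww = 0; ww < ow; ++ww) {
                double* d = an + (size_t)(ww + j) * h + i;
                const float* s = src + (size_t)(nn - n0) * oh * ow +
                                 (size_t)ww * oh;
                for (int hh = 0; hh < oh; ++hh) d[hh] += (double)s[hh];
              }
            }
          }
      }
    }
  }
  NumericMatrix dWr(W.nrow(), Cout);
  NumericVector db(Cout);
  for (int c = 0; c < Cout; ++c) {
    for (int r = 0; r < W.nrow(); ++r) dWr(r, c) = (double)dW(r, c);
    double s = 0;
    const double* dyc = &dY(0, c);
    for (int r = 0; r < dY.nrow(); ++r) s += dyc[r];
    db[c] = s;
  }
  return List::create(_["dW"] = dWr, _["db"] = db, _["dA"] = dA);
}

// Double-precision im2col in matrix layout (used by the relevance
// propagation, where exact elementwise products matter and n is 1).
// [[Rcpp::export]]
NumericMatrix cpp_im2col_mat(NumericMatrix A, IntegerVector hwn,
                             int kh, int kw) {
  const int h = hwn[0], w = hwn[1], n = hwn[2], C = A.ncol();
  const int oh = h - kh + 1, ow = w - kw + 1;
  if (oh <= 0 || ow <= 0) stop("input smaller than kernel");
  NumericMatrix out((size_t)oh * ow * n, C * kh * kw);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < kw; ++j)
      for (int i = 0; i < kh; ++i) {
        double* dst = &out(0, (size_t)c * kh * kw + j * kh + i);
        for (int nn = 0; nn < n; ++nn) {
          const double* an = &A(0, c) + (size_t)nn * h * w;
          for (int ww = 0; ww < ow; ++ww) {
            const double* s = an + (size_t)(ww + j) * h + i;
            double* d = dst + (size_t)nn * oh * ow + (size_t)ww * oh;
            for (int hh = 0; hh < oh; ++hh) d[hh] = s[hh];
          }
        }
      }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_col2im_mat(NumericMatrix M, IntegerVector hwn,
                             int kh, int kw) {
  const int h = hwn[0], w = hwn[1], n = hwn[2];
  const int oh = h - kh + 1, ow = w - kw + 1;
  const int C = M.ncol() / (kh * kw);
  NumericMatrix out((size_t)h * w * n, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < kw; ++j)
      for (int i = 0; i < kh; ++i) {
        const double* src = &M(0, (size_t)c * kh * kw + j * kh + i);
        for (int nn = 0; nn < n; ++nn) {
          double* an = &out(0, c) + (size_t)nn * h * w;
          for (int ww = 0; ww < ow; ++ww) {
            double* d = an + (size_t)(ww + j) * h + i;
            const double* s = src + (size_t)nn * oh * ow + (size_t)ww * oh;
            for (int hh = 0; hh < oh; ++hh) d[hh] += s[hh];
          }
        }
      }
  return out;
}

// 2x2 max pooling, stride 2, floor sizing, on matrix-form activations.
// idx holds 1-based linear indices into A (per column block), reused by the
// backward pass and by winner-routing of relevance.
// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericMatrix A, IntegerVector hwn) {
  const int h = hwn[0], w = hwn[1], n = hwn[2], C = A.ncol();
  const int oh = h / 2, ow = w / 2;
  NumericMatrix Y((size_t)oh * ow * n, C);
  IntegerVector idx((size_t)oh * ow * n * C);
  for (int c = 0; c < C; ++c) {
    const double* ac = &A(0, c);
    double* yc = &Y(0, c);
    int* ic = idx.begin() + (size_t)c * oh * ow * n;
    for (int nn = 0; nn < n; ++nn) {
      const size_t abase = (size_t)nn * h * w;
      const size_t ybase = (size_t)nn * oh * ow;
      for (int ww = 0; ww < ow; ++ww)
        for (int hh = 0; hh < oh; ++hh) {
          size_t best = abase + (size_t)(2 * ww) * h + 2 * hh;
          for (int dj = 0; dj < 2; ++dj)
            for (int di = 0; di < 2; ++di) {
              size_t k = abase + (size_t)(2 * ww + dj) * h + 2 * hh + di;
              if (ac[k] > ac[best]) best = k;
            }
          yc[ybase + (size_t)ww * oh + hh] = ac[best];
          ic[ybase + (size_t)ww * oh + hh] = (int)best + 1;
        }
    }
  }
  return List::create(_["y"] = Y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericMatrix cpp_maxpool_bwd(NumericMatrix dY, IntegerVector idx,
                              IntegerVector hwn, int C) {
  const int h = hwn[0], w = hwn[1], n = hwn[2];
  NumericMatrix dA((size_t)h * w * n, C);
  const size_t block = dY.nrow();
  for (int c = 0; c < C; ++c) {
    const double* dyc = &dY(0, c);
    double* dac = &dA(0, c);
    const int* ic = idx.begin() + (size_t)c * block;
    for (size_t r = 0; r < block; ++r) dac[ic[r] - 1] += dyc[r];
  }
  return dA;
}

// [[Rcpp::export]]
NumericMatrix cpp_relu(NumericMatrix A) {
  NumericMatrix Y(A.nrow(), A.ncol());
  const double* s = A.begin();
  double* d = Y.begin();
  const size_t len = (size_t)A.nrow() * A.ncol();
  for (size_t i = 0; i < len; ++i) d[i] = s[i] > 0 ? s[i] : 0;
  return Y;
}

// [[Rcpp::export]]
NumericMatrix cpp_relu_bwd(NumericMatrix G, NumericMatrix Y) {
  NumericMatrix D(G.nrow(), G.ncol());
  const double* g = G.begin();
  const double* y = Y.begin();
  double* d = D.begin();
  const size_t len = (size_t)G.nrow() * G.ncol();
  for (size_t i = 0; i < len; ++i) d[i] = y[i] > 0 ? g[i] : 0;
  return D;
}

// (h*w*n) x C matrix form -> N x (h*w*C) row-per-image matrix for the
// dense layers; column order within a row: hh fastest, then ww, then c.
// [[Rcpp::export]]
NumericMatrix cpp_flatten_mat(NumericMatrix A, IntegerVector hwn) {
  const int h = hwn[0], w = hwn[1], n = hwn[2], C = A.ncol();
  NumericMatrix out(n, (size_t)h * w * C);
  for (int c = 0; c < C; ++c) {
    const double* ac = &A(0, c);
    for (int nn = 0; nn < n; ++nn) {
      const double* s = ac + (size_t)nn * h * w;
      for (int k = 0; k < h * w; ++k)
        out(nn, (size_t)c * h * w + k) = s[k];
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_unflatten_mat(NumericMatrix X, IntegerVector hwn, int C) {
  const int h = hwn[0], w = hwn[1], n = hwn[2];
  NumericMatrix out((size_t)h * w * n, C);
  for (int c = 0; c < C; ++c) {
    double* ac = &out(0, c);
    for (int nn = 0; nn < n; ++nn) {
      double* d = ac + (size_t)nn * h * w;
      for (int k = 0; k < h * w; ++k)
        d[k] = X(nn, (size_t)c * h * w + k);
    }
  }
  return out;
}
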