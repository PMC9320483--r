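// Numeric kernels for the reduced U-Net: im2col/GEMM convolutions with exact
// adjoints, pooling, nearest up-sampling, and 8-connected labelling.
// Single precision internally; R interfaces stay double.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::fcube as_fcube(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 3) stop("expected a 3-d array");
  arma::fcube out(d[0], d[1], d[2]);
  const double* src = x.begin();
  float* dst = out.memptr();
  const size_t n = out.n_elem;
  for (size_t i = 0; i < n; ++i) dst[i] = static_cast<float>(src[i]);
  return out;
}

static NumericVector as_rarray(const arma::fcube& x) {
  NumericVector out(x.n_elem);
  const float* src = x.memptr();
  for (size_t i = 0; i < x.n_elem; ++i) out[i] = static_cast<double>(src[i]);
  out.attr("dim") = IntegerVector::create(x.n_rows, x.n_cols, x.n_slices);
  return out;
}

static inline int out_side(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// Columns indexed dy + k*dx + k*k*c (dy fastest); rows indexed i + Ho*j.
static arma::fmat im2col(const arma::fcube& x, int k, int stride, int pad,
                         int Ho, int Wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::fmat A(static_cast<size_t>(Ho) * Wo, static_cast<size_t>(k) * k * C,
               arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dx = 0; dx < k; ++dx) {
      for (int dy = 0; dy < k; ++dy) {
        const size_t col = dy + k * dx + static_cast<size_t>(k) * k * c;
        for (int j = 0; j < Wo; ++j) {
          const int ic = j * stride + dx - pad;
          if (ic < 0 || ic >= W) continue;
          for (int i = 0; i < Ho; ++i) {
            const int ir = i * stride + dy - pad;
            if (ir < 0 || ir >= H) continue;
            A(i + static_cast<size_t>(Ho) * j, col) = x(ir, ic, c);
          }
        }
      }
    }
  }
  return A;
}

static void col2im_add(arma::fcube& gx, const arma::fmat& GA, int k, int stride,
                       int pad, int Ho, int Wo) {
  const int H = gx.n_rows, W = gx.n_cols, C = gx.n_slices;
  for (int c = 0; c < C; ++c) {
    for (int dx = 0; dx < k; ++dx) {
      for (int dy = 0; dy < k; ++dy) {
        const size_t col = dy + k * dx + static_cast<size_t>(k) * k * c;
        for (int j = 0; j < Wo; ++j) {
          const int ic = j * stride + dx - pad;
          if (ic < 0 || ic >= W) continue;
          for (int i = 0; i < Ho; ++i) {
            const int ir = i * stride + dy - pad;
            if (ir < 0 || ir >= H) continue;
            gx(ir, ic, c) += GA(i + static_cast<size_t>(Ho) * j, col);
          }
        }
      }
    }
  }
}

// x: (H,W,Cin); w: (k*k*Cin, Cout) with rows dy-fastest; b: length Cout.
// [[Rcpp::export]]
NumericVector cpp_conv_fw(NumericVector x, NumericMatrix w, NumericVector b,
                          int k, int stride, int pad) {
  arma::fcube xc = as_fcube(x);
  const int Ho = out_side(xc.n_rows, k, stride, pad);
  const int Wo = out_side(xc.n_cols, k, stride, pad);
  const int Cout = w.ncol();
  arma::fmat W(w.nrow(), Cout);
  for (int j = 0; j < Cout; ++j)
    for (int i = 0; i < w.nrow(); ++i) W(i, j) = static_cast<float>(w(i, j));
  arma::fmat A = im2col(xc, k, stride, pad, Ho, Wo);
  arma::fmat O = A * W;
  for (int j = 0; j < Cout; ++j) O.col(j) += static_cast<float>(b[j]);
  arma::fcube out(Ho, Wo, Cout);
  std::copy(O.memptr(), O.memptr() + O.n_elem, out.memptr());
  return as_rarray(out);
}

// [[Rcpp::export]]
List cpp_conv_bw(NumericVector x, NumericMatrix w, NumericVector gout,
                 int k, int stride, int pad) {
  arma::fcube xc = as_fcube(x);
  arma::fcube gc = as_fcube(gout);
  const int Ho = gc.n_rows, Wo = gc.n_cols, Cout = gc.n_slices;
  arma::fmat W(w.nrow(), w.ncol());
  for (int j = 0; j < w.ncol(); ++j)
    for (int i = 0; i < w.nrow(); ++i) W(i, j) = static_cast<float>(w(i, j));
  arma::fmat G(static_cast<size_t>(Ho) * Wo, Cout);
  std::copy(gc.memptr(), gc.memptr() + gc.n_elem, G.memptr());

  arma::fmat A = im2col(xc, k, stride, pad, Ho, Wo);
  arma::fmat gW = A.t() * G;
  arma::frowvec gb = arma::sum(G, 0);
  arma::fmat GA = G * W.t();
  arma::fcube gx(xc.n_rows, xc.n_cols, xc.n_slices, arma::fill::zeros);
  col2im_add(gx, GA, k, stride, pad, Ho, Wo);

  NumericMatrix gWr(w.nrow(), w.ncol());
  for (int j = 0; j < w.ncol(); ++j)
    for (int i = 0; i < w.nrow(); ++i) gWr(i, j) = gW(i, j);
  NumericVector gbr(Cout);
  for (int j = 0; j < Cout; ++j) gbr[j] = gb(j);
  return List::create(_["gx"] = as_rarray(gx), _["gw"] = gWr, _["gb"] = gbr);
}

// [[Rcpp::export]]
List cpp_maxpool_fw(NumericVector x, int k, int stride, int pad) {
  arma::fcube xc = as_fcube(x);
  const int H = xc.n_rows, W = xc.n_cols, C = xc.n_slices;
  const int Ho = out_side(H, k, stride, pad);
  const int Wo = out_side(W, k, stride, pad);
  arma::fcube out(Ho, Wo, C);
  IntegerVector arg(static_cast<size_t>(Ho) * Wo * C);
  size_t idx = 0;
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        float best = -std::numeric_limits<float>::infinity();
        int besti = -1;
        for (int dx = 0; dx < k; ++dx) {
          const int ic = j * stride + dx - pad;
          if (ic < 0 || ic >= W) continue;
          for (int dy = 0; dy < k; ++dy) {
            const int ir = i * stride + dy - pad;
            if (ir < 0 || ir >= H) continue;
            const float v = xc(ir, ic, c);
            if (v > best) { best = v; besti = ir + H * ic + H * W * c; }
          }
        }
        out(i, j, c) = best;
        arg[i + static_cast<size_t>(Ho) * j + static_cast<size_t>(Ho) * Wo * c] =
            besti;
        ++idx;
      }
    }
  }
  (void)idx;
  return List::create(_["out"] = as_rarray(out), _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bw(NumericVector gout, IntegerVector argmax,
                             int H, int W, int C) {
  NumericVector gx(static_cast<size_t>(H) * W * C);
  const int n = gout.size();
  for (int t = 0; t < n; ++t) {
    const int a = argmax[t];
    if (a >= 0) gx[a] += gout[t];
  }
  gx.attr("dim") = IntegerVector::create(H, W, C);
  return gx;
}

// [[Rcpp::export]]
NumericVector cpp_up2_fw(NumericVector x) {
  arma::fcube xc = as_fcube(x);
  const int H = xc.n_rows, W = xc.n_cols, C = xc.n_slices;
  arma::fcube out(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        const float v = xc(i, j, c);
        out(2 * i, 2 * j, c) = v;
        out(2 * i + 1, 2 * j, c) = v;
        out(2 * i, 2 * j + 1, c) = v;
        out(2 * i + 1, 2 * j + 1, c) = v;
      }
  return as_rarray(out);
}

// [[Rcpp::export]]
NumericVector cpp_up2_bw(NumericVector gout) {
  arma::fcube gc = as_fcube(gout);
  const int H = gc.n_rows / 2, W = gc.n_cols / 2, C = gc.n_slices;
  arma::fcube gx(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        gx(i, j, c) = gc(2 * i, 2 * j, c) + gc(2 * i + 1, 2 * j, c) +
                      gc(2 * i, 2 * j + 1, c) + gc(2 * i + 1, 2 * j + 1, c);
  return as_rarray(gx);
}

// 8-connected labelling of a binary matrix; labels 1..n in first-encounter order.
// [[Rcpp::export]]
IntegerMatrix cpp_label8(LogicalMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> stack;
  int next = 0;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      stack.push_back(i + H * j);
      lab(i, j) = next;
      while (!stack.empty()) {
        const int p = stack.back();
        stack.pop_back();
        const int pi = p % H, pj = p / H;
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            const int qi = pi + di, qj = pj + dj;
            if (qi < 0 || qi >= H || qj < 0 || qj >= W) continue;
            if (mask(qi, qj) && lab(qi, qj) == 0) {
              lab(qi, qj) = next;
              stack.push_back(qi + H * qj);
            }
          }
        }
      }
    }
  }
  return lab;
}
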