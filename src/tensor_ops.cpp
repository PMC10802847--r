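// Dense tensor kernels for the one-stage detector: 2-D convolution as
// im2col + GEMM, and stride-1 max pooling (spatial pyramid pooling).
// Feature maps are (H, W, C) arrays in R's column-major layout; convolution
// weights are (kh, kw, Cin, Cout) arrays, so flattening the first three
// dimensions matches the im2col column ordering exactly.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export(name = ".conv2d_cpp")]]
NumericVector conv2d_cpp(NumericVector input, NumericVector weights,
                         NumericVector bias, int stride, int pad) {
  IntegerVector di = input.attr("dim");
  IntegerVector dw = weights.attr("dim");
  const int H = di[0], W = di[1], C = di[2];
  const int kh = dw[0], kw = dw[1], Cin = dw[2], Cout = dw[3];
  if (Cin != C) stop("channel mismatch: input %d, weights expect %d", C, Cin);
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;

  const arma::mat X(const_cast<double*>(input.begin()), H * W, C, false, true);
  const arma::mat Wm(const_cast<double*>(weights.begin()), kh * kw * Cin, Cout,
                     false, true);

  arma::mat cols(Ho * Wo, kh * kw * Cin, arma::fill::zeros);
  for (int c = 0; c < Cin; ++c) {
    for (int dj = 0; dj < kw; ++dj) {
      for (int dii = 0; dii < kh; ++dii) {
        const int col_idx = dii + kh * dj + kh * kw * c;
        double* dst = cols.colptr(col_idx);
        const double* src = X.colptr(c);
        for (int j = 0; j < Wo; ++j) {
          const int sj = j * stride - pad + dj;
          if (sj < 0 || sj >= W) continue;
          const double* srcc = src + (size_t)sj * H;
          for (int i = 0; i < Ho; ++i) {
            const int si = i * stride - pad + dii;
            if (si < 0 || si >= H) continue;
            dst[i + (size_t)j * Ho] = srcc[si];
          }
        }
      }
    }
  }

  arma::mat out = cols * Wm;  // (Ho*Wo, Cout)
  for (int o = 0; o < Cout; ++o) out.col(o) += bias[o];

  NumericVector res(Ho * Wo * Cout);
  std::copy(out.begin(), out.end(), res.begin());
  res.attr("dim") = IntegerVector::create(Ho, Wo, Cout);
  return res;
}

// [[Rcpp::export(name = ".maxpool2d_cpp")]]
NumericVector maxpool2d_cpp(NumericVector input, int k, int stride, int pad) {
  IntegerVector di = input.attr("dim");
  const int H = di[0], W = di[1], C = di[2];
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector res(Ho * Wo * C);
  const double* x = input.begin();
  double* y = res.begin();
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    double* yc = y + (size_t)c * Ho * Wo;
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        double m = -std::numeric_limits<double>::infinity();
        for (int dj = 0; dj < k; ++dj) {
          const int sj = j * stride - pad + dj;
          if (sj < 0 || sj >= W) continue;
          for (int dii = 0; dii < k; ++dii) {
            const int si = i * stride - pad + dii;
            if (si < 0 || si >= H) continue;
            const double v = xc[si + (size_t)sj * H];
            if (v > m) m = v;
          }
        }
        yc[i + (size_t)j * Ho] = m;
      }
    }
  }
  res.attr("dim") = IntegerVector::create(Ho, Wo, C);
  return res;
}
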