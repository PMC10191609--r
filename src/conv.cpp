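// Batched 1-D convolution and pooling kernels for the attention blocks.
// Feature maps are [channels, positions, batch] arrays; convolutions use
// "same" padding with left pad floor((m-1)/2). Weight matrices are
// [out_channels, in_channels * m] with the input channel running fastest.

#include <Rcpp.h>
using namespace Rcpp;

static inline void get_dims(const NumericVector &x, int &C, int &L, int &B) {
  IntegerVector d = x.attr("dim");
  C = d[0]; L = d[1]; B = d[2];
}

// im2col gather: columns matrix (Cin*m) x (L*B) for "same" padding,
// input channel fastest within each tap. The convolution itself is then one
// BLAS gemm done from R.
// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int m) {
  int Cin, L, B;
  get_dims(x, Cin, L, B);
  int padl = (m - 1) / 2;
  NumericMatrix cols(Cin * m, L * B);
  const double *xp = x.begin();
  double *cp = cols.begin();
  size_t nrow = (size_t)Cin * m;
  for (int b = 0; b < B; ++b) {
    const double *xb = xp + (size_t)b * Cin * L;
    for (int t = 0; t < L; ++t) {
      double *col = cp + ((size_t)b * L + t) * nrow;
      int j0 = std::max(0, padl - t);
      int j1 = std::min(m, L + padl - t);
      for (int j = 0; j < j0; ++j) {
        for (int ci = 0; ci < Cin; ++ci) col[(size_t)j * Cin + ci] = 0.0;
      }
      for (int j = j0; j < j1; ++j) {
        const double *xcol = xb + (size_t)(t + j - padl) * Cin;
        double *dst = col + (size_t)j * Cin;
        for (int ci = 0; ci < Cin; ++ci) dst[ci] = xcol[ci];
      }
      for (int j = j1; j < m; ++j) {
        for (int ci = 0; ci < Cin; ++ci) col[(size_t)j * Cin + ci] = 0.0;
      }
    }
  }
  return cols;
}

// scatter-add inverse of cpp_im2col
// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix dcols, int Cin, int L, int B, int m) {
  int padl = (m - 1) / 2;
  NumericVector dX(Cin * L * B);
  dX.attr("dim") = IntegerVector::create(Cin, L, B);
  const double *cp = dcols.begin();
  double *dp = dX.begin();
  size_t nrow = (size_t)Cin * m;
  for (int b = 0; b < B; ++b) {
    double *db = dp + (size_t)b * Cin * L;
    for (int t = 0; t < L; ++t) {
      const double *col = cp + ((size_t)b * L + t) * nrow;
      int j0 = std::max(0, padl - t);
      int j1 = std::min(m, L + padl - t);
      for (int j = j0; j < j1; ++j) {
        double *dst = db + (size_t)(t + j - padl) * Cin;
        const double *src = col + (size_t)j * Cin;
        for (int ci = 0; ci < Cin; ++ci) dst[ci] += src[ci];
      }
    }
  }
  return dX;
}

// [[Rcpp::export]]
List cpp_pool_max(NumericVector x) {
  int C, L, B;
  get_dims(x, C, L, B);
  NumericMatrix val(C, B);
  IntegerMatrix arg(C, B);
  const double *xp = x.begin();
  for (int b = 0; b < B; ++b) {
    const double *xb = xp + (size_t)b * C * L;
    for (int c = 0; c < C; ++c) {
      double best = xb[c];
      int bi = 0;
      for (int t = 1; t < L; ++t) {
        double v = xb[(size_t)t * C + c];
        if (v > best) { best = v; bi = t; }
      }
      val(c, b) = best;
      arg(c, b) = bi + 1; // 1-based position
    }
  }
  return List::create(_["val"] = val, _["arg"] = arg);
}

// [[Rcpp::export]]
NumericMatrix cpp_pool_avg(NumericVector x) {
  int C, L, B;
  get_dims(x, C, L, B);
  NumericMatrix out(C, B);
  const double *xp = x.begin();
  for (int b = 0; b < B; ++b) {
    const double *xb = xp + (size_t)b * C * L;
    for (int t = 0; t < L; ++t) {
      for (int c = 0; c < C; ++c) out(c, b) += xb[(size_t)t * C + c];
    }
  }
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < C; ++c) out(c, b) /= L;
  }
  return out;
}

// out[c, t, b] = x[c, t, b] * w[c, b]
// [[Rcpp::export]]
NumericVector cpp_scale_channels(NumericVector x, NumericMatrix w) {
  int C, L, B;
  get_dims(x, C, L, B);
  NumericVector out(clone(x));
  double *op = out.begin();
  for (int b = 0; b < B; ++b) {
    double *ob = op + (size_t)b * C * L;
    for (int t = 0; t < L; ++t) {
      for (int c = 0; c < C; ++c) ob[(size_t)t * C + c] *= w(c, b);
    }
  }
  return out;
}

// per-(channel, sample) sum over positions of x * y
// [[Rcpp::export]]
NumericMatrix cpp_sum_prod_positions(NumericVector x, NumericVector y) {
  int C, L, B;
  get_dims(x, C, L, B);
  NumericMatrix out(C, B);
  const double *xp = x.begin();
  const double *yp = y.begin();
  for (int b = 0; b < B; ++b) {
    size_t off = (size_t)b * C * L;
    for (int t = 0; t < L; ++t) {
      for (int c = 0; c < C; ++c) {
        size_t i = off + (size_t)t * C + c;
        out(c, b) += xp[i] * yp[i];
      }
    }
  }
  return out;
}

// gk = sum_j wg[j, b] * E_j ; E is a list of [C, L, B] arrays
// [[Rcpp::export]]
NumericVector cpp_gate_mix(List E, NumericMatrix wg) {
  NumericVector e0 = E[0];
  int C, L, B;
  get_dims(e0, C, L, B);
  int J = E.size();
  NumericVector out(C * L * B);
  out.attr("dim") = IntegerVector::create(C, L, B);
  double *op = out.begin();
  for (int j = 0; j < J; ++j) {
    NumericVector ej = E[j];
    const double *ep = ej.begin();
    for (int b = 0; b < B; ++b) {
      double w = wg(j, b);
      if (w == 0.0) continue;
      size_t off = (size_t)b * C * L;
      for (size_t i = 0; i < (size_t)C * L; ++i) op[off + i] += w * ep[off + i];
    }
  }
  return out;
}

// dwg[j, b] = sum_{c,t} dgk[c,t,b] * E_j[c,t,b]
// [[Rcpp::export]]
NumericMatrix cpp_gate_mix_backward_w(List E, NumericVector dgk) {
  NumericVector e0 = E[0];
  int C, L, B;
  get_dims(e0, C, L, B);
  int J = E.size();
  NumericMatrix dwg(J, B);
  const double *dp = dgk.begin();
  for (int j = 0; j < J; ++j) {
    NumericVector ej = E[j];
    const double *ep = ej.begin();
    for (int b = 0; b < B; ++b) {
      size_t off = (size_t)b * C * L;
      double acc = 0.0;
      for (size_t i = 0; i < (size_t)C * L; ++i) acc += dp[off + i] * ep[off + i];
      dwg(j, b) = acc;
    }
  }
  return dwg;
}

// acc[row0..row0+C-1, , ] += x * w[b]; acc is [CA, L, B], x is [C, L, B].
// In-place on an accumulator private to the backward pass.
// [[Rcpp::export]]
void cpp_axpy_sample_rows(NumericVector acc, NumericVector x, NumericVector w,
                          int row0) {
  int C, L, B, CA, LA, BA;
  get_dims(x, C, L, B);
  get_dims(acc, CA, LA, BA);
  double *ap = acc.begin();
  const double *xp = x.begin();
  for (int b = 0; b < B; ++b) {
    double wb = w[b];
    if (wb == 0.0) continue;
    const double *xb = xp + (size_t)b * C * L;
    double *ab = ap + (size_t)b * CA * LA + (row0 - 1);
    for (int t = 0; t < L; ++t) {
      const double *xc = xb + (size_t)t * C;
      double *ac = ab + (size_t)t * CA;
      for (int c = 0; c < C; ++c) ac[c] += wb * xc[c];
    }
  }
}
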