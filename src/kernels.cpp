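// Compiled kernels for the 1-D network hot path: im2col convolution
// forward/backward, per-channel batch normalization (optionally fused with
// ReLU) forward/backward, ReLU, global average pooling, and channel
// gating. Activations are numeric arrays (C, L, B); views are taken
// without copying. The im2col matrix has rows ordered with the input
// channel fastest, matching (out, in, k) weight tensors flattened to
// (out, in*k).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;
using Rcpp::List;
using Rcpp::Named;
using Rcpp::NumericVector;
using Rcpp::NumericMatrix;
using Rcpp::IntegerVector;

static void get_dims3(const NumericVector& x, int& C, int& L, int& B) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 3) Rcpp::stop("expected a 3-d array");
  C = d[0]; L = d[1]; B = d[2];
}

static NumericVector alloc3(int C, int L, int B) {
  NumericVector out((R_xlen_t)C * L * B);
  out.attr("dim") = IntegerVector::create(C, L, B);
  return out;
}

// [[Rcpp::export]]
List conv1d_fwd_cpp(NumericVector x, NumericMatrix W, NumericVector b,
                    int k, int stride, int pad) {
  int C, L, B;
  get_dims3(x, C, L, B);
  const int Lp = L + 2 * pad;
  if (Lp < k) Rcpp::stop("input length shorter than kernel");
  const int Lo = (Lp - k) / stride + 1;
  const int Co = W.nrow();
  if (W.ncol() != C * k) Rcpp::stop("kernel/input channel mismatch");
  const cube xc(const_cast<double*>(x.begin()), C, L, B, false, true);
  const mat Wm(const_cast<double*>(W.begin()), Co, C * k, false, true);
  const vec bv(const_cast<double*>(b.begin()), Co, false, true);

  if (k == 1 && stride == 1 && pad == 0) {
    // 1x1 pointwise fast path: the im2col matrix is x itself
    const mat xmat(const_cast<double*>(x.begin()), C, (size_t)L * B, false,
                   true);
    NumericVector outR = alloc3(Co, L, B);
    mat y(outR.begin(), Co, (size_t)L * B, false, true);
    y = Wm * xmat;
    y.each_col() += bv;
    return List::create(Named("out") = outR, Named("col") = R_NilValue,
                        Named("Lo") = L);
  }

  NumericMatrix colR(C * k, Lo * B);
  mat col(colR.begin(), C * k, (size_t)Lo * B, false, true);
  col.zeros();
  for (int s = 0; s < B; ++s) {
    const mat& xs = xc.slice(s);
    for (int o = 0; o < Lo; ++o) {
      double* dst = col.colptr((size_t)s * Lo + o);
      const int start = o * stride - pad;
      for (int j = 0; j < k; ++j) {
        const int p = start + j;
        if (p >= 0 && p < L) {
          std::memcpy(dst + (size_t)j * C, xs.colptr(p), C * sizeof(double));
        }
      }
    }
  }
  NumericVector outR = alloc3(Co, Lo, B);
  mat y(outR.begin(), Co, (size_t)Lo * B, false, true);
  y = Wm * col;
  y.each_col() += bv;
  return List::create(Named("out") = outR, Named("col") = colR,
                      Named("Lo") = Lo);
}

// [[Rcpp::export]]
List conv1d_bwd_cpp(NumericVector dy, SEXP colS, NumericMatrix W,
                    int C, int L, int B, int k, int stride, int pad,
                    bool need_dx) {
  int Co, Lo, B2;
  get_dims3(dy, Co, Lo, B2);
  const mat dym(const_cast<double*>(dy.begin()), Co, (size_t)Lo * B, false,
                true);
  const mat Wfast(const_cast<double*>(
                    Rcpp::NumericMatrix(W).begin()), Co, C * k, false, true);
  if (k == 1 && stride == 1 && pad == 0) {
    // colS holds the layer input array (C, L, B) in the 1x1 fast path
    NumericVector xin(colS);
    const mat xmat(const_cast<double*>(xin.begin()), C, (size_t)L * B,
                   false, true);
    NumericMatrix dWR(Co, C);
    mat dW(dWR.begin(), Co, C, false, true);
    dW = dym * xmat.t();
    NumericVector dbR(Co);
    vec db(dbR.begin(), Co, false, true);
    db = sum(dym, 1);
    NumericVector dxR = alloc3(C, L, B);
    if (need_dx) {
      mat dx(dxR.begin(), C, (size_t)L * B, false, true);
      dx = Wfast.t() * dym;
    }
    return List::create(Named("dW") = dWR, Named("db") = dbR,
                        Named("dx") = dxR);
  }
  NumericMatrix colR(colS);
  const mat col(const_cast<double*>(colR.begin()), C * k, (size_t)Lo * B,
                false, true);
  const mat Wm(const_cast<double*>(W.begin()), Co, C * k, false, true);
  NumericMatrix dWR(Co, C * k);
  mat dW(dWR.begin(), Co, C * k, false, true);
  dW = dym * col.t();
  NumericVector dbR(Co);
  vec db(dbR.begin(), Co, false, true);
  db = sum(dym, 1);
  NumericVector dxR = alloc3(C, L, B);
  if (need_dx) {
    cube dx(dxR.begin(), C, L, B, false, true);
    mat dcol = Wm.t() * dym;                 // (C*k, Lo*B)
    for (int s = 0; s < B; ++s) {
      mat& dxs = dx.slice(s);
      for (int o = 0; o < Lo; ++o) {
        const double* src = dcol.colptr((size_t)s * Lo + o);
        const int start = o * stride - pad;
        for (int j = 0; j < k; ++j) {
          const int p = start + j;
          if (p >= 0 && p < L) {
            double* d = dxs.colptr(p);
            const double* srcj = src + (size_t)j * C;
            for (int c = 0; c < C; ++c) d[c] += srcj[c];
          }
        }
      }
    }
  }
  return List::create(Named("dW") = dWR, Named("db") = dbR,
                      Named("dx") = dxR);
}

// [[Rcpp::export]]
List bn_fwd_cpp(NumericVector x, NumericVector gamma, NumericVector beta,
                NumericVector run_mean, NumericVector run_var, bool train,
                double momentum, double eps, bool relu) {
  int C, L, B;
  get_dims3(x, C, L, B);
  const size_t n = (size_t)L * B;
  const mat xm(const_cast<double*>(x.begin()), C, n, false, true);
  vec mu(C), v(C);
  NumericVector nmR(C), nvR(C);
  vec new_mean(nmR.begin(), C, false, true);
  vec new_var(nvR.begin(), C, false, true);
  const vec rm(const_cast<double*>(run_mean.begin()), C, false, true);
  const vec rv(const_cast<double*>(run_var.begin()), C, false, true);
  if (train) {
    mu = mean(xm, 1);
    v.zeros();
    for (size_t j = 0; j < n; ++j) {
      const double* xc = xm.colptr(j);
      for (int c = 0; c < C; ++c) {
        const double d = xc[c] - mu[c];
        v[c] += d * d;
      }
    }
    v /= (double)n;
    const double unbias = n > 1 ? (double)n / (double)(n - 1) : 1.0;
    new_mean = (1 - momentum) * rm + momentum * mu;
    new_var = (1 - momentum) * rv + momentum * v * unbias;
  } else {
    mu = rm;
    v = rv;
    new_mean = rm;
    new_var = rv;
  }
  NumericVector isR(C);
  vec invstd(isR.begin(), C, false, true);
  invstd = 1.0 / sqrt(v + eps);
  NumericVector xhatR = alloc3(C, L, B);
  NumericVector outR = alloc3(C, L, B);
  mat xhm(xhatR.begin(), C, n, false, true);
  mat ym(outR.begin(), C, n, false, true);
  const double* g = gamma.begin();
  const double* be = beta.begin();
  for (size_t j = 0; j < n; ++j) {
    const double* xc = xm.colptr(j);
    double* hc = xhm.colptr(j);
    double* yc = ym.colptr(j);
    for (int c = 0; c < C; ++c) {
      hc[c] = (xc[c] - mu[c]) * invstd[c];
      double y = g[c] * hc[c] + be[c];
      yc[c] = (relu && y < 0) ? 0.0 : y;
    }
  }
  return List::create(Named("out") = outR, Named("xhat") = xhatR,
                      Named("invstd") = isR, Named("run_mean") = nmR,
                      Named("run_var") = nvR);
}

// [[Rcpp::export]]
List bn_bwd_cpp(NumericVector dyR, NumericVector xhatR, NumericVector invstd,
                NumericVector gamma, NumericVector beta, bool train,
                bool relu) {
  int C, L, B;
  get_dims3(dyR, C, L, B);
  const size_t n = (size_t)L * B;
  const mat dym(const_cast<double*>(dyR.begin()), C, n, false, true);
  const mat xhm(const_cast<double*>(xhatR.begin()), C, n, false, true);
  const double* g = gamma.begin();
  const double* be = beta.begin();
  const double* is = invstd.begin();
  // effective dy (after the fused ReLU mask), accumulated stats
  NumericVector dgR(C), dbR(C);
  vec dgamma(dgR.begin(), C, false, true);
  vec dbeta(dbR.begin(), C, false, true);
  dgamma.zeros();
  dbeta.zeros();
  NumericVector dxR = alloc3(C, L, B);
  mat dxm(dxR.begin(), C, n, false, true);
  // first pass: masked dy into dx as scratch, accumulate dgamma/dbeta
  for (size_t j = 0; j < n; ++j) {
    const double* dc = dym.colptr(j);
    const double* hc = xhm.colptr(j);
    double* sc = dxm.colptr(j);
    for (int c = 0; c < C; ++c) {
      double d = dc[c];
      if (relu && (g[c] * hc[c] + be[c]) <= 0) d = 0.0;
      sc[c] = d;
      dgamma[c] += d * hc[c];
      dbeta[c] += d;
    }
  }
  if (train) {
    vec m1(C), m2(C);
    for (int c = 0; c < C; ++c) {
      m1[c] = g[c] * dbeta[c] / (double)n;
      m2[c] = g[c] * dgamma[c] / (double)n;
    }
    for (size_t j = 0; j < n; ++j) {
      const double* hc = xhm.colptr(j);
      double* sc = dxm.colptr(j);
      for (int c = 0; c < C; ++c) {
        sc[c] = (g[c] * sc[c] - m1[c] - hc[c] * m2[c]) * is[c];
      }
    }
  } else {
    for (size_t j = 0; j < n; ++j) {
      double* sc = dxm.colptr(j);
      for (int c = 0; c < C; ++c) sc[c] *= g[c] * is[c];
    }
  }
  return List::create(Named("dx") = dxR, Named("dgamma") = dgR,
                      Named("dbeta") = dbR);
}

// [[Rcpp::export]]
NumericVector relu_fwd_cpp(NumericVector x) {
  NumericVector y = Rcpp::clone(x);
  double* d = y.begin();
  for (R_xlen_t i = 0; i < y.size(); ++i) if (d[i] < 0) d[i] = 0;
  return y;
}

// [[Rcpp::export]]
NumericVector masked_mul_cpp(NumericVector dy, NumericVector ref) {
  NumericVector dx = Rcpp::clone(dy);
  const double* r = ref.begin();
  double* d = dx.begin();
  for (R_xlen_t i = 0; i < dx.size(); ++i) if (r[i] <= 0) d[i] = 0;
  return dx;
}

// mean over length: (C, L, B) -> (C, B)
// [[Rcpp::export]]
NumericMatrix gap_fwd_cpp(NumericVector x) {
  int C, L, B;
  get_dims3(x, C, L, B);
  const cube xc(const_cast<double*>(x.begin()), C, L, B, false, true);
  NumericMatrix outR(C, B);
  mat out(outR.begin(), C, B, false, true);
  for (int s = 0; s < B; ++s) out.col(s) = mean(xc.slice(s), 1);
  return outR;
}

// [[Rcpp::export]]
NumericVector gap_bwd_cpp(NumericMatrix dyR, int L) {
  const int C = dyR.nrow(), B = dyR.ncol();
  NumericVector dxR = alloc3(C, L, B);
  cube dx(dxR.begin(), C, L, B, false, true);
  const mat dy(const_cast<double*>(dyR.begin()), C, B, false, true);
  for (int s = 0; s < B; ++s) {
    dx.slice(s).each_col() = dy.col(s) / (double)L;
  }
  return dxR;
}

// y = x * g (per channel, per batch), g: (C, B)
// [[Rcpp::export]]
NumericVector channel_scale_cpp(NumericVector x, NumericMatrix gR) {
  int C, L, B;
  get_dims3(x, C, L, B);
  const cube xc(const_cast<double*>(x.begin()), C, L, B, false, true);
  const mat g(const_cast<double*>(gR.begin()), C, B, false, true);
  NumericVector yR = alloc3(C, L, B);
  cube y(yR.begin(), C, L, B, false, true);
  for (int s = 0; s < B; ++s) y.slice(s) = xc.slice(s).each_col() % g.col(s);
  return yR;
}

// sum over length of x .* dy -> (C, B)
// [[Rcpp::export]]
NumericMatrix channel_dot_cpp(NumericVector x, NumericVector dy) {
  int C, L, B;
  get_dims3(x, C, L, B);
  const cube xc(const_cast<double*>(x.begin()), C, L, B, false, true);
  const cube dc(const_cast<double*>(dy.begin()), C, L, B, false, true);
  NumericMatrix outR(C, B);
  mat out(outR.begin(), C, B, false, true);
  for (int s = 0; s < B; ++s) out.col(s) = sum(xc.slice(s) % dc.slice(s), 1);
  return outR;
}
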