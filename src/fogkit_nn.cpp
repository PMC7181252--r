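// Hot paths of the neural-network engine: valid 1-D convolution forward and
// backward (single-precision accumulation through BLAS sgemm; inputs and
// outputs stay double) and max-pooling.  Layouts match nn.R: conv-domain
// matrices are N x (L*C), channel-blocked, batch index fastest.
//
// Two convolution strategies, picked by input channel count:
//   * few channels (first layer, C <= 16): explicit im2col into an
//     (N*T) x (K*C) buffer so the BLAS product has inner dimension K*C
//     instead of the degenerate C;
//   * many channels: shift-and-add over the K kernel taps on the free
//     (N*L) x C reshape, whose tap-k rows form one contiguous block.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const int IM2COL_MAX_C = 16;

static fmat as_f(const Rcpp::NumericMatrix& X) {
  const mat Xd(const_cast<double*>(X.begin()), X.nrow(), X.ncol(), false, true);
  return conv_to<fmat>::from(Xd);
}

static uvec tap_rows(const int K, const int C, const int k) {
  uvec r(C);
  for (int c = 0; c < C; ++c) r[c] = (uword)(c * K + k);
  return r;
}

// (N*T) x (K*C) patch matrix, rows (n, t) with n fastest, cols (c-1)*K + k
static fmat im2col(const fmat& Xf, const int N, const int L, const int C,
                   const int K, const int T) {
  fmat M((uword)N * T, (uword)K * C);
  for (int c = 0; c < C; ++c)
    for (int k = 0; k < K; ++k) {
      float* dst = M.colptr(c * K + k);
      for (int t = 0; t < T; ++t) {
        const float* src = Xf.colptr(c * L + t + k);
        std::copy(src, src + N, dst + (uword)t * N);
      }
    }
  return M;
}

// [[Rcpp::export]]
Rcpp::NumericMatrix cpp_conv_forward(const Rcpp::NumericMatrix& X,
                                     const Rcpp::NumericMatrix& W,
                                     const Rcpp::NumericVector& b,
                                     const int L, const int C, const int K,
                                     const bool relu) {
  const int N = X.nrow();
  const int T = L - K + 1;
  const int F = W.ncol();
  fmat Xf = as_f(X);
  fmat Wf = as_f(W);
  fmat Ym;
  if (C <= IM2COL_MAX_C) {
    Ym = im2col(Xf, N, L, C, K, T) * Wf;
  } else {
    const fmat M0(Xf.memptr(), (uword)N * L, C, false, true);
    Ym.zeros((uword)N * T, F);
    for (int k = 0; k < K; ++k)
      Ym += M0.rows((uword)k * N, (uword)(k + T) * N - 1) *
            Wf.rows(tap_rows(K, C, k));
  }
  frowvec bf(F);
  for (int f = 0; f < F; ++f) bf[f] = (float)b[f];
  Ym.each_row() += bf;
  if (relu) Ym.clamp(0.0f, std::numeric_limits<float>::max());
  Rcpp::NumericMatrix out(N, T * F);
  std::copy(Ym.begin(), Ym.end(), out.begin());
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv_backward(const Rcpp::NumericMatrix& X,
                             const Rcpp::NumericMatrix& W,
                             const Rcpp::NumericMatrix& Yact,
                             const Rcpp::NumericMatrix& dY,
                             const int L, const int C, const int K,
                             const bool relu) {
  const int N = X.nrow();
  const int T = L - K + 1;
  const int F = W.ncol();
  fmat Xf = as_f(X);
  fmat Wf = as_f(W);
  // convert dY to float with the ReLU mask fused in one pass
  const uword nel = (uword)N * T * F;
  fmat Dm((uword)N * T, F);
  {
    const double* g = dY.begin();
    const double* a = Yact.begin();
    float* d = Dm.memptr();
    if (relu) {
      for (uword i = 0; i < nel; ++i) d[i] = a[i] > 0.0 ? (float)g[i] : 0.0f;
    } else {
      for (uword i = 0; i < nel; ++i) d[i] = (float)g[i];
    }
  }
  fmat dW((uword)K * C, F);
  Rcpp::NumericMatrix dXout(N, L * C);
  if (C <= IM2COL_MAX_C) {
    const fmat M = im2col(Xf, N, L, C, K, T);
    dW = M.t() * Dm;
    const fmat dM = Dm * Wf.t();            // (N*T) x (K*C)
    mat dXa(dXout.begin(), N, (uword)L * C, false, true);
    for (int c = 0; c < C; ++c)
      for (int k = 0; k < K; ++k) {
        const float* src = dM.colptr(c * K + k);
        for (int t = 0; t < T; ++t) {
          double* dst = dXa.colptr(c * L + t + k);
          const float* s = src + (uword)t * N;
          for (int n = 0; n < N; ++n) dst[n] += s[n];
        }
      }
  } else {
    const fmat M0(Xf.memptr(), (uword)N * L, C, false, true);
    fmat dM0((uword)N * L, C, fill::zeros);
    for (int k = 0; k < K; ++k) {
      const uvec rows_w = tap_rows(K, C, k);
      const uword r0 = (uword)k * N, r1 = (uword)(k + T) * N - 1;
      dW.rows(rows_w) = M0.rows(r0, r1).t() * Dm;
      dM0.rows(r0, r1) += Dm * Wf.rows(rows_w).t();
    }
    std::copy(dM0.begin(), dM0.end(), dXout.begin());
  }
  Rcpp::NumericMatrix dWout(K * C, F);
  std::copy(dW.begin(), dW.end(), dWout.begin());
  Rcpp::NumericVector dbout(F);
  for (int f = 0; f < F; ++f) dbout[f] = accu(Dm.col(f));
  return Rcpp::List::create(Rcpp::Named("dX") = dXout,
                            Rcpp::Named("dW") = dWout,
                            Rcpp::Named("db") = dbout);
}

// max-pool of size 2 along t within each channel block; odd tails truncated
// [[Rcpp::export]]
Rcpp::NumericMatrix cpp_maxpool_forward(const Rcpp::NumericMatrix& X,
                                        const int T, const int F) {
  const int N = X.nrow();
  const int P = T / 2;
  Rcpp::NumericMatrix Y(N, P * F);
  for (int f = 0; f < F; ++f)
    for (int p = 0; p < P; ++p) {
      const double* a = &X(0, f * T + 2 * p);
      const double* b = &X(0, f * T + 2 * p + 1);
      double* y = &Y(0, f * P + p);
      for (int n = 0; n < N; ++n) y[n] = a[n] >= b[n] ? a[n] : b[n];
    }
  return Y;
}

// [[Rcpp::export]]
Rcpp::NumericMatrix cpp_maxpool_backward(const Rcpp::NumericMatrix& X,
                                         const Rcpp::NumericMatrix& dY,
                                         const int T, const int F) {
  const int N = X.nrow();
  const int P = T / 2;
  Rcpp::NumericMatrix dX(N, T * F);  // zero-initialized
  for (int f = 0; f < F; ++f)
    for (int p = 0; p < P; ++p) {
      const double* a = &X(0, f * T + 2 * p);
      const double* b = &X(0, f * T + 2 * p + 1);
      const double* g = &dY(0, f * P + p);
      double* da = &dX(0, f * T + 2 * p);
      double* db = &dX(0, f * T + 2 * p + 1);
      for (int n = 0; n < N; ++n) {
        if (a[n] >= b[n]) da[n] = g[n]; else db[n] = g[n];
      }
    }
  return dX;
}

// ---- fused two-layer convolutional stack -----------------------------------
//
// conv1(K1,F1,ReLU) -> pool2 -> conv2(K2,F2,ReLU) -> pool2 -> flatten, all in
// single precision with intermediates cached across the forward/backward pair
// of one mini-batch (handle returned to R as an external pointer).  Only
// weight gradients are produced: the stack always sits at the input end of a
// network, so no input gradient is needed.

struct ConvStackCache {
  fmat M1;   // im2col of the input, (N*T1) x (K1*C)
  fmat A1;   // conv1 output after ReLU, N x (T1*F1)
  fmat P1;   // pool1 output, N x (L2*F1)
  fmat A2;   // conv2 output after ReLU, N x (T2*F2)
  int N, C, L, K1, F1, T1, L2, K2, F2, T2, P2;
};

static void pool2_f(const fmat& A, fmat& P, const int N, const int T,
                    const int F) {
  const int Pl = T / 2;
  P.set_size(N, (uword)Pl * F);
  for (int f = 0; f < F; ++f)
    for (int p = 0; p < Pl; ++p) {
      const float* a = A.colptr((uword)f * T + 2 * p);
      const float* b = A.colptr((uword)f * T + 2 * p + 1);
      float* y = P.colptr((uword)f * Pl + p);
      for (int n = 0; n < N; ++n) y[n] = a[n] >= b[n] ? a[n] : b[n];
    }
}

// route pooled gradients back to the argmax and apply the ReLU mask (A > 0)
static void pool2_b(const fmat& A, const fmat& dP, fmat& dA, const int N,
                    const int T, const int F) {
  const int Pl = T / 2;
  dA.zeros(N, (uword)T * F);
  for (int f = 0; f < F; ++f)
    for (int p = 0; p < Pl; ++p) {
      const float* a = A.colptr((uword)f * T + 2 * p);
      const float* b = A.colptr((uword)f * T + 2 * p + 1);
      const float* g = dP.colptr((uword)f * Pl + p);
      float* da = dA.colptr((uword)f * T + 2 * p);
      float* db = dA.colptr((uword)f * T + 2 * p + 1);
      for (int n = 0; n < N; ++n) {
        if (a[n] >= b[n]) { if (a[n] > 0.0f) da[n] = g[n]; }
        else              { if (b[n] > 0.0f) db[n] = g[n]; }
      }
    }
}

// [[Rcpp::export]]
Rcpp::List cpp_convstack_forward(const Rcpp::NumericMatrix& X,
                                 const Rcpp::NumericMatrix& W1,
                                 const Rcpp::NumericVector& b1,
                                 const Rcpp::NumericMatrix& W2,
                                 const Rcpp::NumericVector& b2,
                                 const int L, const int C,
                                 const int K1, const int K2) {
  ConvStackCache* cc = new ConvStackCache();
  const int N = X.nrow();
  const int F1 = W1.ncol(), F2 = W2.ncol();
  const int T1 = L - K1 + 1, L2 = T1 / 2;
  const int T2 = L2 - K2 + 1, P2 = T2 / 2;
  cc->N = N; cc->C = C; cc->L = L; cc->K1 = K1; cc->F1 = F1; cc->T1 = T1;
  cc->L2 = L2; cc->K2 = K2; cc->F2 = F2; cc->T2 = T2; cc->P2 = P2;
  fmat Xf = as_f(X);
  // conv1 via im2col (C is small: 3 axes)
  cc->M1 = im2col(Xf, N, L, C, K1, T1);
  fmat A1m = cc->M1 * as_f(W1);                 // (N*T1) x F1
  frowvec b1f(F1);
  for (int f = 0; f < F1; ++f) b1f[f] = (float)b1[f];
  A1m.each_row() += b1f;
  A1m.clamp(0.0f, std::numeric_limits<float>::max());
  cc->A1 = fmat(A1m.memptr(), N, (uword)T1 * F1);   // same memory layout
  pool2_f(cc->A1, cc->P1, N, T1, F1);
  // conv2 via shift-and-add (F1 channels)
  const fmat M0(cc->P1.memptr(), (uword)N * L2, F1, false, true);
  fmat Wf2 = as_f(W2);
  fmat A2m((uword)N * T2, F2, fill::zeros);
  for (int k = 0; k < K2; ++k)
    A2m += M0.rows((uword)k * N, (uword)(k + T2) * N - 1) *
           Wf2.rows(tap_rows(K2, F1, k));
  frowvec b2f(F2);
  for (int f = 0; f < F2; ++f) b2f[f] = (float)b2[f];
  A2m.each_row() += b2f;
  A2m.clamp(0.0f, std::numeric_limits<float>::max());
  cc->A2 = fmat(A2m.memptr(), N, (uword)T2 * F2);
  fmat P2m;
  pool2_f(cc->A2, P2m, N, T2, F2);
  Rcpp::NumericMatrix out(N, P2 * F2);
  std::copy(P2m.begin(), P2m.end(), out.begin());
  Rcpp::XPtr<ConvStackCache> ptr(cc, true);
  return Rcpp::List::create(Rcpp::Named("out") = out,
                            Rcpp::Named("cache") = ptr);
}

// [[Rcpp::export]]
Rcpp::List cpp_convstack_backward(SEXP cache,
                                  const Rcpp::NumericMatrix& W1,
                                  const Rcpp::NumericMatrix& W2,
                                  const Rcpp::NumericMatrix& dout) {
  Rcpp::XPtr<ConvStackCache> cc(cache);
  const int N = cc->N, F1 = cc->F1, F2 = cc->F2, T1 = cc->T1, T2 = cc->T2,
            L2 = cc->L2, K1 = cc->K1, K2 = cc->K2, C = cc->C;
  fmat dP2 = as_f(dout);                       // N x (P2*F2)
  fmat dA2;
  pool2_b(cc->A2, dP2, dA2, N, T2, F2);        // ReLU mask fused
  // conv2 backward
  fmat Dm2(dA2.memptr(), (uword)N * T2, F2, false, true);
  const fmat M0(cc->P1.memptr(), (uword)N * L2, F1, false, true);
  fmat Wf2 = as_f(W2);
  fmat dW2((uword)K2 * F1, F2);
  fmat dP1m((uword)N * L2, F1, fill::zeros);
  for (int k = 0; k < K2; ++k) {
    const uvec rw = tap_rows(K2, F1, k);
    const uword r0 = (uword)k * N, r1 = (uword)(k + T2) * N - 1;
    dW2.rows(rw) = M0.rows(r0, r1).t() * Dm2;
    dP1m.rows(r0, r1) += Dm2 * Wf2.rows(rw).t();
  }
  // pool1 + conv1 backward (weight gradients only)
  const fmat dP1(dP1m.memptr(), N, (uword)L2 * F1, false, true);
  fmat dA1;
  pool2_b(cc->A1, dP1, dA1, N, T1, F1);
  fmat Dm1(dA1.memptr(), (uword)N * T1, F1, false, true);
  fmat dW1 = cc->M1.t() * Dm1;
  Rcpp::NumericMatrix dW1o(K1 * C, F1), dW2o(K2 * F1, F2);
  std::copy(dW1.begin(), dW1.end(), dW1o.begin());
  std::copy(dW2.begin(), dW2.end(), dW2o.begin());
  Rcpp::NumericVector db1(F1), db2(F2);
  for (int f = 0; f < F1; ++f) db1[f] = accu(Dm1.col(f));
  for (int f = 0; f < F2; ++f) db2[f] = accu(Dm2.col(f));
  return Rcpp::List::create(Rcpp::Named("W1") = dW1o,
                            Rcpp::Named("b1") = db1,
                            Rcpp::Named("W2") = dW2o,
                            Rcpp::Named("b2") = db2);
}
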