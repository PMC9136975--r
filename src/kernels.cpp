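// Hot inner kernels of the CNN decoder: im2col gather / col2im
// scatter-add, fused two-stage max-pooling with argmax tracking, and
// batch-norm forward/backward reductions. Layouts match the R side:
// feature maps are (F, P*B) channel-major matrices, flattened batches
// are (H*W*C, B) with column-major spatial order per channel.

#include <Rcpp.h>
#include <cfloat>
using namespace Rcpp;

// X: padded batch (Npad x B); idx: (K x P), 1-based rows of X.
// Returns patch matrix (K x P*B) (column p + b*P holds patch p of item b).
// [[Rcpp::export]]
NumericMatrix cpp_im2col(const NumericMatrix& X, const IntegerMatrix& idx) {
  const int K = idx.nrow(), P = idx.ncol(), B = X.ncol(), Npad = X.nrow();
  NumericMatrix out(K, (R_xlen_t)P * B);
  const int* ip = idx.begin();
  const size_t KP = (size_t)K * P;
  for (int b = 0; b < B; ++b) {
    const double* xb = X.begin() + (size_t)b * Npad;
    double* ob = out.begin() + (size_t)b * KP;
    for (size_t j = 0; j < KP; ++j) ob[j] = xb[ip[j] - 1];
  }
  return out;
}

// Transpose of cpp_im2col: accumulate dcols (K x P*B) back into the
// padded image gradient (Npad x B).
// [[Rcpp::export]]
NumericMatrix cpp_col2im(const NumericMatrix& dcols, const IntegerMatrix& idx,
                         int Npad) {
  const int K = idx.nrow(), P = idx.ncol();
  const int B = dcols.ncol() / P;
  NumericMatrix out(Npad, B);
  const int* ip = idx.begin();
  const size_t KP = (size_t)K * P;
  for (int b = 0; b < B; ++b) {
    const double* dc = dcols.begin() + (size_t)b * KP;
    double* ob = out.begin() + (size_t)b * Npad;
    for (size_t j = 0; j < KP; ++j) ob[ip[j] - 1] += dc[j];
  }
  return out;
}

// Fused overlapping max-pool, decomposed into a disjoint block max
// (idxA, over the conv spatial grid of P positions) followed by a
// stride-1 window max (idxB, over the reduced grid). Z is (F, P*B).
// Returns pooled (Pp*F x B) in spatial-then-channel stacking plus the
// 0-based source spatial index of each pooled maximum.
// [[Rcpp::export]]
List cpp_maxpool(const NumericMatrix& Z, int F, int P, int B,
                 const IntegerMatrix& idxA, const IntegerMatrix& idxB) {
  const int KA = idxA.nrow(), PA = idxA.ncol();
  const int KB = idxB.nrow(), Pp = idxB.ncol();
  NumericMatrix val((R_xlen_t)Pp * F, B);
  IntegerVector src((R_xlen_t)Pp * F * B);
  std::vector<double> MA(PA);
  std::vector<int> MAsrc(PA);
  const double* zp = Z.begin();
  for (int b = 0; b < B; ++b) {
    const size_t zoff = (size_t)b * P;
    for (int f = 0; f < F; ++f) {
      for (int pa = 0; pa < PA; ++pa) {
        const int* ia = idxA.begin() + (size_t)pa * KA;
        double best = -DBL_MAX; int bs = 0;
        for (int k = 0; k < KA; ++k) {
          const int sp = ia[k] - 1;
          const double v = zp[(size_t)f + (zoff + sp) * F];
          if (v > best) { best = v; bs = sp; }
        }
        MA[pa] = best; MAsrc[pa] = bs;
      }
      double* vb = val.begin() + (size_t)b * Pp * F + (size_t)f * Pp;
      int* sb = src.begin() + (size_t)b * Pp * F + (size_t)f * Pp;
      for (int pb = 0; pb < Pp; ++pb) {
        const int* ib = idxB.begin() + (size_t)pb * KB;
        double best = -DBL_MAX; int bs = 0;
        for (int k = 0; k < KB; ++k) {
          const int pa = ib[k] - 1;
          if (MA[pa] > best) { best = MA[pa]; bs = MAsrc[pa]; }
        }
        vb[pb] = best; sb[pb] = bs;
      }
    }
  }
  return List::create(_["val"] = val, _["src"] = src);
}

// Scatter pooled gradients g (Pp*F x B) back to dZ (F x P*B) through the
// recorded argmax spatial sources.
// [[Rcpp::export]]
NumericMatrix cpp_maxpool_bwd(const NumericMatrix& g, const IntegerVector& src,
                              int F, int P) {
  const int PpF = g.nrow(), B = g.ncol();
  const int Pp = PpF / F;
  NumericMatrix dZ(F, (R_xlen_t)P * B);
  const double* gp = g.begin();
  const int* sp = src.begin();
  double* dz = dZ.begin();
  for (int b = 0; b < B; ++b) {
    const size_t goff = (size_t)b * PpF;
    const size_t zoff = (size_t)b * P;
    for (int f = 0; f < F; ++f) {
      for (int pb = 0; pb < Pp; ++pb) {
        const size_t gi = goff + (size_t)f * Pp + pb;
        dz[(size_t)f + (zoff + sp[gi]) * F] += gp[gi];
      }
    }
  }
  return dZ;
}

// Per-row mean and (biased) variance of Z (F x N) in one pass.
// [[Rcpp::export]]
List cpp_row_meanvar(const NumericMatrix& Z) {
  const int F = Z.nrow();
  const R_xlen_t N = Z.ncol();
  NumericVector m(F), v(F);
  const double* zp = Z.begin();
  for (R_xlen_t j = 0; j < N; ++j) {
    const double* col = zp + (size_t)j * F;
    for (int f = 0; f < F; ++f) { m[f] += col[f]; v[f] += col[f] * col[f]; }
  }
  for (int f = 0; f < F; ++f) {
    m[f] /= N;
    v[f] = v[f] / N - m[f] * m[f];
    if (v[f] < 0) v[f] = 0;
  }
  return List::create(_["mean"] = m, _["var"] = v);
}

// Fused batch-norm + ReLU forward: given Z (F x N) and per-row stats,
// returns xhat, the rectified activation A and the ReLU mask.
// [[Rcpp::export]]
List cpp_bn_relu_fwd(const NumericMatrix& Z, const NumericVector& m,
                     const NumericVector& v, const NumericVector& gamma,
                     const NumericVector& beta, double eps) {
  const int F = Z.nrow();
  const R_xlen_t N = Z.ncol();
  NumericMatrix xhat(F, N), A(F, N);
  LogicalMatrix mask(F, N);
  std::vector<double> inv(F);
  for (int f = 0; f < F; ++f) inv[f] = 1.0 / std::sqrt(v[f] + eps);
  const double* zp = Z.begin();
  double* xp = xhat.begin();
  double* ap = A.begin();
  int* mp = mask.begin();
  for (R_xlen_t j = 0; j < N; ++j) {
    const size_t off = (size_t)j * F;
    for (int f = 0; f < F; ++f) {
      const double xh = (zp[off + f] - m[f]) * inv[f];
      xp[off + f] = xh;
      const double a = gamma[f] * xh + beta[f];
      if (a > 0) { ap[off + f] = a; mp[off + f] = 1; }
      else { ap[off + f] = 0; mp[off + f] = 0; }
    }
  }
  return List::create(_["xhat"] = xhat, _["A"] = A, _["mask"] = mask);
}

// Batch-norm backward (per row): returns dx, dgamma, dbeta.
// dout and xhat are (F x N); dout is consumed after ReLU masking.
// [[Rcpp::export]]
List cpp_bn_bwd(const NumericMatrix& dout, const NumericMatrix& xhat,
                const NumericVector& gamma, const NumericVector& v,
                double eps) {
  const int F = dout.nrow();
  const R_xlen_t N = dout.ncol();
  NumericVector dgamma(F), dbeta(F);
  std::vector<double> s1(F, 0.0), s2(F, 0.0);
  const double* dp = dout.begin();
  const double* xp = xhat.begin();
  for (R_xlen_t j = 0; j < N; ++j) {
    const size_t off = (size_t)j * F;
    for (int f = 0; f < F; ++f) {
      const double dxh = dp[off + f] * gamma[f];
      dgamma[f] += dp[off + f] * xp[off + f];
      dbeta[f] += dp[off + f];
      s1[f] += dxh;
      s2[f] += dxh * xp[off + f];
    }
  }
  NumericMatrix dx(F, N);
  std::vector<double> inv(F);
  for (int f = 0; f < F; ++f) inv[f] = 1.0 / (std::sqrt(v[f] + eps) * N);
  double* op = dx.begin();
  for (R_xlen_t j = 0; j < N; ++j) {
    const size_t off = (size_t)j * F;
    for (int f = 0; f < F; ++f) {
      const double dxh = dp[off + f] * gamma[f];
      op[off + f] = inv[f] * (N * dxh - s1[f] - xp[off + f] * s2[f]);
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// In-place ADAM update: p, m, v are modified directly (the training loop
// owns deep copies); c1 = 1/(1-b1^t), c2 = 1/(1-b2^t).
// [[Rcpp::export]]
void cpp_adam_step(NumericVector p, const NumericVector& g, NumericVector m,
                   NumericVector v, double lr, double b1, double b2,
                   double eps, double c1, double c2) {
  const R_xlen_t n = p.size();
  double* pp = p.begin(); const double* gp = g.begin();
  double* mp = m.begin(); double* vp = v.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    mp[i] = b1 * mp[i] + (1 - b1) * gp[i];
    vp[i] = b2 * vp[i] + (1 - b2) * gp[i] * gp[i];
    pp[i] -= lr * (mp[i] * c1) / (std::sqrt(vp[i] * c2) + eps);
  }
}
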