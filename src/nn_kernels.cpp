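// Hot-path kernels for the sequence front end and the optimiser: embedding
// lookup with fused dropout, 1-D convolution as per-tap GEMMs,
// average pooling fused with the LeakyReLU that precedes it, and an
// in-place Adam update.  Everything that is a small dense product (dense
// layers, losses, the gradient-penalty double-backward) lives in R where
// BLAS already does the work.
//
// Layout: sequence batches are cubes with channels first, X(C, Lx, n), so a
// convolution window is one contiguous memory block of k*C doubles; the
// convolution output keeps positions in rows, Z(Lc, F, n).
#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Embedding lookup for a batch of index-encoded sequences.
// idx: (L x n), values in [0, V]; 0 is the padding code and maps to a fixed
// all-zero column.  E: (C x (V+1)) table stored channels-first, whose first
// column is the padding column.  `extra` zero columns are appended so
// convolution windows that straddle the sequence end see explicit padding.
// When `rate` > 0 and `u` has L*C*n uniform draws, inverted dropout is
// applied on the fly (entry kept iff u >= rate, scaled by 1/(1-rate)).
// [[Rcpp::export]]
arma::cube embed_fwd(const arma::imat& idx, const arma::mat& E, int extra,
                     const arma::vec& u, double rate) {
  const int L = idx.n_rows, n = idx.n_cols, C = E.n_rows;
  cube X(C, L + extra, n, fill::zeros);
  const bool drop = rate > 0 && u.n_elem > 0;
  const double scale = drop ? 1.0 / (1.0 - rate) : 1.0;
  for (int s = 0; s < n; ++s) {
    mat& Xs = X.slice(s);
    for (int l = 0; l < L; ++l) {
      const int v = idx(l, s);
      if (v <= 0) continue;
      std::memcpy(Xs.colptr(l), E.colptr(v), sizeof(double) * C);
      if (drop) {
        const double* up = u.memptr() + ((size_t)s * L + l) * C;
        double* xp = Xs.colptr(l);
        for (int c = 0; c < C; ++c)
          xp[c] = (up[c] >= rate) ? xp[c] * scale : 0.0;
      }
    }
  }
  return X;
}

// Scatter-add of embedding gradients, applying the same dropout mask as the
// forward pass; the padding column stays zero.
// [[Rcpp::export]]
arma::mat embed_bwd(const arma::imat& idx, const arma::cube& dX,
                    const arma::vec& u, double rate, int vocab_cols) {
  const int L = idx.n_rows, n = idx.n_cols, C = dX.n_rows;
  mat dEt(C, vocab_cols, fill::zeros);
  const bool drop = rate > 0 && u.n_elem > 0;
  const double scale = drop ? 1.0 / (1.0 - rate) : 1.0;
  for (int s = 0; s < n; ++s) {
    const mat& dXs = dX.slice(s);
    for (int l = 0; l < L; ++l) {
      const int v = idx(l, s);
      if (v <= 0) continue;
      const double* gp = dXs.colptr(l);
      double* ep = dEt.colptr(v);
      if (drop) {
        const double* up = u.memptr() + ((size_t)s * L + l) * C;
        for (int c = 0; c < C; ++c)
          if (up[c] >= rate) ep[c] += gp[c] * scale;
      } else {
        for (int c = 0; c < C; ++c) ep[c] += gp[c];
      }
    }
  }
  return dEt;
}

// 1-D convolution over positions (valid windows), pre-activation output.
// X: (C x Lx x n) with Lx = Lb + k - 1 zero-padded; W: (k*C x F); b: F.
// Output rows beyond the batch's own window count carry exactly the bias
// (their windows are pure padding), so a short batch equals convolving the
// fully padded sequence.
// [[Rcpp::export]]
arma::cube conv1d_fwd(const arma::cube& X, const arma::mat& W,
                      const arma::rowvec& b, int k, int Lc_full) {
  const int C = X.n_rows, Lx = X.n_cols, n = X.n_slices;
  const int F = W.n_cols;
  const int Lc = std::min(Lx - k + 1, Lc_full);
  cube Z(Lc_full, F, n);
  mat Ys(Lc, F);
  for (int s = 0; s < n; ++s) {
    const mat& Xs = X.slice(s);
    Ys = Xs.cols(0, Lc - 1).t() * W.rows(0, C - 1);
    for (int j = 1; j < k; ++j)
      Ys += Xs.cols(j, j + Lc - 1).t() * W.rows(j * C, (j + 1) * C - 1);
    Ys.each_row() += b;
    Z.slice(s).rows(0, Lc - 1) = Ys;
    if (Lc < Lc_full)
      Z.slice(s).rows(Lc, Lc_full - 1) = repmat(b, Lc_full - Lc, 1);
  }
  return Z;
}

// Backward of conv1d_fwd given the gradient at the pre-activation output.
// Rows past the computed window count have all-zero inputs and contribute
// to db only.
// [[Rcpp::export]]
Rcpp::List conv1d_bwd(const arma::cube& X, const arma::mat& W,
                      const arma::cube& dZ, int k) {
  const int C = X.n_rows, Lx = X.n_cols, n = X.n_slices;
  const int F = W.n_cols;
  const int Lc = std::min(Lx - k + 1, (int)dZ.n_rows);
  cube dX(C, Lx, n, fill::zeros);
  mat dW(k * C, F, fill::zeros);
  rowvec db(F, fill::zeros);
  mat dYt(F, Lc);
  for (int s = 0; s < n; ++s) {
    db += sum(dZ.slice(s), 0);
    dYt = dZ.slice(s).rows(0, Lc - 1).t();
    const mat& Xs = X.slice(s);
    mat& dXs = dX.slice(s);
    for (int j = 0; j < k; ++j) {
      dW.rows(j * C, (j + 1) * C - 1) += Xs.cols(j, j + Lc - 1) * dYt.t();
      dXs.cols(j, j + Lc - 1) += W.rows(j * C, (j + 1) * C - 1) * dYt;
    }
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

static int pool_len(int Lc, int size, int stride) {
  return (Lc < size) ? 1 : (Lc - size) / stride + 1;
}

static inline double lrelu1(double z, double alpha) {
  return z > 0 ? z : alpha * z;
}

// Average pooling of LeakyReLU(Z).  If the map is shorter than one window
// the whole map is averaged (degenerate single window).
// Z: (Lc x F x n) pre-activations; output (Lp x F x n).
// [[Rcpp::export]]
arma::cube avgpool_lrelu_fwd(const arma::cube& Z, double alpha, int size,
                             int stride) {
  const int Lc = Z.n_rows, F = Z.n_cols, n = Z.n_slices;
  const int Lp = pool_len(Lc, size, stride);
  cube P(Lp, F, n);
  for (int s = 0; s < n; ++s) {
    const mat& Zs = Z.slice(s);
    mat& Ps = P.slice(s);
    for (int f = 0; f < F; ++f) {
      const double* zp = Zs.colptr(f);
      for (int p = 0; p < Lp; ++p) {
        const int a = p * stride;
        const int b = std::min(a + size, Lc);
        double acc = 0;
        for (int l = a; l < b; ++l) acc += lrelu1(zp[l], alpha);
        Ps(p, f) = acc / (b - a);
      }
    }
  }
  return P;
}

// Backward of avgpool_lrelu_fwd: spreads the pooled gradient back over the
// (possibly overlapping) windows, then applies the LeakyReLU slope mask
// evaluated at the pre-activations.
// [[Rcpp::export]]
arma::cube avgpool_lrelu_bwd(const arma::cube& dP, const arma::cube& Z,
                             double alpha, int size, int stride) {
  const int Lc = Z.n_rows, F = Z.n_cols, n = Z.n_slices;
  const int Lp = dP.n_rows;
  cube dZ(Lc, F, n, fill::zeros);
  for (int s = 0; s < n; ++s) {
    const mat& Zs = Z.slice(s);
    mat& dZs = dZ.slice(s);
    for (int f = 0; f < F; ++f) {
      const double* zp = Zs.colptr(f);
      double* dp = dZs.colptr(f);
      for (int p = 0; p < Lp; ++p) {
        const int a = p * stride;
        const int b = std::min(a + size, Lc);
        const double w = dP(p, f, s) / (b - a);
        for (int l = a; l < b; ++l)
          dp[l] += (zp[l] > 0 ? w : alpha * w);
      }
    }
  }
  return dZ;
}

// Fused in-place Adam update (param, m and v are modified).
// [[Rcpp::export]]
void adam_update_inplace(Rcpp::NumericVector param,
                         const Rcpp::NumericVector& grad,
                         Rcpp::NumericVector m, Rcpp::NumericVector v,
                         double lr, double b1, double b2, double bc1,
                         double bc2, double eps) {
  const R_xlen_t N = param.size();
  if (grad.size() != N || m.size() != N || v.size() != N)
    Rcpp::stop("adam_update_inplace: size mismatch");
  double* p = REAL(param);
  const double* g = REAL(grad);
  double* mp = REAL(m);
  double* vp = REAL(v);
  for (R_xlen_t i = 0; i < N; ++i) {
    mp[i] = b1 * mp[i] + (1 - b1) * g[i];
    vp[i] = b2 * vp[i] + (1 - b2) * g[i] * g[i];
    p[i] -= lr * (mp[i] / bc1) / (std::sqrt(vp[i] / bc2) + eps);
  }
}
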