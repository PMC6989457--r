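// Hot loops of the conv/pool primitives: patch gathering (im2col), max
// pooling with argmax, and scatter-add for the backward passes. Matrix
// products stay in R (BLAS); these kernels only remove R-level indexing
// overhead. All indices are 1-based as produced by the R planners.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static inline void gather_into(const double* xc, const int* ip,
                               R_xlen_t total, double* op) {
  for (R_xlen_t j = 0; j < total; ++j) op[j] = xc[ip[j] - 1];
}

// batched im2col convolution: for every batch column b of the padded input,
// Y[, b] = vec(gather(Xp[, b]) %*% W) + bias (per filter)
// [[Rcpp::export]]
NumericMatrix cpp_conv_forward(const NumericMatrix& Xp,
                               const IntegerMatrix& idx,
                               const NumericMatrix& W,
                               const NumericVector& bias) {
  const int n = idx.nrow(), m = idx.ncol(), B = Xp.ncol(), F = W.ncol();
  const R_xlen_t total = (R_xlen_t)n * m;
  arma::mat xcol(n, m);
  const arma::mat Wm(const_cast<double*>(W.begin()), m, F, false, true);
  const arma::rowvec bv(const_cast<double*>(bias.begin()), F, false, true);
  NumericMatrix Y((R_xlen_t)n * F, B);
  const int* ip = idx.begin();
  for (int b = 0; b < B; ++b) {
    gather_into(&Xp(0, b), ip, total, xcol.memptr());
    arma::mat Yb(&Y(0, b), n, F, false, true);
    Yb = xcol * Wm;
    Yb.each_row() += bv;
  }
  return Y;
}

// in-place rectifier: x = max(x, 0)
// [[Rcpp::export]]
void cpp_relu_inplace(NumericVector x) {
  double* p = x.begin();
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i) if (p[i] < 0) p[i] = 0;
}

// rectifier gradient through the cached *post*-ReLU activations:
// dx = dr * (y_post > 0), in place on dr
// [[Rcpp::export]]
void cpp_relu_backward(NumericVector dr, const NumericVector& y) {
  double* d = dr.begin();
  const double* yp = y.begin();
  const R_xlen_t n = dr.size();
  for (R_xlen_t i = 0; i < n; ++i) if (yp[i] <= 0) d[i] = 0;
}

// weight/bias gradients: dW = sum_b gather(Xp[, b])' * dY_b, db = sum dY_b
// [[Rcpp::export]]
List cpp_conv_dw(const NumericMatrix& Xp, const IntegerMatrix& idx,
                 const NumericMatrix& dY, int F) {
  const int n = idx.nrow(), m = idx.ncol(), B = Xp.ncol();
  const R_xlen_t total = (R_xlen_t)n * m;
  arma::mat xcol(n, m);
  arma::mat dW(m, F, arma::fill::zeros);
  arma::rowvec db(F, arma::fill::zeros);
  const int* ip = idx.begin();
  for (int b = 0; b < B; ++b) {
    gather_into(&Xp(0, b), ip, total, xcol.memptr());
    const arma::mat dYb(const_cast<double*>(&dY(0, b)), n, F, false, true);
    dW += xcol.t() * dYb;
    db += arma::sum(dYb, 0);
  }
  return List::create(_["dW"] = wrap(dW), _["db"] = wrap(db.t()));
}

// max + argmax over pooling windows; x: [HpWp x CB], idxt: [k2 x ohw]
// (transposed so the inner loop reads indices contiguously)
// [[Rcpp::export]]
List cpp_pool_max(const NumericMatrix& x, const IntegerMatrix& idxt) {
  const int k2 = idxt.nrow(), ohw = idxt.ncol(), CB = x.ncol();
  NumericMatrix out(ohw, CB);
  IntegerMatrix amax(ohw, CB);
  const int* ip0 = idxt.begin();
  for (int c = 0; c < CB; ++c) {
    const double* xc = &x(0, c);
    double* oc = &out(0, c);
    int* ac = &amax(0, c);
    for (int r = 0; r < ohw; ++r) {
      const int* ip = ip0 + (R_xlen_t)r * k2;
      double best = xc[ip[0] - 1];
      int bj = 0;
      for (int j = 1; j < k2; ++j) {
        const double v = xc[ip[j] - 1];
        if (v > best) { best = v; bj = j; }
      }
      oc[r] = best;
      ac[r] = bj + 1;
    }
  }
  return List::create(_["out"] = out, _["amax"] = amax);
}

// route pooled gradients to their argmax positions (ceil-mode padding kept)
// [[Rcpp::export]]
NumericMatrix cpp_pool_scatter(const NumericMatrix& dY,
                               const IntegerMatrix& amax,
                               const IntegerMatrix& idxt, int HpWp) {
  const int k2 = idxt.nrow(), ohw = idxt.ncol(), CB = dY.ncol();
  NumericMatrix dXp(HpWp, CB);
  const int* ip0 = idxt.begin();
  for (int c = 0; c < CB; ++c) {
    double* dc = &dXp(0, c);
    const double* gy = &dY(0, c);
    const int* ac = &amax(0, c);
    for (int r = 0; r < ohw; ++r) {
      dc[ip0[(R_xlen_t)r * k2 + (ac[r] - 1)] - 1] += gy[r];
    }
  }
  return dXp;
}

// col2im: accumulate patch-gradient columns back onto the padded input
// [[Rcpp::export]]
NumericVector cpp_scatter_add(const NumericMatrix& dcol,
                              const IntegerMatrix& idx, int npad) {
  const int n = idx.nrow(), m = idx.ncol();
  NumericVector dx(npad);
  const double* dp = dcol.begin();
  const int* ip = idx.begin();
  double* ox = dx.begin();
  const R_xlen_t total = (R_xlen_t)n * m;
  for (R_xlen_t j = 0; j < total; ++j) ox[ip[j] - 1] += dp[j];
  return dx;
}
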