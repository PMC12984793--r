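#include <Rcpp.h>
using namespace Rcpp;

// Fused in-place Adam update: one pass over the parameter tensor instead of
// the ~9 vectorized passes (and temporaries) the plain-R formulation needs.
// The caller owns p, m and v exclusively (optimizer state is never shared),
// so in-place mutation is safe. lr_t is the bias-corrected step size
// lr * sqrt(1 - beta2^t) / (1 - beta1^t).
// [[Rcpp::export]]
void cpp_adam_step(NumericVector p, NumericVector m, NumericVector v,
                   NumericVector g, double lr_t, double beta1, double beta2,
                   double eps) {
  R_xlen_t n = p.size();
  if (m.size() != n || v.size() != n || g.size() != n)
    stop("adam: tensor sizes differ");
  double *pp = REAL(p), *pm = REAL(m), *pv = REAL(v), *pg = REAL(g);
  for (R_xlen_t i = 0; i < n; ++i) {
    double gi = pg[i];
    double mi = beta1 * pm[i] + (1.0 - beta1) * gi;
    double vi = beta2 * pv[i] + (1.0 - beta2) * gi * gi;
    pm[i] = mi;
    pv[i] = vi;
    pp[i] -= lr_t * mi / (std::sqrt(vi) + eps);
  }
}

// Gather x[idx] into a pre-shaped numeric matrix (nrow x ncol), avoiding the
// extra copy of matrix(x[idx], ...). idx is 1-based.
// [[Rcpp::export]]
NumericMatrix cpp_gather(NumericVector x, IntegerVector idx, int nrow,
                         int ncol) {
  if ((R_xlen_t)nrow * ncol != idx.size()) stop("gather: shape mismatch");
  NumericMatrix out(nrow, ncol);
  double *po = REAL(out), *px = REAL(x);
  int *pi = INTEGER(idx);
  R_xlen_t n = idx.size(), xn = x.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    int j = pi[i] - 1;
    if (j < 0 || j >= xn) stop("gather: index out of range");
    po[i] = px[j];
  }
  return out;
}

// Fused in-place bias add + ReLU on a (positions x filters) pre-activation
// matrix: Z[, f] = max(Z[, f] + b[f], 0).
// [[Rcpp::export]]
void cpp_add_bias_relu(NumericMatrix Z, NumericVector b) {
  int P = Z.nrow(), F = Z.ncol();
  if (b.size() != F) stop("bias length mismatch");
  double *pz = REAL(Z), *pb = REAL(b);
  for (int f = 0; f < F; ++f) {
    double bf = pb[f];
    double *col = pz + (R_xlen_t)f * P;
    for (int p = 0; p < P; ++p) {
      double v = col[p] + bf;
      col[p] = v > 0.0 ? v : 0.0;
    }
  }
}

// In-place ReLU backward: dA[i] = 0 wherever A[i] <= 0 (A is the ReLU
// output, so A > 0 marks the active units).
// [[Rcpp::export]]
void cpp_relu_bwd(NumericVector dA, NumericVector A) {
  R_xlen_t n = dA.size();
  if (A.size() != n) stop("relu backward: size mismatch");
  double *pd = REAL(dA), *pa = REAL(A);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (pa[i] <= 0.0) pd[i] = 0.0;
  }
}

// In-place y += a * x (used to fold the L2 penalty into a gradient tensor
// without allocating another full-size temporary).
// [[Rcpp::export]]
void cpp_axpy(NumericVector y, NumericVector x, double a) {
  R_xlen_t n = y.size();
  if (x.size() != n) stop("axpy: size mismatch");
  double *py = REAL(y), *px = REAL(x);
  for (R_xlen_t i = 0; i < n; ++i) py[i] += a * px[i];
}

// Scatter-add accumulation: out[idx[i]] += val[i] (1-based idx), the
// backward counterpart of the im2col gather.
// [[Rcpp::export]]
NumericVector cpp_scatter_add(NumericVector val, IntegerVector idx,
                              int out_len) {
  NumericVector out(out_len);
  double *po = REAL(out), *pv = REAL(val);
  int *pi = INTEGER(idx);
  R_xlen_t n = idx.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    int j = pi[i] - 1;
    if (j < 0 || j >= out_len) stop("scatter: index out of range");
    po[j] += pv[i];
  }
  return out;
}
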