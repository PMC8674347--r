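#include <Rcpp.h>
using namespace Rcpp;

// Asymmetric least squares baseline: minimise
//   sum_i w_i (y_i - z_i)^2 + lambda * sum (second difference of z)^2
// with w_i = p where y_i > z_i and 1 - p otherwise, iterated to
// convergence. The normal-equation matrix W + lambda * D'D is symmetric
// positive definite and pentadiagonal, so each iteration is one banded
// Cholesky solve (O(n)).

static void solve_penta(const std::vector<double>& d0,
                        const std::vector<double>& d1,
                        const std::vector<double>& d2,
                        const std::vector<double>& b,
                        std::vector<double>& z) {
  const int n = (int) d0.size();
  // LDL^T factorisation of the banded matrix (bandwidth 2)
  std::vector<double> D(n), L1(n, 0.0), L2(n, 0.0);
  for (int i = 0; i < n; ++i) {
    double di = d0[i];
    if (i >= 1) di -= L1[i - 1] * L1[i - 1] * D[i - 1];
    if (i >= 2) di -= L2[i - 2] * L2[i - 2] * D[i - 2];
    D[i] = di;
    if (i + 1 < n) {
      double e = d1[i];
      if (i >= 1) e -= L1[i - 1] * D[i - 1] * L2[i - 1];
      L1[i] = e / D[i];
    }
    if (i + 2 < n) L2[i] = d2[i] / D[i];
  }
  // forward substitution L v = b
  std::vector<double> v(n);
  for (int i = 0; i < n; ++i) {
    double s = b[i];
    if (i >= 1) s -= L1[i - 1] * v[i - 1];
    if (i >= 2) s -= L2[i - 2] * v[i - 2];
    v[i] = s;
  }
  // diagonal + back substitution L^T z = D^{-1} v
  for (int i = n - 1; i >= 0; --i) {
    double s = v[i] / D[i];
    if (i + 1 < n) s -= L1[i] * z[i + 1];
    if (i + 2 < n) s -= L2[i] * z[i + 2];
    z[i] = s;
  }
}

// [[Rcpp::export(name = ".als_baseline_cpp")]]
NumericVector als_baseline_cpp(NumericVector y, double lambda, double p,
                               int maxit) {
  const int n = y.size();
  if (n < 3) return clone(y);
  // band coefficients of lambda * D'D for the (n-2) x n second-difference D
  std::vector<double> c0(n), c1(n - 1), c2(n - 2);
  for (int i = 0; i < n; ++i) {
    double v = 0.0;
    if (i <= n - 3) v += 1.0;
    if (i >= 1 && i <= n - 2) v += 4.0;
    if (i >= 2) v += 1.0;
    c0[i] = lambda * v;
  }
  for (int i = 0; i < n - 1; ++i) {
    double v = 0.0;
    if (i <= n - 3) v += -2.0;
    if (i >= 1) v += -2.0;
    c1[i] = lambda * v;
  }
  for (int i = 0; i < n - 2; ++i) c2[i] = lambda * 1.0;

  std::vector<double> w(n, 1.0), d0(n), b(n), z(n, 0.0);
  for (int it = 0; it < maxit; ++it) {
    for (int i = 0; i < n; ++i) {
      d0[i] = c0[i] + w[i];
      b[i] = w[i] * y[i];
    }
    solve_penta(d0, c1, c2, b, z);
    bool changed = false;
    for (int i = 0; i < n; ++i) {
      double wn = (y[i] > z[i]) ? p : 1.0 - p;
      if (wn != w[i]) { w[i] = wn; changed = true; }
    }
    if (!changed) break;
  }
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = z[i];
  return out;
}
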