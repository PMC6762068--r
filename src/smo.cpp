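#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Dense Gaussian kernel matrix K[i, j] = exp(-gamma * ||X[i,] - Y[j,]||^2).
// Dense is adequate at the scales this package targets (l <= ~10^4 rows).
// [[Rcpp::export]]
NumericMatrix rbf_kernel_matrix_cpp(NumericMatrix X, NumericMatrix Y,
                                    double gamma) {
  const int n = X.nrow(), m = Y.nrow(), d = X.ncol();
  if (Y.ncol() != d)
    stop("feature dimension mismatch: %d vs %d", d, Y.ncol());
  NumericMatrix K(n, m);
  for (int j = 0; j < m; ++j) {
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        const double diff = X(i, k) - Y(j, k);
        s += diff * diff;
      }
      K(i, j) = std::exp(-gamma * s);
    }
  }
  return K;
}

// Working-set (SMO-style, pairs of size 2) solver for the one-class SVM dual
//   min_alpha 1/2 alpha' K alpha   s.t.  0 <= alpha_i <= C,  sum alpha_i = 1.
// The equality constraint forces updates along e_i - e_j; the pair is chosen
// by maximal first-order KKT violation: i = argmin gradient among variables
// that can grow, j = argmax gradient among variables that can shrink.
// Terminates when the maximal violation g_j - g_i drops below tol.
// Returns alpha, the gradient g = K alpha (the Eq-9 quantities used for rho),
// the iteration count and the final violation.
// [[Rcpp::export]]
List smo_solve_cpp(NumericMatrix K, double C, double tol, int max_iter) {
  const int l = K.nrow();
  if (K.ncol() != l) stop("kernel matrix must be square");
  if (C * l < 1.0 - 1e-12)
    stop("infeasible box: C * l < 1 (nu * l < 1)");

  std::vector<double> alpha(l, 1.0 / l);
  std::vector<double> g(l, 0.0);

  // initial gradient g = K alpha for the uniform feasible start
  for (int j = 0; j < l; ++j) {
    const double aj = alpha[j];
    const double* Kj = &K(0, j);
    for (int i = 0; i < l; ++i) g[i] += aj * Kj[i];
  }

  const double eps_a = C * 1e-12;  // box-edge slack for candidate sets
  double viol = R_PosInf;
  int iter = 0;
  for (; iter < max_iter; ++iter) {
    int i_up = -1, j_dn = -1;
    double g_min = R_PosInf, g_max = R_NegInf;
    for (int i = 0; i < l; ++i) {
      if (alpha[i] < C - eps_a && g[i] < g_min) { g_min = g[i]; i_up = i; }
      if (alpha[i] > eps_a && g[i] > g_max) { g_max = g[i]; j_dn = i; }
    }
    viol = g_max - g_min;
    if (i_up < 0 || j_dn < 0 || viol < tol) break;

    const int i = i_up, j = j_dn;
    double eta = K(i, i) + K(j, j) - 2.0 * K(i, j);
    if (eta <= 1e-15) eta = 1e-15;  // duplicate rows: take maximal step
    double lambda = viol / eta;
    const double room_i = C - alpha[i];
    if (lambda > room_i) lambda = room_i;
    if (lambda > alpha[j]) lambda = alpha[j];
    if (lambda <= 0.0) break;

    alpha[i] += lambda;
    alpha[j] -= lambda;  // clipped steps land exactly on 0 or C

    const double* Ki = &K(0, i);
    const double* Kj = &K(0, j);
    for (int r = 0; r < l; ++r) g[r] += lambda * (Ki[r] - Kj[r]);
  }

  double obj = 0.0;
  for (int i = 0; i < l; ++i) obj += alpha[i] * g[i];
  obj *= 0.5;

  return List::create(
      _["alpha"] = NumericVector(alpha.begin(), alpha.end()),
      _["gradient"] = NumericVector(g.begin(), g.end()),
      _["objective"] = obj,
      _["iterations"] = iter,
      _["max_violation"] = viol,
      _["converged"] = (viol < tol));
}
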