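#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// SMO solver for the kernel SVM dual with a precomputed Gram matrix:
//   min_a  0.5 * sum_ij a_i a_j y_i y_j K_ij - sum_i a_i
//   s.t.   sum_i a_i y_i = 0,  0 <= a_i <= C
// Maximal-violating-pair working-set selection; stops when the KKT gap
// max_{I_up}(-y g) - min_{I_low}(-y g) drops below tol.

// [[Rcpp::export]]
List smo_solve_cpp(NumericMatrix K, NumericVector y, double C,
                   double tol, int max_iter) {
  const int n = K.nrow();
  const double TAU = 1e-12;
  std::vector<double> alpha(n, 0.0);
  std::vector<double> grad(n, -1.0);  // grad_i = sum_j y_i y_j K_ij a_j - 1

  int iter = 0;
  double gap = R_PosInf;
  while (iter < max_iter) {
    // working-set selection
    double gmax = R_NegInf, gmin = R_PosInf;
    int i = -1, j = -1;
    for (int t = 0; t < n; ++t) {
      const double v = -y[t] * grad[t];
      const bool up  = (y[t] > 0) ? (alpha[t] < C) : (alpha[t] > 0);
      const bool low = (y[t] > 0) ? (alpha[t] > 0) : (alpha[t] < C);
      if (up && v > gmax) { gmax = v; i = t; }
      if (low && v < gmin) { gmin = v; j = t; }
    }
    gap = gmax - gmin;
    if (i < 0 || j < 0 || gap <= tol) break;

    // curvature along the feasible pair direction is the same in both
    // label cases: K_ii + K_jj - 2 K_ij
    double quad = K(i, i) + K(j, j) - 2.0 * K(i, j);
    if (quad <= 0) quad = TAU;
    const double ai_old = alpha[i], aj_old = alpha[j];
    if (y[i] != y[j]) {
      const double delta = (-grad[i] - grad[j]) / quad;
      const double diff = alpha[i] - alpha[j];
      alpha[i] += delta;
      alpha[j] += delta;
      if (diff > 0) {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = diff; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = -diff; }
      }
      if (diff > 0) {
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = C - diff; }
      } else {
        if (alpha[j] > C) { alpha[j] = C; alpha[i] = C + diff; }
      }
    } else {
      const double delta = (grad[i] - grad[j]) / quad;
      const double sum = alpha[i] + alpha[j];
      alpha[i] -= delta;
      alpha[j] += delta;
      if (sum > C) {
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = sum - C; }
      } else {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = sum; }
      }
      if (sum > C) {
        if (alpha[j] > C) { alpha[j] = C; alpha[i] = sum - C; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = sum; }
      }
    }

    const double di = alpha[i] - ai_old, dj = alpha[j] - aj_old;
    if (di == 0.0 && dj == 0.0) break;  // numerically stalled
    for (int t = 0; t < n; ++t) {
      grad[t] += y[t] * (y[i] * K(t, i) * di + y[j] * K(t, j) * dj);
    }
    ++iter;
  }

  // dual objective: 0.5 * sum_i a_i (grad_i - 1)
  double obj = 0.0;
  for (int t = 0; t < n; ++t) obj += alpha[t] * (grad[t] - 1.0);
  obj *= 0.5;

  // offset from free support vectors (KKT: y_i f(x_i) = 1 there)
  double bsum = 0.0;
  int nfree = 0;
  const double eps_sv = 1e-8 * (C > 1 ? C : 1.0);
  for (int t = 0; t < n; ++t) {
    if (alpha[t] > eps_sv && alpha[t] < C - eps_sv) {
      bsum += -y[t] * grad[t];
      ++nfree;
    }
  }
  double b;
  if (nfree > 0) {
    b = bsum / nfree;
  } else {
    // midpoint of the feasible offset interval
    double gmax = R_NegInf, gmin = R_PosInf;
    for (int t = 0; t < n; ++t) {
      const double v = -y[t] * grad[t];
      const bool up  = (y[t] > 0) ? (alpha[t] < C) : (alpha[t] > 0);
      const bool low = (y[t] > 0) ? (alpha[t] > 0) : (alpha[t] < C);
      if (up && v > gmax) gmax = v;
      if (low && v < gmin) gmin = v;
    }
    b = (gmax + gmin) / 2.0;
  }

  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["b"] = b,
                      _["objective"] = obj,
                      _["iterations"] = iter,
                      _["kkt_gap"] = gap,
                      _["n_free_sv"] = nfree);
}
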