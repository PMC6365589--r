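#include <Rcpp.h>
using namespace Rcpp;

// SMO solver for the weighted soft-margin C-SVC dual:
//   min_a  1/2 sum_ij a_i a_j y_i y_j K_ij - sum_i a_i
//   s.t.   0 <= a_i <= C_i,  sum_i a_i y_i = 0
// Per-sample upper bounds C_i carry the boosting sample distribution into
// the solver as weighted hinge penalties. Maximal-violating-pair working
// set selection (first-order), dense precomputed kernel.
//
// Returns alpha, bias b, number of pair updates, and the final KKT gap.

// [[Rcpp::export(name = ".smo_solve")]]
List smo_solve(NumericMatrix K, NumericVector y, NumericVector C,
               double eps = 1e-3, int max_iter = 0) {
  const int n = K.nrow();
  if (K.ncol() != n || y.size() != n || C.size() != n)
    stop("K must be square with matching y and C");
  if (max_iter <= 0) max_iter = std::max(200000, 200 * n);

  std::vector<double> alpha(n, 0.0);
  // F_i = sum_j alpha_j y_j K_ij (decision value without bias)
  std::vector<double> F(n, 0.0);

  int iter = 0;
  double gap = R_PosInf;
  double m_up = 0.0, m_low = 0.0;

  for (iter = 0; iter < max_iter; ++iter) {
    // i = argmax over I_up of (y_i - F_i); j = argmin over I_low
    int i = -1, j = -1;
    m_up = -R_PosInf;
    m_low = R_PosInf;
    for (int t = 0; t < n; ++t) {
      double v = y[t] - F[t];
      bool in_up = (y[t] > 0) ? (alpha[t] < C[t]) : (alpha[t] > 0);
      bool in_low = (y[t] > 0) ? (alpha[t] > 0) : (alpha[t] < C[t]);
      if (in_up && v > m_up) { m_up = v; i = t; }
      if (in_low && v < m_low) { m_low = v; j = t; }
    }
    gap = m_up - m_low;
    if (i < 0 || j < 0 || gap <= eps) break;

    const double ai_old = alpha[i], aj_old = alpha[j];
    const double Ci = C[i], Cj = C[j];
    // dual gradient G_t = y_t F_t - 1
    const double Gi = y[i] * F[i] - 1.0;
    const double Gj = y[j] * F[j] - 1.0;

    if (y[i] != y[j]) {
      // alpha_i - alpha_j is conserved
      double quad = K(i, i) + K(j, j) + 2.0 * K(i, j);
      if (quad <= 0) quad = 1e-12;
      double delta = (-Gi - Gj) / quad;
      double diff = ai_old - aj_old;
      alpha[i] = ai_old + delta;
      alpha[j] = aj_old + delta;
      if (diff > 0) {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = diff; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = -diff; }
      }
      if (diff > Ci - Cj) {
        if (alpha[i] > Ci) { alpha[i] = Ci; alpha[j] = Ci - diff; }
      } else {
        if (alpha[j] > Cj) { alpha[j] = Cj; alpha[i] = Cj + diff; }
      }
    } else {
      // alpha_i + alpha_j is conserved
      double quad = K(i, i) + K(j, j) - 2.0 * K(i, j);
      if (quad <= 0) quad = 1e-12;
      double delta = (Gi - Gj) / quad;
      double sum = ai_old + aj_old;
      alpha[i] = ai_old - delta;
      alpha[j] = aj_old + delta;
      if (sum > Ci) {
        if (alpha[i] > Ci) { alpha[i] = Ci; alpha[j] = sum - Ci; }
      } else {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = sum; }
      }
      if (sum > Cj) {
        if (alpha[j] > Cj) { alpha[j] = Cj; alpha[i] = sum - Cj; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = sum; }
      }
    }

    const double dai = (alpha[i] - ai_old) * y[i];
    const double daj = (alpha[j] - aj_old) * y[j];
    if (dai == 0.0 && daj == 0.0) break;  // numerically stuck
    for (int t = 0; t < n; ++t)
      F[t] += dai * K(t, i) + daj * K(t, j);
  }

  // bias from the converged bounds; free SVs give y_i - F_i = b exactly
  double b;
  if (std::isfinite(m_up) && std::isfinite(m_low))
    b = 0.5 * (m_up + m_low);
  else
    b = 0.0;

  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["b"] = b,
                      _["iter"] = iter,
                      _["gap"] = gap);
}
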