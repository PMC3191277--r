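#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Sequential minimal optimisation for the one-class SVM dual:
//   minimise (1/2) alpha' K alpha
//   subject to 0 <= alpha_i <= C = 1/(nu * n), sum(alpha) = 1.
// Maximal-violating-pair selection on the gradient g = K alpha; the
// equality constraint is maintained by moving mass between the pair.
// At optimality there is a rho with g_i >= rho (alpha_i = 0),
// g_i <= rho (alpha_i = C) and g_i = rho on the margin.
// [[Rcpp::export(name = ".smo_ocsvm")]]
List smo_ocsvm(NumericMatrix K, double nu, double tol, int max_iter) {
  const int n = K.nrow();
  const double C = 1.0 / (nu * static_cast<double>(n));
  const double bound_eps = 1e-12 * std::max(1.0, C);

  std::vector<double> alpha(n, 1.0 / n);  // feasible start
  std::vector<double> g(n, 0.0);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < n; ++j) s += K(i, j) * alpha[j];
    g[i] = s;
  }

  int iter = 0;
  double viol = 0.0;
  bool converged = false;
  for (iter = 0; iter < max_iter; ++iter) {
    int up = -1, dn = -1;
    double gmin = R_PosInf, gmax = R_NegInf;
    for (int t = 0; t < n; ++t) {
      if (alpha[t] < C - bound_eps && g[t] < gmin) { gmin = g[t]; up = t; }
      if (alpha[t] > bound_eps && g[t] > gmax) { gmax = g[t]; dn = t; }
    }
    if (up < 0 || dn < 0) { converged = true; viol = 0.0; break; }
    viol = gmax - gmin;
    if (viol < tol) { converged = true; break; }

    double eta = K(up, up) + K(dn, dn) - 2.0 * K(up, dn);
    double step_max = std::min(C - alpha[up], alpha[dn]);
    double step = (eta > 1e-15) ? std::min(step_max, viol / eta) : step_max;
    if (step <= 0.0) { converged = true; break; }

    alpha[up] += step;
    alpha[dn] -= step;
    if (alpha[up] > C) alpha[up] = C;
    if (alpha[dn] < 0.0) alpha[dn] = 0.0;
    for (int t = 0; t < n; ++t) g[t] += step * (K(t, up) - K(t, dn));
  }

  double obj = 0.0;
  for (int i = 0; i < n; ++i) obj += 0.5 * alpha[i] * g[i];

  return List::create(_["alpha"] = alpha,
                      _["grad"] = g,
                      _["objective"] = obj,
                      _["iterations"] = iter,
                      _["kkt_violation"] = viol,
                      _["converged"] = converged);
}
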