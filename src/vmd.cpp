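#include <Rcpp.h>
#include <complex>
#include <vector>

using namespace Rcpp;

// ADMM iteration for variational mode decomposition, run on the one-sided
// spectrum of the (mirrored) input. Mode update is the Wiener-filter form
//   U_k = (F - sum_{i != k} U_i + lambda/2) / (1 + 2 alpha (xi - omega_k)^2),
// the centre frequency is the power-weighted spectral centroid of U_k, and
// the dual variable is updated with step tau. Iterations stop when
//   sum_k ||U_k^{n+1} - U_k^n||^2 / ||U_k^n||^2 < eps
// or at max_iter. Bins above Nyquist carry F = 0 and stay identically zero.
//
// [[Rcpp::export]]
List vmd_admm_cpp(ComplexVector fhat_plus, NumericVector freqs, int K,
                  double alpha, double tau, double eps, int max_iter,
                  NumericVector omega_init, bool monitor_objective) {
  const int T = fhat_plus.size();
  std::vector<std::complex<double>> F(T);
  for (int t = 0; t < T; ++t) F[t] = std::complex<double>(fhat_plus[t].r, fhat_plus[t].i);

  std::vector<std::vector<std::complex<double>>> U(K, std::vector<std::complex<double>>(T, 0.0));
  std::vector<std::complex<double>> lambda(T, 0.0), sum_all(T, 0.0);
  std::vector<double> omega(omega_init.begin(), omega_init.end());
  std::vector<double> objective;

  int n_iter = 0;
  bool converged = false;
  for (int it = 0; it < max_iter; ++it) {
    double udiff = 0.0;
    for (int k = 0; k < K; ++k) {
      double num = 0.0, den = 0.0, dnorm = 0.0, onorm = 0.0;
      for (int t = 0; t < T; ++t) {
        std::complex<double> others = sum_all[t] - U[k][t];
        std::complex<double> unew =
          (F[t] - others + lambda[t] * 0.5) /
          (1.0 + 2.0 * alpha * (freqs[t] - omega[k]) * (freqs[t] - omega[k]));
        std::complex<double> d = unew - U[k][t];
        dnorm += std::norm(d);
        onorm += std::norm(U[k][t]);
        sum_all[t] = others + unew;
        U[k][t] = unew;
        double p = std::norm(unew);
        num += freqs[t] * p;
        den += p;
      }
      if (den > 0.0) omega[k] = num / den;
      udiff += dnorm / std::max(onorm, 2.220446049250313e-16);
    }
    if (tau != 0.0) {
      for (int t = 0; t < T; ++t) lambda[t] += tau * (F[t] - sum_all[t]);
    }
    if (monitor_objective) {
      double obj = 0.0;
      for (int t = 0; t < T; ++t) {
        double fit = std::norm(F[t] - sum_all[t]);
        double bw = 0.0;
        for (int k = 0; k < K; ++k)
          bw += (freqs[t] - omega[k]) * (freqs[t] - omega[k]) * std::norm(U[k][t]);
        obj += 2.0 * alpha * bw + fit;
      }
      objective.push_back(obj);
    }
    n_iter = it + 1;
    if (udiff < eps) { converged = true; break; }
  }

  ComplexMatrix u_hat(T, K);
  for (int k = 0; k < K; ++k)
    for (int t = 0; t < T; ++t) {
      u_hat(t, k).r = U[k][t].real();
      u_hat(t, k).i = U[k][t].imag();
    }

  return List::create(_["u_hat"] = u_hat,
                      _["omega"] = NumericVector(omega.begin(), omega.end()),
                      _["n_iter"] = n_iter,
                      _["converged"] = converged,
                      _["objective"] = NumericVector(objective.begin(), objective.end()));
}
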