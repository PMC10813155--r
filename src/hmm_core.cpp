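#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward pass. logB is n x K log emission densities. Per-step max
// subtraction keeps the scaled densities in range for arbitrarily long
// sequences; the subtracted constants are added back to the log-likelihood.
// [[Rcpp::export]]
double cpp_forward_loglik(const NumericMatrix& logB,
                          const NumericVector& pi,
                          const NumericMatrix& A) {
  const int n = logB.nrow(), K = logB.ncol();
  std::vector<double> alpha(K), tmp(K);
  double loglik = 0.0;

  double m = logB(0, 0);
  for (int k = 1; k < K; ++k) m = std::max(m, logB(0, k));
  double c = 0.0;
  for (int k = 0; k < K; ++k) {
    alpha[k] = pi[k] * std::exp(logB(0, k) - m);
    c += alpha[k];
  }
  if (c <= 0.0) return R_NegInf;
  for (int k = 0; k < K; ++k) alpha[k] /= c;
  loglik += std::log(c) + m;

  for (int i = 1; i < n; ++i) {
    m = logB(i, 0);
    for (int k = 1; k < K; ++k) m = std::max(m, logB(i, k));
    c = 0.0;
    for (int l = 0; l < K; ++l) {
      double s = 0.0;
      for (int k = 0; k < K; ++k) s += alpha[k] * A(k, l);
      tmp[l] = s * std::exp(logB(i, l) - m);
      c += tmp[l];
    }
    if (c <= 0.0) return R_NegInf;
    for (int l = 0; l < K; ++l) alpha[l] = tmp[l] / c;
    loglik += std::log(c) + m;
  }
  return loglik;
}

// Scaled forward-backward: returns per-sample state posteriors (gamma),
// expected transition counts summed over time (xi_sum, K x K) and the
// log-likelihood. Scaling convention: alpha-hat rows sum to 1, beta-hat
// carries the inverse scale factors, so gamma = alpha-hat * beta-hat rows
// sum to 1 exactly and xi sums to 1 per transition step.
// [[Rcpp::export]]
List cpp_forward_backward(const NumericMatrix& logB,
                          const NumericVector& pi,
                          const NumericMatrix& A) {
  const int n = logB.nrow(), K = logB.ncol();
  NumericMatrix alpha(n, K), Bs(n, K);
  NumericVector cvec(n), mvec(n);
  double loglik = 0.0;

  for (int i = 0; i < n; ++i) {
    double m = logB(i, 0);
    for (int k = 1; k < K; ++k) m = std::max(m, logB(i, k));
    mvec[i] = m;
    for (int k = 0; k < K; ++k) Bs(i, k) = std::exp(logB(i, k) - m);
  }

  double c = 0.0;
  for (int k = 0; k < K; ++k) { alpha(0, k) = pi[k] * Bs(0, k); c += alpha(0, k); }
  if (c <= 0.0) stop("forward pass underflowed to zero probability at step 1");
  for (int k = 0; k < K; ++k) alpha(0, k) /= c;
  cvec[0] = c; loglik += std::log(c) + mvec[0];

  for (int i = 1; i < n; ++i) {
    c = 0.0;
    for (int l = 0; l < K; ++l) {
      double s = 0.0;
      for (int k = 0; k < K; ++k) s += alpha(i - 1, k) * A(k, l);
      alpha(i, l) = s * Bs(i, l);
      c += alpha(i, l);
    }
    if (c <= 0.0) stop("forward pass underflowed to zero probability at step %d", i + 1);
    for (int l = 0; l < K; ++l) alpha(i, l) /= c;
    cvec[i] = c; loglik += std::log(c) + mvec[i];
  }

  NumericMatrix gamma(n, K), xi_sum(K, K);
  std::vector<double> beta(K, 1.0), beta_new(K);
  for (int k = 0; k < K; ++k) gamma(n - 1, k) = alpha(n - 1, k);

  for (int i = n - 2; i >= 0; --i) {
    // xi_t(k,l) = alpha-hat_t(k) A(k,l) Bs_{t+1}(l) beta-hat_{t+1}(l) / c_{t+1}
    for (int k = 0; k < K; ++k) {
      double s = 0.0;
      for (int l = 0; l < K; ++l) {
        double term = A(k, l) * Bs(i + 1, l) * beta[l] / cvec[i + 1];
        xi_sum(k, l) += alpha(i, k) * term;
        s += term;
      }
      beta_new[k] = s;
    }
    double g = 0.0;
    for (int k = 0; k < K; ++k) { gamma(i, k) = alpha(i, k) * beta_new[k]; g += gamma(i, k); }
    // renormalise against accumulated rounding on very long sequences
    if (g > 0.0) for (int k = 0; k < K; ++k) gamma(i, k) /= g;
    beta.assign(beta_new.begin(), beta_new.end());
  }

  return List::create(_["gamma"] = gamma, _["xi_sum"] = xi_sum,
                      _["loglik"] = loglik);
}

// Log-space Viterbi. Ties broken toward the lower state index: strict
// inequality when scanning predecessors in increasing order.
// [[Rcpp::export]]
List cpp_viterbi(const NumericMatrix& logB,
                 const NumericVector& logpi,
                 const NumericMatrix& logA) {
  const int n = logB.nrow(), K = logB.ncol();
  NumericMatrix delta(n, K);
  IntegerMatrix psi(n, K);

  for (int k = 0; k < K; ++k) delta(0, k) = logpi[k] + logB(0, k);
  for (int i = 1; i < n; ++i) {
    for (int l = 0; l < K; ++l) {
      double best = delta(i - 1, 0) + logA(0, l);
      int arg = 0;
      for (int k = 1; k < K; ++k) {
        double v = delta(i - 1, k) + logA(k, l);
        if (v > best) { best = v; arg = k; }
      }
      delta(i, l) = best + logB(i, l);
      psi(i, l) = arg;
    }
  }

  IntegerVector path(n);
  double best = delta(n - 1, 0);
  int arg = 0;
  for (int k = 1; k < K; ++k)
    if (delta(n - 1, k) > best) { best = delta(n - 1, k); arg = k; }
  path[n - 1] = arg;
  for (int i = n - 2; i >= 0; --i) path[i] = psi(i + 1, path[i + 1]);
  for (int i = 0; i < n; ++i) path[i] += 1;  // 1-based states for R

  return List::create(_["path"] = path, _["logjoint"] = best);
}
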