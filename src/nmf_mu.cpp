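#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Frobenius-norm multiplicative updates (Lee-Seung). Inits W0/H0 must be
// strictly positive; with update_w = false only H is updated (coefficient
// refit against a fixed basis). The squared reconstruction error is evaluated
// every eval_every iterations; tol is the relative error change between
// successive evaluations. All randomness lives on the R side: this routine is
// deterministic in its inputs.
// [[Rcpp::export(name = ".nmf_mu_cpp")]]
Rcpp::List nmf_mu_cpp(const arma::mat& E, arma::mat W, arma::mat H,
                      int max_iter, double tol, bool update_w, int eval_every) {
  const double eps = 1e-12;
  std::vector<double> sse;
  double prev = accu(square(E - W * H));
  sse.push_back(prev);
  int it = 0;
  for (it = 1; it <= max_iter; ++it) {
    H %= (W.t() * E) / (W.t() * W * H + eps);
    if (update_w) {
      W %= (E * H.t()) / (W * (H * H.t()) + eps);
    }
    if (it % eval_every == 0 || it == max_iter) {
      double cur = accu(square(E - W * H));
      sse.push_back(cur);
      if (std::abs(prev - cur) <= tol * std::max(prev, eps)) {
        break;
      }
      prev = cur;
    }
  }
  if (it > max_iter) it = max_iter;
  return Rcpp::List::create(Rcpp::Named("W") = W,
                            Rcpp::Named("H") = H,
                            Rcpp::Named("sse") = sse,
                            Rcpp::Named("iterations") = it);
}
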