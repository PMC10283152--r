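#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Negative log marginal likelihood of a constant-mean RBF-kernel GP and its
// gradient with respect to (mu_c, log sigma_k2, log length_scale, log sigma_n2).
//
// D2 is the matrix of squared Euclidean distances between training locations.
// A relative jitter (jitter_rel * sigma_k2) is added to the kernel diagonal
// before factorisation; the gradient accounts for its sigma_k2 dependence so
// the optimiser sees an exactly differentiable objective.
// [[Rcpp::export]]
Rcpp::List gp_nlml_grad_cpp(const arma::vec& y, const arma::mat& D2,
                            double mu_c, double log_sk2, double log_l,
                            double log_sn2, double jitter_rel,
                            bool fixed_mean) {
  const uword n = y.n_elem;
  const double sk2 = std::exp(log_sk2);
  const double l = std::exp(log_l);
  const double sn2 = std::exp(log_sn2);

  mat E = exp(-D2 / (2.0 * l * l));
  mat Ky = sk2 * E;
  Ky.diag() += sn2 + jitter_rel * sk2;

  mat L;
  vec grad(4, fill::zeros);
  if (!chol(L, Ky, "lower")) {
    // Numerically indefinite despite jitter: signal a large finite value so
    // L-BFGS-B backtracks instead of aborting on Inf.
    return Rcpp::List::create(Rcpp::Named("value") = 1e10,
                              Rcpp::Named("gradient") = grad,
                              Rcpp::Named("ok") = false);
  }

  vec r = y - mu_c;
  vec alpha = solve(trimatu(L.t()), solve(trimatl(L), r));
  double logdet = 2.0 * accu(log(L.diag()));
  double value = 0.5 * dot(r, alpha) + 0.5 * logdet
               + 0.5 * n * std::log(2.0 * M_PI);

  // Kinv via the Cholesky factor (one O(n^3) pass shared by all parameters).
  mat Linv = inv(trimatl(L));
  mat Kinv = Linv.t() * Linv;

  // d/d mu_c
  if (!fixed_mean) grad(0) = -accu(alpha);

  // dKy/dlog sigma_k2 = sk2 * E + jitter_rel * sk2 * I
  {
    mat dK = sk2 * E;
    dK.diag() += jitter_rel * sk2;
    grad(1) = 0.5 * accu(Kinv % dK) - 0.5 * dot(alpha, dK * alpha);
  }
  // dKy/dlog l = sk2 * E % D2 / l^2
  {
    mat dK = (sk2 / (l * l)) * (E % D2);
    grad(2) = 0.5 * accu(Kinv % dK) - 0.5 * dot(alpha, dK * alpha);
  }
  // dKy/dlog sigma_n2 = sn2 * I
  grad(3) = 0.5 * sn2 * trace(Kinv) - 0.5 * sn2 * dot(alpha, alpha);

  return Rcpp::List::create(Rcpp::Named("value") = value,
                            Rcpp::Named("gradient") = grad,
                            Rcpp::Named("ok") = true);
}
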