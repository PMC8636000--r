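// Conjugate Gibbs sampler for the measurement-error meta-regression
//   y_j | theta_j ~ N(theta_j, se2_j)        (se2_j known)
//   theta_j      ~ N(x_j' beta, sigma2)
//   beta         ~ N(0, beta_prior_var * I)
//   sigma2       ~ Inv-Gamma(ig_shape, ig_scale)
// Uses R's RNG so runs are reproducible under set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::vec rnorm_vec(int n) {
  arma::vec z(n);
  for (int i = 0; i < n; ++i) z(i) = R::norm_rand();
  return z;
}

// [[Rcpp::export]]
List gibbs_me_chain(const arma::vec& y, const arma::mat& X,
                    const arma::vec& se2, int iter, int burnin, int thin,
                    double beta_prior_var, double ig_shape, double ig_scale) {
  const int n = y.n_elem;
  const int p = X.n_cols;
  const arma::mat XtX = X.t() * X;

  // init at OLS with a small positive residual variance
  arma::vec beta = arma::solve(XtX + 1e-10 * arma::eye(p, p), X.t() * y);
  double sigma2 = arma::as_scalar(arma::mean(arma::square(y - X * beta)));
  if (sigma2 <= 0) sigma2 = 1e-4;
  arma::vec theta = y;

  const int n_keep = (iter - burnin + thin - 1) / thin;
  arma::mat beta_out(n_keep, p);
  arma::vec sigma2_out(n_keep), dev_out(n_keep);
  int kept = 0;

  for (int it = 0; it < iter; ++it) {
    // theta | beta, sigma2
    arma::vec mu = X * beta;
    arma::vec prec = 1.0 / se2 + 1.0 / sigma2;
    arma::vec m = (y / se2 + mu / sigma2) / prec;
    theta = m + rnorm_vec(n) / arma::sqrt(prec);

    // beta | theta, sigma2
    arma::mat A = XtX / sigma2 +
      arma::eye(p, p) / beta_prior_var;
    arma::vec b = X.t() * theta / sigma2;
    arma::mat U = arma::chol(A);            // A = U' U
    arma::vec mean_b = arma::solve(A, b);
    beta = mean_b + arma::solve(arma::trimatu(U), rnorm_vec(p));

    // sigma2 | theta, beta
    arma::vec r = theta - X * beta;
    double shape = ig_shape + 0.5 * n;
    double rate = ig_scale + 0.5 * arma::dot(r, r);
    sigma2 = 1.0 / R::rgamma(shape, 1.0 / rate);

    if (it >= burnin && (it - burnin) % thin == 0) {
      beta_out.row(kept) = beta.t();
      sigma2_out(kept) = sigma2;
      // marginal deviance: y_j ~ N(x_j' beta, sigma2 + se2_j)
      arma::vec v = sigma2 + se2;
      arma::vec e = y - X * beta;
      dev_out(kept) = arma::sum(arma::log(2.0 * M_PI * v) +
                                arma::square(e) / v);
      ++kept;
    }
  }

  return List::create(
    _["beta"] = beta_out.rows(0, kept - 1),
    _["sigma2"] = sigma2_out.subvec(0, kept - 1),
    _["deviance"] = dev_out.subvec(0, kept - 1)
  );
}
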