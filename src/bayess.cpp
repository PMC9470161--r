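// BayesS spike-slab Gibbs sampler with MAF-dependent effect variance.
// Model: y = 1*mu + X beta + e,
//   beta_j = 0 with prob 1-pi, else N(0, sigma2_b * v_j), v_j = (2 p_j (1-p_j))^S.
// Updates: residual-update spike-slab per SNP; conjugate Beta for pi;
// scaled-inverse-chi2 for sigma2_b, sigma2_e; random-walk Metropolis for S
// (step adapted during burn-in to 20-40% acceptance, then frozen).
// Uses R's RNG so chains are reproducible under set.seed().
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export]]
List bayess_mcmc(const arma::vec& y, const arma::mat& X, const arma::vec& het,
                 int chain_length, int burnin, int thin,
                 double pi_a, double pi_b,
                 double nu0, double scale_b0, double scale_e0,
                 double s_prior_sd, double s_max, double s_step_init) {
  const int n = y.n_elem;
  const int p = X.n_cols;
  arma::vec log_h = arma::log(het);
  arma::vec xx(p);
  for (int j = 0; j < p; ++j) xx(j) = arma::dot(X.col(j), X.col(j));

  // state
  double mu = arma::mean(y);
  arma::vec beta(p, arma::fill::zeros);
  arma::uvec nz(p, arma::fill::zeros); // indicator
  double pi_cur = std::min(0.5, std::max(1e-4, pi_a / (pi_a + pi_b)));
  double s2b = scale_b0;
  double s2e = scale_e0;
  double S = 0.0;
  double s_step = s_step_init;
  arma::vec r = y - mu; // residual

  int n_keep = (chain_length - burnin) / thin;
  arma::vec out_S(n_keep), out_pi(n_keep), out_s2b(n_keep), out_s2e(n_keep);
  arma::vec out_nnz(n_keep);
  arma::vec pip(p, arma::fill::zeros), beta_mean(p, arma::fill::zeros);
  int keep_i = 0;
  long s_prop_n = 0, s_acc_n = 0;
  long s_prop_win = 0, s_acc_win = 0;

  for (int it = 0; it < chain_length; ++it) {
    arma::vec v = arma::exp(S * log_h); // effect-variance weights

    // mu: conditional N(mean(y - X beta), s2e/n); r = y - mu - X beta
    double mu_old = mu;
    double m_hat = arma::mean(r) + mu_old;
    mu = m_hat + R::rnorm(0.0, std::sqrt(s2e / n));
    r += (mu_old - mu);

    double log_pi = std::log(pi_cur), log_1mpi = std::log1p(-pi_cur);
    int nnz_count = 0;
    for (int j = 0; j < p; ++j) {
      if (nz(j)) r += X.col(j) * beta(j); // restore
      double rhs = arma::dot(X.col(j), r);
      double vb = s2b * v(j);
      double denom = xx(j) * vb + s2e;
      // log Bayes factor nonzero vs zero
      double log_l1 = 0.5 * std::log(s2e / denom) +
        0.5 * rhs * rhs * vb / (s2e * denom);
      double log_odds = log_pi + log_l1 - log_1mpi;
      double prob = 1.0 / (1.0 + std::exp(-log_odds));
      if (R::unif_rand() < prob) {
        double post_var = vb * s2e / denom;
        double post_mean = rhs * vb / denom;
        beta(j) = post_mean + R::rnorm(0.0, std::sqrt(post_var));
        nz(j) = 1;
        r -= X.col(j) * beta(j);
        ++nnz_count;
      } else {
        beta(j) = 0.0;
        nz(j) = 0;
      }
    }

    // pi
    pi_cur = R::rbeta(pi_a + nnz_count, pi_b + p - nnz_count);
    pi_cur = std::min(1.0 - 1e-8, std::max(1e-8, pi_cur));

    // sigma2_b
    double ssb = 0.0;
    for (int j = 0; j < p; ++j) if (nz(j)) {
      ssb += beta(j) * beta(j) / v(j);
    }
    s2b = (nu0 * scale_b0 + ssb) / R::rchisq(nu0 + nnz_count);

    // sigma2_e
    double sse = arma::dot(r, r);
    s2e = (nu0 * scale_e0 + sse) / R::rchisq(nu0 + n);
    if (!std::isfinite(s2e) || s2e <= 0) stop("non-finite residual variance");

    // S: random-walk Metropolis on the conditional given nonzero betas
    double S_new = S + R::rnorm(0.0, s_step);
    ++s_prop_n; ++s_prop_win;
    if (std::fabs(S_new) <= s_max) {
      // log target: -(1/2) sum_nz [S log h_j + beta_j^2/(s2b h_j^S)] + prior
      double lt_old = 0.0, lt_new = 0.0;
      for (int j = 0; j < p; ++j) if (nz(j)) {
        double lv_old = S * log_h(j), lv_new = S_new * log_h(j);
        lt_old += -0.5 * (lv_old + beta(j) * beta(j) / (s2b * std::exp(lv_old)));
        lt_new += -0.5 * (lv_new + beta(j) * beta(j) / (s2b * std::exp(lv_new)));
      }
      lt_old += -0.5 * S * S / (s_prior_sd * s_prior_sd);
      lt_new += -0.5 * S_new * S_new / (s_prior_sd * s_prior_sd);
      if (std::log(R::unif_rand()) < lt_new - lt_old) {
        S = S_new;
        ++s_acc_n; ++s_acc_win;
      }
    }
    // adapt step during burn-in only
    if (it < burnin && s_prop_win >= 100) {
      double acc = (double)s_acc_win / s_prop_win;
      if (acc > 0.40) s_step *= 1.25;
      else if (acc < 0.20) s_step /= 1.25;
      s_prop_win = 0; s_acc_win = 0;
    }

    if (it >= burnin && ((it - burnin) % thin) == 0 && keep_i < n_keep) {
      out_S(keep_i) = S;
      out_pi(keep_i) = pi_cur;
      out_s2b(keep_i) = s2b;
      out_s2e(keep_i) = s2e;
      out_nnz(keep_i) = nnz_count;
      for (int j = 0; j < p; ++j) if (nz(j)) {
        pip(j) += 1.0;
        beta_mean(j) += beta(j);
      }
      ++keep_i;
    }
  }
  pip /= n_keep;
  beta_mean /= n_keep;
  return List::create(
    _["S"] = out_S, _["pi"] = out_pi, _["sigma2_b"] = out_s2b,
    _["sigma2_e"] = out_s2e, _["nnz"] = out_nnz,
    _["pip"] = pip, _["beta_mean"] = beta_mean,
    _["acceptance"] = (double)s_acc_n / std::max(1L, s_prop_n),
    _["s_step_final"] = s_step
  );
}
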