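// Gibbs samplers for finite normal-mixture SNP effect models on a
// standardized genotype design matrix:
//   * K-class mixture with fixed per-class variance fractions of sigma_g2
//     (class 1 is the point mass at zero)  -> BayesR when K = 4
//   * two-class spike/slab with slab variance sigma_g2 / m recomputed from
//     the current nonnull count m          -> BayesCpi
// Class indicators are sampled with the SNP effect integrated out; effects
// are then drawn from their conditional normal. Residuals are maintained
// incrementally and refreshed periodically to bound drift.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct Rng {
  std::mt19937_64 eng;
  std::normal_distribution<double> norm;
  std::uniform_real_distribution<double> unif;
  explicit Rng(unsigned long long seed) : eng(seed), norm(0.0, 1.0), unif(0.0, 1.0) {}
  double rnorm() { return norm(eng); }
  double runif() { return unif(eng); }
  double rchisq(double df) {
    std::gamma_distribution<double> g(df / 2.0, 2.0);
    return g(eng);
  }
  double rgamma(double shape) {
    std::gamma_distribution<double> g(shape, 1.0);
    return g(eng);
  }
};

// sample index from unnormalized log weights
int sample_class(const std::vector<double>& logw, Rng& rng) {
  const int K = static_cast<int>(logw.size());
  double mx = logw[0];
  for (int k = 1; k < K; ++k) if (logw[k] > mx) mx = logw[k];
  double tot = 0.0;
  std::vector<double> w(K);
  for (int k = 0; k < K; ++k) { w[k] = std::exp(logw[k] - mx); tot += w[k]; }
  double u = rng.runif() * tot, acc = 0.0;
  for (int k = 0; k < K; ++k) { acc += w[k]; if (u <= acc) return k; }
  return K - 1;
}

}  // namespace

// [[Rcpp::export(name = ".mixture_gibbs_cpp")]]
List mixture_gibbs_cpp(const arma::mat& X,          // n x p standardized design
                       const arma::vec& y,
                       const arma::vec& cfrac,      // K variance fractions, cfrac[0] == 0
                       const arma::vec& alpha,      // K Dirichlet pseudocounts (BayesR path)
                       const int n_iter, const int burn_in, const int thin,
                       const double nu_g, const double s_g,
                       const double nu_e, const double s_e,
                       const double seed,
                       const bool cpi,               // BayesCpi path (K must be 2)
                       const bool update_mu, const double mu_init,
                       const bool update_pi, const arma::vec& pi_init,
                       const bool update_sigma_g, const double sigma_g2_init,
                       const bool update_sigma_e, const double sigma_e2_init,
                       const bool fix_sigma_beta2, const double sigma_beta2_init,
                       const int refresh_every, const bool shuffle) {
  const int n = X.n_rows, p = X.n_cols;
  const int K = cfrac.n_elem;
  Rng rng(static_cast<unsigned long long>(seed));

  arma::vec xtx(p);
  for (int j = 0; j < p; ++j) xtx[j] = arma::dot(X.col(j), X.col(j));

  arma::vec beta(p, arma::fill::zeros);
  arma::ivec cls(p, arma::fill::zeros);              // class indicator, 0-based
  arma::vec pi = pi_init;
  double mu = mu_init;
  double sigma_e2 = sigma_e2_init;
  double sigma_g2 = sigma_g2_init;
  double sigma_beta2 = sigma_beta2_init;             // BayesCpi slab variance
  arma::vec r = y - mu;                              // residuals (beta starts at 0)

  // accumulators over retained draws
  arma::mat pip(p, K, arma::fill::zeros);
  arma::vec beta_sum(p, arma::fill::zeros), beta_sq_sum(p, arma::fill::zeros);
  arma::vec count_sum(K, arma::fill::zeros), pi_sum(K, arma::fill::zeros);
  double sg_sum = 0.0, se_sum = 0.0, mu_sum = 0.0;
  long nret = 0;
  const int keep = (n_iter > burn_in) ? (n_iter - burn_in - 1) / thin + 1 : 0;
  arma::mat trace(keep > 0 ? keep : 1, 4, arma::fill::zeros); // sigma_g2, sigma_e2, mu, nonnull count

  std::vector<double> logw(K);
  arma::vec counts(K);
  std::vector<int> order(p);
  for (int j = 0; j < p; ++j) order[j] = j;

  for (int it = 1; it <= n_iter; ++it) {
    if (shuffle)
      for (int j = p - 1; j > 0; --j)
        std::swap(order[j], order[(int)(rng.runif() * (j + 1))]);
    if (update_mu) {
      r += mu;
      mu = arma::mean(r) + rng.rnorm() * std::sqrt(sigma_e2 / n);
      r -= mu;
    }

    counts.zeros();
    for (int jj = 0; jj < p; ++jj) {
      const int j = order[jj];
      const double bj = beta[j];
      const double* xj = X.colptr(j);
      double* rp = r.memptr();
      double rhs = 0.0;
      for (int i = 0; i < n; ++i) rhs += xj[i] * rp[i];
      if (bj != 0.0) rhs += bj * xtx[j];   // residual with SNP j added back
      for (int k = 0; k < K; ++k) {
        const double pk = pi[k];
        if (pk <= 0.0) { logw[k] = -std::numeric_limits<double>::infinity(); continue; }
        double v;
        if (k == 0) v = 0.0;
        else if (cpi) v = sigma_beta2;
        else v = cfrac[k] * sigma_g2;
        if (v <= 0.0) {
          logw[k] = std::log(pk);
        } else {
          const double d = v * xtx[j] + sigma_e2;
          logw[k] = std::log(pk) - 0.5 * std::log(d / sigma_e2)
                    + 0.5 * rhs * rhs * v / (sigma_e2 * d);
        }
      }
      const int k = sample_class(logw, rng);
      cls[j] = k;
      counts[k] += 1.0;
      double v;
      if (k == 0) v = 0.0;
      else if (cpi) v = sigma_beta2;
      else v = cfrac[k] * sigma_g2;
      if (v > 0.0) {
        const double vpost = v * sigma_e2 / (v * xtx[j] + sigma_e2);
        const double mpost = rhs * v / (v * xtx[j] + sigma_e2);
        beta[j] = mpost + std::sqrt(vpost) * rng.rnorm();
      } else {
        beta[j] = 0.0;
      }
      const double delta = beta[j] - bj;
      if (delta != 0.0)
        for (int i = 0; i < n; ++i) rp[i] -= xj[i] * delta;
    }
    const double m = arma::accu(counts) - counts[0];   // nonnull count

    if (update_pi) {
      if (cpi) {
        // Beta(1 + m, 1 + p - m) full conditional under a uniform prior
        const double a = rng.rgamma(1.0 + m), b = rng.rgamma(1.0 + (p - m));
        pi[1] = a / (a + b);
        pi[0] = 1.0 - pi[1];
      } else {
        double tot = 0.0;
        for (int k = 0; k < K; ++k) { pi[k] = rng.rgamma(alpha[k] + counts[k]); tot += pi[k]; }
        pi /= tot;
      }
    }

    if (update_sigma_g && m > 0) {
      // sigma_g2 is the total additive genetic variance: sampled from its
      // scaled inverse-chi-square conditional given the current genetic
      // values g = X beta (the improper nu0 = -2, S0 = 0 prior makes the
      // draw concentrate on the realized variance of g); with an empty
      // model the conditional is undefined under the improper prior and
      // zero would be absorbing, so the update is skipped that sweep
      double ssq = 0.0;
      for (int i = 0; i < n; ++i) {
        const double gi = y[i] - mu - r[i];    // (X beta)_i
        ssq += gi * gi;
      }
      const double df = nu_g + n;
      const double scale = ssq + nu_g * s_g;
      if (df > 0 && scale > 0) sigma_g2 = scale / rng.rchisq(df);
    }
    if (cpi && !fix_sigma_beta2 && m > 0) sigma_beta2 = sigma_g2 / m;

    if (update_sigma_e) {
      const double df = nu_e + n;
      const double scale = arma::dot(r, r) + nu_e * s_e;
      if (df > 0 && scale > 0) sigma_e2 = scale / rng.rchisq(df);
    }

    if (refresh_every > 0 && it % refresh_every == 0)
      r = y - mu - X * beta;

    if (it > burn_in && (it - burn_in - 1) % thin == 0) {
      for (int j = 0; j < p; ++j) pip(j, cls[j]) += 1.0;
      beta_sum += beta;
      beta_sq_sum += arma::square(beta);
      count_sum += counts;
      pi_sum += pi;
      sg_sum += sigma_g2; se_sum += sigma_e2; mu_sum += mu;
      trace(nret, 0) = sigma_g2; trace(nret, 1) = sigma_e2;
      trace(nret, 2) = mu; trace(nret, 3) = m;
      ++nret;
    }
  }

  if (nret == 0) stop("no retained draws: check n_iter/burn_in/thin");
  const double nr = static_cast<double>(nret);
  return List::create(
    _["pip"] = pip / nr,
    _["beta_mean"] = beta_sum / nr,
    _["beta_sq_mean"] = beta_sq_sum / nr,
    _["class_counts_mean"] = count_sum / nr,
    _["pi_mean"] = pi_sum / nr,
    _["sigma_g2_mean"] = sg_sum / nr,
    _["sigma_e2_mean"] = se_sum / nr,
    _["mu_mean"] = mu_sum / nr,
    _["retained"] = static_cast<int>(nret),
    _["trace"] = trace);
}
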