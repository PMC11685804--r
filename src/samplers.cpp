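// Single-site Gibbs samplers for Bayesian whole-genome regression
// (Bayesian ridge, Bayesian lasso, BayesA, BayesB, BayesC).
// Uses R's RNG so set.seed() on the R side makes chains reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// scaled-inverse-chi-square draw: (S + ss) / chisq(df)
static inline double rinvchi(double df, double S) {
  return S / R::rchisq(df);
}

// inverse-Gaussian draw (Michael-Schucany-Haas)
static inline double rinvgauss(double mu, double lambda) {
  double nu = R::norm_rand();
  double y = nu * nu;
  double x = mu + (mu * mu * y) / (2.0 * lambda) -
             (mu / (2.0 * lambda)) * std::sqrt(4.0 * mu * lambda * y + mu * mu * y * y);
  if (x <= 0) x = 1e-12;
  if (R::unif_rand() <= mu / (mu + x)) return x;
  return mu * mu / x;
}

// [[Rcpp::export(name = ".wgr_gibbs")]]
List wgr_gibbs(const arma::mat& W,      // training design, centered, n x m
               const arma::vec& y,      // training response
               const arma::mat& Wall,   // design for all ids to predict, N x m
               const std::string method,
               const int n_iter, const int burn_in, const int thin,
               const double R2, const double df0, const double dfe,
               const double pi_a, const double pi_b) {
  const int n = W.n_rows, m = W.n_cols, N = Wall.n_rows;
  const double vary = arma::var(y);

  arma::vec x2(m);
  double MSx = 0.0;
  for (int j = 0; j < m; ++j) {
    x2[j] = arma::dot(W.col(j), W.col(j));
    MSx += x2[j] / n;          // sum of column mean squares (columns centered)
  }
  if (MSx <= 0) stop("all markers are constant");

  const bool is_brr = method == "BRR", is_bl = method == "BL",
             is_ba = method == "BayesA", is_bb = method == "BayesB",
             is_bc = method == "BayesC";
  if (!(is_brr || is_bl || is_ba || is_bb || is_bc)) stop("unknown method");

  // hyper-parameters: each term's prior explains R2 of the phenotypic variance
  double pi = 0.5;                       // inclusion probability (BayesB/C)
  double vb0 = vary * R2 / MSx;
  double Sb_common = vb0 * (df0 + 2.0);  // prior scale*df for marker variances
  double Sb_slab = vary * R2 / (MSx * 0.5) * (df0 + 2.0);
  double Se0 = vary * (1.0 - R2) * (dfe + 2.0);

  double mu = arma::mean(y);
  arma::vec beta(m, arma::fill::zeros);
  arma::vec vbj(m); vbj.fill(vb0);       // per-marker prior variances
  double vb = vb0;                        // common prior variance
  arma::vec tau2(m, arma::fill::ones);    // BL scale mixture
  double lambda2 = 2.0 * MSx * (1.0 - R2) / R2;  // BL penalty, BGLR-style start
  const double l2_shape = 1.1, l2_rate = l2_shape / lambda2;  // prior mean = start
  arma::uvec delta(m, arma::fill::ones);  // inclusion indicators
  double ve = vary * (1.0 - R2);
  if (ve <= 0) ve = vary * 0.5;

  arma::vec e = y - mu;                   // residual (beta = 0 at start)

  const int keep = (n_iter - burn_in) / thin;
  if (keep <= 0) stop("n_iter must exceed burn_in by at least thin");
  arma::vec chain_ve(keep), chain_vb(keep), chain_pi(keep);
  arma::vec beta_sum(m, arma::fill::zeros);
  arma::vec g_sum(N, arma::fill::zeros), g_ss(N, arma::fill::zeros);
  double mu_sum = 0.0;
  int kept = 0;

  for (int it = 1; it <= n_iter; ++it) {
    // intercept
    double mu_old = mu;
    double ebar = arma::mean(e) + mu;
    mu = ebar + R::norm_rand() * std::sqrt(ve / n);
    e += (mu_old - mu);

    // marker effects
    for (int j = 0; j < m; ++j) {
      if (x2[j] <= 0) continue;
      double b_old = beta[j];
      double rhs = arma::dot(W.col(j), e) + x2[j] * b_old;
      double prior_v;
      bool include = true;
      if (is_brr) prior_v = vb;
      else if (is_ba) prior_v = vbj[j];
      else if (is_bl) prior_v = tau2[j] * ve;
      else { // BayesB / BayesC spike-and-slab
        prior_v = is_bb ? vbj[j] : vb;
        double c1 = x2[j] * prior_v + ve;
        double logit = std::log(pi / (1.0 - pi)) + 0.5 * std::log(ve / c1) +
                       0.5 * rhs * rhs * prior_v / (ve * c1);
        double p1 = 1.0 / (1.0 + std::exp(-logit));
        include = (R::unif_rand() < p1);
        delta[j] = include ? 1 : 0;
      }
      double b_new = 0.0;
      if (include) {
        double prec = x2[j] / ve + 1.0 / prior_v;
        double bhat = (rhs / ve) / prec;
        b_new = bhat + R::norm_rand() / std::sqrt(prec);
      }
      if (b_new != b_old) {
        e += W.col(j) * (b_old - b_new);
        beta[j] = b_new;
      }
    }

    // variance / mixture updates
    if (is_brr) {
      vb = rinvchi(df0 + m, Sb_common + arma::dot(beta, beta));
    } else if (is_ba) {
      for (int j = 0; j < m; ++j)
        vbj[j] = rinvchi(df0 + 1.0, Sb_common + beta[j] * beta[j]);
    } else if (is_bb) {
      int k = 0;
      for (int j = 0; j < m; ++j) {
        vbj[j] = rinvchi(df0 + delta[j], Sb_slab + beta[j] * beta[j]);
        k += delta[j];
      }
      pi = R::rbeta(pi_a + k, pi_b + m - k);
    } else if (is_bc) {
      int k = 0; double ssb = 0.0;
      for (int j = 0; j < m; ++j) { k += delta[j]; ssb += beta[j] * beta[j]; }
      vb = rinvchi(df0 + k, Sb_slab + ssb);
      pi = R::rbeta(pi_a + k, pi_b + m - k);
    } else if (is_bl) {
      double sum_tau2 = 0.0;
      for (int j = 0; j < m; ++j) {
        double b2 = std::max(beta[j] * beta[j], 1e-10 * ve);
        double inv_t = rinvgauss(std::sqrt(lambda2 * ve / b2), lambda2);
        tau2[j] = 1.0 / inv_t;
        sum_tau2 += tau2[j];
      }
      // gamma prior on lambda^2, rate fixed from the start value
      lambda2 = R::rgamma(l2_shape + m, 1.0 / (l2_rate + sum_tau2 / 2.0));
    }

    // residual variance
    double sse = arma::dot(e, e);
    if (is_bl) {
      double ssb = 0.0;
      for (int j = 0; j < m; ++j) ssb += beta[j] * beta[j] / tau2[j];
      ve = rinvchi(dfe + n + m, Se0 + sse + ssb);
    } else {
      ve = rinvchi(dfe + n, Se0 + sse);
    }
    if (!std::isfinite(ve) || !beta.is_finite())
      stop("divergent chain at iteration %d", it);

    if (it > burn_in && (it - burn_in) % thin == 0) {
      arma::vec g = Wall * beta;
      g_sum += g;
      g_ss += arma::square(g);
      beta_sum += beta;
      mu_sum += mu;
      chain_ve[kept] = ve;
      chain_vb[kept] = is_brr || is_bc ? vb : (is_bl ? arma::mean(tau2) * ve : arma::mean(vbj));
      chain_pi[kept] = pi;
      ++kept;
    }
  }

  arma::vec g_mean = g_sum / kept;
  arma::vec g_sd = arma::sqrt(arma::clamp(g_ss / kept - arma::square(g_mean), 0.0, arma::datum::inf));
  return List::create(_["mu"] = mu_sum / kept,
                      _["beta"] = beta_sum / kept,
                      _["g_mean"] = g_mean,
                      _["g_sd"] = g_sd,
                      _["chain_varE"] = chain_ve,
                      _["chain_varB"] = chain_vb,
                      _["chain_pi"] = chain_pi,
                      _["n_retained"] = kept);
}
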