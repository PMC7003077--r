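#include <Rcpp.h>
using namespace Rcpp;

// Gibbs sampler for the BayesC-pi marker-effect model
//   y = mu + X alpha(delta) + e
// delta_j ~ Bern(1 - pi), alpha_j | delta_j = 1 ~ N(0, sigma2_a),
// sigma2_a ~ nu_a * s_a / chi2_{nu_a}, sigma2_e ~ nu_e * s_e / chi2_{nu_e},
// pi ~ Uniform(0,1) unless fix_pi >= 0.
// Draws come from R's RNG, so runs are reproducible under set.seed().
// [[Rcpp::export]]
List bayesc_gibbs(NumericVector y, NumericMatrix X, NumericMatrix Xp,
                  int niter, int burnin, int thin,
                  double nu_a, double s_a, double nu_e, double s_e,
                  double pi_init, double fix_pi) {
  const int n = X.nrow(), m = X.ncol(), np = Xp.nrow();
  if (thin < 1) thin = 1;

  std::vector<double> xtx(m);
  const double *xcol = REAL(X);
  for (int j = 0; j < m; ++j) {
    const double *xj = xcol + (size_t)j * n;
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += xj[i] * xj[i];
    xtx[j] = s;
  }

  double mu = mean(y);
  std::vector<double> alpha(m, 0.0);
  std::vector<int> delta(m, 0);
  std::vector<double> e(n);
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;

  double pi = (fix_pi >= 0.0) ? fix_pi : pi_init;
  double vara = (s_a > 0.0) ? s_a : 1e-4;
  double vare = 0.0;
  for (int i = 0; i < n; ++i) vare += e[i] * e[i];
  vare = std::max(vare / (2.0 * n), 1e-12);

  std::vector<double> gsum(np, 0.0), gssq(np, 0.0), pip(m, 0.0);
  double pisum = 0.0, varasum = 0.0, varesum = 0.0, musum = 0.0;
  int nsave = 0;

  for (int it = 1; it <= niter; ++it) {
    // grand mean
    double rmean = 0.0;
    for (int i = 0; i < n; ++i) rmean += e[i];
    rmean = rmean / n + mu;
    double mu_new = rmean + norm_rand() * std::sqrt(vare / n);
    for (int i = 0; i < n; ++i) e[i] += mu - mu_new;
    mu = mu_new;

    // marker effects with inclusion indicators
    const double log_prior_ratio =
      std::log(std::max(1.0 - pi, 1e-300)) - std::log(std::max(pi, 1e-300));
    int m_in = 0;
    double ssq_alpha = 0.0;
    for (int j = 0; j < m; ++j) {
      if (xtx[j] <= 0.0) { alpha[j] = 0.0; delta[j] = 0; continue; }
      const double *xj = xcol + (size_t)j * n;
      if (delta[j]) {
        const double aj = alpha[j];
        for (int i = 0; i < n; ++i) e[i] += xj[i] * aj;
      }
      double rhs = 0.0;
      for (int i = 0; i < n; ++i) rhs += xj[i] * e[i];
      const double v0 = xtx[j] * vare;
      const double v1 = xtx[j] * xtx[j] * vara + xtx[j] * vare;
      double logodds = log_prior_ratio +
        0.5 * (std::log(v0) - std::log(v1)) +
        0.5 * rhs * rhs * (1.0 / v0 - 1.0 / v1);
      double pincl = 1.0 / (1.0 + std::exp(-logodds));
      if (pi <= 0.0) pincl = 1.0;          // all markers forced in
      if (unif_rand() < pincl) {
        const double C = xtx[j] + vare / vara;
        const double aj = rhs / C + norm_rand() * std::sqrt(vare / C);
        alpha[j] = aj;
        delta[j] = 1;
        for (int i = 0; i < n; ++i) e[i] -= xj[i] * aj;
        ++m_in;
        ssq_alpha += aj * aj;
      } else {
        alpha[j] = 0.0;
        delta[j] = 0;
      }
    }

    // variances
    vara = (ssq_alpha + nu_a * s_a) / Rf_rchisq(nu_a + m_in);
    double sse = 0.0;
    for (int i = 0; i < n; ++i) sse += e[i] * e[i];
    vare = (sse + nu_e * s_e) / Rf_rchisq(nu_e + n);
    if (!R_finite(vare) || !R_finite(vara) || vare <= 0.0)
      stop("BayesC-pi chain diverged (non-finite state) at iteration %d", it);

    // zero-effect proportion
    if (fix_pi < 0.0)
      pi = Rf_rbeta((double)(m - m_in) + 1.0, (double)m_in + 1.0);

    // posterior accumulation
    if (it > burnin && ((it - burnin) % thin) == 0) {
      ++nsave;
      const double *pcol = REAL(Xp);
      std::vector<double> g(np, 0.0);
      for (int j = 0; j < m; ++j) {
        if (!delta[j]) continue;
        const double aj = alpha[j];
        const double *pj = pcol + (size_t)j * np;
        for (int r = 0; r < np; ++r) g[r] += pj[r] * aj;
      }
      for (int r = 0; r < np; ++r) {
        gsum[r] += g[r];
        gssq[r] += g[r] * g[r];
      }
      for (int j = 0; j < m; ++j) pip[j] += delta[j];
      pisum += pi; varasum += vara; varesum += vare; musum += mu;
    }
  }

  if (nsave == 0) stop("no posterior samples recorded; check burn_in/thin");
  NumericVector gebv(np), gebv_sd(np), pip_out(m);
  for (int r = 0; r < np; ++r) {
    gebv[r] = gsum[r] / nsave;
    double v = gssq[r] / nsave - gebv[r] * gebv[r];
    gebv_sd[r] = std::sqrt(std::max(v, 0.0));
  }
  for (int j = 0; j < m; ++j) pip_out[j] = pip[j] / nsave;

  return List::create(
    _["gebv"] = gebv, _["gebv_sd"] = gebv_sd, _["pip"] = pip_out,
    _["pi"] = pisum / nsave, _["sigma2_a"] = varasum / nsave,
    _["sigma2_e"] = varesum / nsave, _["mu"] = musum / nsave,
    _["n_samples"] = nsave);
}
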