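#include <Rcpp.h>
using namespace Rcpp;

// Single-site Gibbs samplers for the whole-genome regression model
//   y = W b + X g + e,   e ~ N(0, sigma_e^2 I)
// with locus-effect priors selected by `method`:
//   0 (BayesA): g_j | s2_j ~ N(0, s2_j),  s2_j ~ scaled-inv-chisq(nu, S)
//   1 (BayesB): g_j = 0 with prob pi, else as BayesA
//   2 (BL):     g_j | t2_j ~ N(0, sigma_e^2 t2_j), t2_j exponential mixture
//               (double-exponential marginal; lambda^2 fixed or Gamma
//               hyperprior with full-conditional update)
// Fixed effects b get a flat prior. sigma_e^2 ~ scaled-inv-chisq(nue, Se).
// Residuals are maintained incrementally; columns of X should be centred or
// W should contain an intercept.

static double rinvgauss(double mu, double lambda) {
  double z = norm_rand();
  double y = z * z;
  double x = mu + mu * mu * y / (2.0 * lambda) -
             mu / (2.0 * lambda) * std::sqrt(4.0 * mu * lambda * y + mu * mu * y * y);
  if (x <= 0) x = 1e-12;
  if (unif_rand() <= mu / (mu + x)) return x;
  return mu * mu / x;
}

// [[Rcpp::export]]
List bayes_gibbs_cpp(NumericVector y, NumericMatrix X, NumericMatrix W,
                     int niter, int burnin, int thin,
                     double nu, double S, double pi_zero,
                     double nue, double Se, int method,
                     double lambda2, double lambda_shape, double lambda_rate,
                     bool lambda_fixed) {
  int n = y.size(), p = X.ncol(), q = W.ncol();
  if (X.nrow() != n || W.nrow() != n) stop("conformability");
  if (burnin >= niter) stop("chain length must exceed burn-in");

  std::vector<double> g(p, 0.0), s2(p, 0.0), t2(p, 1.0), b(q, 0.0);
  std::vector<int> del(p, 1);
  std::vector<double> xtx(p), wtw(q);
  for (int j = 0; j < p; ++j) {
    double s = 0; const double* xj = &X(0, j);
    for (int i = 0; i < n; ++i) s += xj[i] * xj[i];
    xtx[j] = s;
  }
  for (int k = 0; k < q; ++k) {
    double s = 0; const double* wk = &W(0, k);
    for (int i = 0; i < n; ++i) s += wk[i] * wk[i];
    wtw[k] = s;
  }
  std::vector<double> e(n);
  double ybar = mean(y);
  for (int i = 0; i < n; ++i) e[i] = y[i] - (q > 0 ? 0.0 : ybar);
  double sigma_e2 = Se > 0 ? Se : var(y) * 0.5;
  for (int j = 0; j < p; ++j) s2[j] = (S > 0 ? S * nu / std::max(nu - 2.0, 0.1) : sigma_e2 / p);

  int nsave = 0;
  std::vector<double> gsum(p, 0.0), bsum(q, 0.0), pipsum(p, 0.0), s2sum(p, 0.0);
  double se2sum = 0.0, l2sum = 0.0;
  std::vector<double> se2_chain;
  se2_chain.reserve((niter - burnin) / thin + 1);

  for (int it = 0; it < niter; ++it) {
    // fixed effects
    for (int k = 0; k < q; ++k) {
      const double* wk = &W(0, k);
      double r = 0;
      for (int i = 0; i < n; ++i) r += wk[i] * e[i];
      r += wtw[k] * b[k];
      double bnew = r / wtw[k] + norm_rand() * std::sqrt(sigma_e2 / wtw[k]);
      double dlt = b[k] - bnew;
      for (int i = 0; i < n; ++i) e[i] += wk[i] * dlt;
      b[k] = bnew;
    }
    // locus effects
    for (int j = 0; j < p; ++j) {
      if (xtx[j] <= 0) { g[j] = 0; del[j] = 0; continue; }
      const double* xj = &X(0, j);
      double r = 0;
      for (int i = 0; i < n; ++i) r += xj[i] * e[i];
      r += xtx[j] * g[j];
      double gnew = 0.0;
      if (method == 2) { // Bayesian LASSO
        double C = xtx[j] + 1.0 / t2[j];
        gnew = r / C + norm_rand() * std::sqrt(sigma_e2 / C);
        double g2 = std::max(gnew * gnew, 1e-12);
        double muig = std::sqrt(lambda2 * sigma_e2 / g2);
        double inv_t2 = rinvgauss(muig, lambda2);
        t2[j] = 1.0 / std::max(inv_t2, 1e-10);
      } else {
        // locus variance
        if (method == 0 || del[j]) {
          s2[j] = (nu * S + g[j] * g[j]) / R::rchisq(nu + 1.0);
        } else {
          s2[j] = (nu * S) / R::rchisq(nu);
        }
        int incl = 1;
        if (method == 1 && pi_zero > 0) {
          double v1 = sigma_e2 + s2[j] * xtx[j];
          double logbf = 0.5 * (std::log(sigma_e2 / v1) +
                                r * r * s2[j] / (sigma_e2 * v1));
          // log posterior odds of exclusion; guard the exp against overflow
          double lodds = std::log(pi_zero / (1.0 - pi_zero)) - logbf;
          double p1 = lodds > 35 ? 0.0 : 1.0 / (1.0 + std::exp(lodds));
          incl = (unif_rand() < p1) ? 1 : 0;
        }
        del[j] = incl;
        if (incl) {
          double C = xtx[j] + sigma_e2 / s2[j];
          gnew = r / C + norm_rand() * std::sqrt(sigma_e2 / C);
        }
      }
      if (gnew != g[j]) {
        double dlt = g[j] - gnew;
        for (int i = 0; i < n; ++i) e[i] += xj[i] * dlt;
        g[j] = gnew;
      }
    }
    if (method == 2 && !lambda_fixed) {
      double st = 0;
      for (int j = 0; j < p; ++j) st += t2[j];
      lambda2 = R::rgamma(p + lambda_shape, 1.0 / (lambda_rate + st / 2.0));
    }
    // residual variance
    double sse = 0;
    for (int i = 0; i < n; ++i) sse += e[i] * e[i];
    sigma_e2 = (sse + nue * Se) / R::rchisq((double) n + nue);
    if (!R_finite(sigma_e2) || sigma_e2 <= 0)
      stop("residual variance diverged at iteration %d", it + 1);

    if (it >= burnin && (it - burnin) % thin == 0) {
      ++nsave;
      for (int j = 0; j < p; ++j) {
        gsum[j] += g[j];
        pipsum[j] += del[j];
        s2sum[j] += (method == 2 ? t2[j] * sigma_e2 : s2[j]);
      }
      for (int k = 0; k < q; ++k) bsum[k] += b[k];
      se2sum += sigma_e2;
      l2sum += lambda2;
      se2_chain.push_back(sigma_e2);
    }
  }
  NumericVector gout(p), pip(p), s2out(p), bout(q);
  for (int j = 0; j < p; ++j) {
    gout[j] = gsum[j] / nsave;
    pip[j] = pipsum[j] / nsave;
    s2out[j] = s2sum[j] / nsave;
  }
  for (int k = 0; k < q; ++k) bout[k] = bsum[k] / nsave;
  return List::create(_["g"] = gout, _["b"] = bout, _["pip"] = pip,
                      _["sigma_e2"] = se2sum / nsave,
                      _["sigma_g2_locus"] = s2out,
                      _["lambda2"] = l2sum / nsave,
                      _["sigma_e2_chain"] = NumericVector(se2_chain.begin(), se2_chain.end()),
                      _["n_saved"] = nsave);
}
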