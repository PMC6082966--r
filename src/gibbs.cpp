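#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Design-matrix-agnostic single-site Gibbs sampler for whole-genome
// regression y = X s + Z b + e. The same core fits the SNP-based models
// (Bayesian ridge, BayesA, BayesB) and the PC-score models (PCR-Normal,
// PCR-t, PCR-Lasso); only the prior on b differs:
//   prior 0 "gaussian":           b_j ~ N(0, s2b), common s2b ~ scaled-inv-chi2
//   prior 1 "scaled_t":           b_j ~ N(0, s2b_j), locus-specific scaled-inv-chi2
//   prior 2 "spike_slab_t":       point mass at zero with prior prob pi + t slab
//   prior 3 "double_exponential": b_j ~ N(0, tau2_j * s2e), tau2_j exponential,
//                                 rate gamma2/2, gamma2 ~ Gamma(shape, rate)
// Fixed effects get a flat prior; s2e ~ scaled-inv-chi2(nu_e, S_e).
// Residuals are carried through every update (rhs computed against the
// current residual with the predictor's own contribution restored).

static const double EPS_VAR = 1e-10;  // floor on variances and |b_j|

static double rscinvchi2(double nu, double S) {
  return nu * S / R::rchisq(nu);
}

// Michael-Schucany-Haas inverse-Gaussian sampler
static double rinvgauss(double mu, double lambda) {
  double z = norm_rand();
  double y = z * z;
  double x = mu + (mu * mu * y) / (2.0 * lambda) -
    (mu / (2.0 * lambda)) * std::sqrt(4.0 * mu * lambda * y + mu * mu * y * y);
  if (x <= 0) x = EPS_VAR;
  if (unif_rand() <= mu / (mu + x)) return x;
  return mu * mu / x;
}

// [[Rcpp::export]]
List cpp_gibbs(NumericMatrix Z, NumericVector y, NumericMatrix X,
               int prior_type, int niter, int burnin, int thin,
               double nu_b, double S_b, double nu_e, double S_e,
               double pi_a, double pi_b,
               double gamma_shape, double gamma_rate,
               bool fix_s2e, double s2e_init,
               bool fix_s2b, double s2b_init,
               bool fix_pi, double pi_init,
               bool keep_effect_draws) {
  const int n = Z.nrow(), p = Z.ncol(), q = X.ncol();
  if (y.size() != n || X.nrow() != n) stop("dimension mismatch");
  if (niter <= burnin) stop("niter must exceed burnin");

  std::vector<double> zz(p), xx(q);
  for (int j = 0; j < p; ++j) {
    double s = 0; for (int i = 0; i < n; ++i) s += Z(i, j) * Z(i, j);
    zz[j] = s;
  }
  for (int k = 0; k < q; ++k) {
    double s = 0; for (int i = 0; i < n; ++i) s += X(i, k) * X(i, k);
    if (s <= 0) stop("fixed-effect column with zero sum of squares");
    xx[k] = s;
  }

  std::vector<double> b(p, 0.0), fx(q, 0.0), e(y.begin(), y.end());
  std::vector<double> s2bj(p, s2b_init);       // per-locus variances (priors 1,2)
  std::vector<double> tau2(p, 1.0);            // lasso local scales
  std::vector<int>    del(p, 1);               // BayesB inclusion indicators
  double s2b = s2b_init;
  double s2e = s2e_init;
  double pi_zero = fix_pi ? pi_init : 0.5;     // prior prob of a zero effect
  double gamma2 = gamma_shape / gamma_rate;

  const int n_saved = (niter - burnin + thin - 1) / thin;
  std::vector<double> b_sum(p, 0.0), fx_sum(q, 0.0), s2bj_sum(p, 0.0);
  NumericVector s2e_chain(n_saved);
  double s2e_sum = 0, s2b_sum = 0, pi_sum = 0, gamma2_sum = 0;
  NumericMatrix b_draws = keep_effect_draws ? NumericMatrix(n_saved, p)
                                            : NumericMatrix(0, 0);
  int saved = 0;

  for (int it = 0; it < niter; ++it) {
    // fixed effects, flat prior
    for (int k = 0; k < q; ++k) {
      double rhs = 0;
      for (int i = 0; i < n; ++i) rhs += X(i, k) * e[i];
      rhs += xx[k] * fx[k];
      double newf = rhs / xx[k] + norm_rand() * std::sqrt(s2e / xx[k]);
      double df = newf - fx[k];
      for (int i = 0; i < n; ++i) e[i] -= X(i, k) * df;
      fx[k] = newf;
    }

    // predictor effects
    for (int j = 0; j < p; ++j) {
      if (zz[j] <= 0) { b[j] = 0; continue; }
      double vj;
      switch (prior_type) {
        case 0: vj = s2b; break;
        case 1: vj = s2bj[j]; break;
        case 2: vj = s2bj[j]; break;
        default: vj = tau2[j] * s2e; break;
      }
      if (vj < EPS_VAR) vj = EPS_VAR;
      double rhs = 0;
      const double* zcol = &Z(0, j);
      for (int i = 0; i < n; ++i) rhs += zcol[i] * e[i];
      rhs += zz[j] * b[j];
      double C = zz[j] + s2e / vj;

      double bnew;
      if (prior_type == 2) {
        // sample inclusion from the marginal likelihood ratio (b_j integrated out)
        double log_ratio = 0.5 * std::log(s2e / (vj * C)) +
          rhs * rhs / (2.0 * s2e * C);
        double p_in = 1.0 - pi_zero;
        double odds = std::log(p_in / std::max(pi_zero, 1e-300)) + log_ratio;
        double prob_in = 1.0 / (1.0 + std::exp(-odds));
        if (unif_rand() < prob_in) {
          del[j] = 1;
          bnew = rhs / C + norm_rand() * std::sqrt(s2e / C);
        } else {
          del[j] = 0;
          bnew = 0.0;
        }
      } else {
        bnew = rhs / C + norm_rand() * std::sqrt(s2e / C);
      }
      if (!std::isfinite(bnew))
        stop("non-finite effect draw at iteration %d (predictor %d)", it + 1, j + 1);
      double db = bnew - b[j];
      if (db != 0.0) for (int i = 0; i < n; ++i) e[i] -= zcol[i] * db;
      b[j] = bnew;
    }

    // effect-variance updates
    if (prior_type == 0) {
      if (!fix_s2b) {
        double ssb = 0; for (int j = 0; j < p; ++j) ssb += b[j] * b[j];
        s2b = (ssb + nu_b * S_b) / R::rchisq(nu_b + p);
        if (s2b < EPS_VAR) s2b = EPS_VAR;
      }
    } else if (prior_type == 1 || prior_type == 2) {
      if (!fix_s2b) {
        for (int j = 0; j < p; ++j) {
          if (prior_type == 2 && del[j] == 0) {
            s2bj[j] = rscinvchi2(nu_b, S_b);       // prior draw for excluded loci
          } else {
            s2bj[j] = (b[j] * b[j] + nu_b * S_b) / R::rchisq(nu_b + 1.0);
          }
          if (s2bj[j] < EPS_VAR) s2bj[j] = EPS_VAR;
          if (!std::isfinite(s2bj[j]))
            stop("non-finite variance draw at iteration %d", it + 1);
        }
      }
    } else {
      // Bayesian Lasso local/global scales
      for (int j = 0; j < p; ++j) {
        double babs = std::fabs(b[j]);
        if (babs < EPS_VAR) babs = EPS_VAR;
        double mu = std::sqrt(gamma2 * s2e) / babs;
        double inv_tau2 = rinvgauss(mu, gamma2);
        tau2[j] = 1.0 / std::max(inv_tau2, EPS_VAR);
        if (!std::isfinite(tau2[j]))
          stop("non-finite lasso scale at iteration %d", it + 1);
      }
      double st = 0; for (int j = 0; j < p; ++j) st += tau2[j];
      gamma2 = R::rgamma(gamma_shape + p, 1.0 / (gamma_rate + st / 2.0));
    }

    // BayesB mixing proportion (prob of zero)
    if (prior_type == 2 && !fix_pi) {
      int n_in = 0; for (int j = 0; j < p; ++j) n_in += del[j];
      pi_zero = R::rbeta(pi_a + (p - n_in), pi_b + n_in);
    }

    // residual variance
    if (!fix_s2e) {
      double sse = 0; for (int i = 0; i < n; ++i) sse += e[i] * e[i];
      s2e = (sse + nu_e * S_e) / R::rchisq(nu_e + n);
      if (!std::isfinite(s2e))
        stop("non-finite residual variance at iteration %d", it + 1);
      if (s2e < EPS_VAR) s2e = EPS_VAR;
    }

    if (it >= burnin && (it - burnin) % thin == 0) {
      for (int j = 0; j < p; ++j) { b_sum[j] += b[j]; s2bj_sum[j] += s2bj[j]; }
      for (int k = 0; k < q; ++k) fx_sum[k] += fx[k];
      s2e_chain[saved] = s2e;
      s2e_sum += s2e; s2b_sum += s2b; pi_sum += pi_zero; gamma2_sum += gamma2;
      if (keep_effect_draws)
        for (int j = 0; j < p; ++j) b_draws(saved, j) = b[j];
      ++saved;
    }
  }

  NumericVector b_mean(p), fx_mean(q), s2bj_mean(p);
  for (int j = 0; j < p; ++j) {
    b_mean[j] = b_sum[j] / saved;
    s2bj_mean[j] = s2bj_sum[j] / saved;
  }
  for (int k = 0; k < q; ++k) fx_mean[k] = fx_sum[k] / saved;

  List out = List::create(
    _["b"] = b_mean, _["fixed"] = fx_mean,
    _["sigma2_e"] = s2e_sum / saved,
    _["sigma2_e_chain"] = s2e_chain,
    _["sigma2_b"] = s2b_sum / saved,
    _["sigma2_bj"] = s2bj_mean,
    _["pi_zero"] = pi_sum / saved,
    _["gamma2"] = gamma2_sum / saved,
    _["n_saved"] = saved);
  if (keep_effect_draws) out["b_draws"] = b_draws;
  return out;
}
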