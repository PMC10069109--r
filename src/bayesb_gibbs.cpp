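#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// BayesB Gibbs sampler: mixture prior on penalized effects with a point mass
// at zero (probability 1 - pi) and a scaled-t slab (probability pi),
// implemented hierarchically as w_j | sigma2_j ~ N(0, sigma2_j) with
// sigma2_j ~ scaled-inv-chi2(df_u, S_B). Inclusion indicators are sampled
// with the effect analytically marginalized (no trans-dimensional moves);
// excluded effects are exact zeros. An unpenalized block (intercept +
// covariates) is updated with a flat prior. pi has a beta full conditional.
// [[Rcpp::export(name = ".bayesb_gibbs")]]
List bayesb_gibbs(NumericVector y,
                  NumericMatrix Xf,   // n x pf unpenalized block (incl. intercept)
                  NumericMatrix Xp,   // n x p penalized block (standardized)
                  int n_iter, int burn_in, int thin,
                  double df_u, double S_B,
                  double df_e, double S_e,
                  double shape_in, double shape_out,  // beta prior on pi
                  double pi_init,
                  bool update_pi,
                  double fix_sigma2_j,   // NA: hierarchical; else common fixed slab var
                  double fix_sigma2_e) { // NA: sampled
  RNGScope scope;
  const int n = y.size();
  const int pf = Xf.ncol();
  const int p = Xp.ncol();
  const bool tied_var = !NumericVector::is_na(fix_sigma2_j);
  const bool fix_e = !NumericVector::is_na(fix_sigma2_e);

  std::vector<double> bf(pf, 0.0), w(p, 0.0), sv(p);
  std::vector<int> delta(p, 1);
  double pi = pi_init;
  double vy = 0.0, my = 0.0;
  for (int i = 0; i < n; ++i) my += y[i];
  my /= n;
  for (int i = 0; i < n; ++i) vy += (y[i] - my) * (y[i] - my);
  vy /= (n - 1);
  double s2e = fix_e ? fix_sigma2_e : 0.5 * vy;
  for (int j = 0; j < p; ++j)
    sv[j] = tied_var ? fix_sigma2_j : S_B / R::rchisq(df_u);

  std::vector<double> xtx_f(pf), xtx(p);
  for (int j = 0; j < pf; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += Xf(i, j) * Xf(i, j);
    xtx_f[j] = s;
  }
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    const double* col = &Xp(0, j);
    for (int i = 0; i < n; ++i) s += col[i] * col[i];
    xtx[j] = s;
  }

  std::vector<double> e(n);
  for (int i = 0; i < n; ++i) e[i] = y[i];

  const int n_store = (n_iter - burn_in) / thin;
  NumericVector w_mean(p), incl_freq(p), bf_mean(pf);
  NumericVector pi_chain(n_store), s2e_chain(n_store);
  int stored = 0;

  for (int it = 1; it <= n_iter; ++it) {
    // unpenalized block, flat prior
    for (int j = 0; j < pf; ++j) {
      if (xtx_f[j] <= 0) continue;
      double rhs = 0.0;
      for (int i = 0; i < n; ++i) rhs += Xf(i, j) * e[i];
      rhs += xtx_f[j] * bf[j];
      double bnew = R::rnorm(rhs / xtx_f[j], std::sqrt(s2e / xtx_f[j]));
      double del = bnew - bf[j];
      if (del != 0.0) for (int i = 0; i < n; ++i) e[i] -= Xf(i, j) * del;
      bf[j] = bnew;
    }
    // penalized block: inclusion (marginalized) then effect, then slab var
    int m_in = 0;
    for (int j = 0; j < p; ++j) {
      const double* col = &Xp(0, j);
      double xe = 0.0;
      for (int i = 0; i < n; ++i) xe += col[i] * e[i];
      double xr = xe + xtx[j] * w[j];  // x_j' (y - rest), w_j removed
      double C = xtx[j] / s2e + 1.0 / sv[j];
      double m = (xr / s2e) / C;
      double log_bf = 0.5 * (-std::log(sv[j] * C) + m * m * C);
      double log_odds = std::log(pi) - std::log1p(-pi) + log_bf;
      double prob = 1.0 / (1.0 + std::exp(-log_odds));
      int dnew = (R::unif_rand() < prob) ? 1 : 0;
      double wold = w[j];
      double wnew = 0.0;
      if (dnew == 1) {
        wnew = R::rnorm(m, std::sqrt(1.0 / C));
        ++m_in;
      }
      double del = wnew - wold;
      if (del != 0.0) for (int i = 0; i < n; ++i) e[i] -= col[i] * del;
      w[j] = wnew;
      delta[j] = dnew;
      if (!tied_var) {
        if (dnew == 1)
          sv[j] = (wnew * wnew + S_B) / R::rchisq(df_u + 1.0);
        else
          sv[j] = S_B / R::rchisq(df_u);
      }
    }
    if (update_pi)
      pi = R::rbeta(shape_in + m_in, shape_out + (p - m_in));
    if (!fix_e) {
      double ess = 0.0;
      for (int i = 0; i < n; ++i) ess += e[i] * e[i];
      s2e = (ess + S_e) / R::rchisq(n + df_e);
    }
    if (it > burn_in && (it - burn_in) % thin == 0 && stored < n_store) {
      for (int j = 0; j < p; ++j) {
        w_mean[j] += w[j];
        incl_freq[j] += delta[j];
      }
      for (int j = 0; j < pf; ++j) bf_mean[j] += bf[j];
      pi_chain[stored] = pi;
      s2e_chain[stored] = s2e;
      ++stored;
    }
  }
  if (stored > 0) {
    for (int j = 0; j < p; ++j) { w_mean[j] /= stored; incl_freq[j] /= stored; }
    for (int j = 0; j < pf; ++j) bf_mean[j] /= stored;
  }
  return List::create(_["effect_mean"] = w_mean,
                      _["inclusion_freq"] = incl_freq,
                      _["fixed_mean"] = bf_mean,
                      _["pi_chain"] = pi_chain,
                      _["sigma2_e_chain"] = s2e_chain,
                      _["n_stored"] = stored);
}
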