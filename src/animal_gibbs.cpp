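#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Single-site Gibbs sampler for the animal model
//   y = X b + W h + Z a + e,
//   a ~ N(0, H sigma2_a), h ~ N(0, I sigma2_batch), e ~ N(0, I sigma2_e),
// parameterized directly through the inverse combined relationship matrix
// Hinv (N x N over all animals, dense). Location effects are updated
// single-site with residual updating; a running u = Hinv %*% a is maintained
// incrementally so each sweep costs O(N^2) and the quadratic form a'Hinv a
// is free. Variances have scaled-inverse-chi-square full conditionals.
//
// batch: 0-based batch index per record, or -1 when the model has no batch
// term. animal: 0-based index of each record's animal in the Hinv ordering.
// fix_sigma2: length-3 vector (a, batch, e); NA entries are sampled.
// [[Rcpp::export(name = ".animal_gibbs")]]
List animal_gibbs(NumericVector y,
                  NumericMatrix X,
                  IntegerVector batch,
                  int n_batch,
                  IntegerVector animal,
                  NumericMatrix Hinv,
                  int n_iter, int burn_in, int thin,
                  double nu_a, double S_a,
                  double nu_b, double S_b,
                  double nu_e, double S_e,
                  NumericVector fix_sigma2,
                  NumericVector init_sigma2) {
  RNGScope scope;
  const int n = y.size();
  const int p = X.ncol();
  const int N = Hinv.nrow();
  const bool has_batch = n_batch > 0;

  std::vector<double> b(p, 0.0), h(n_batch, 0.0), a(N, 0.0), u(N, 0.0);
  double s2a = init_sigma2[0], s2b = init_sigma2[1], s2e = init_sigma2[2];
  const bool fix_a = !NumericVector::is_na(fix_sigma2[0]);
  const bool fix_b = !NumericVector::is_na(fix_sigma2[1]);
  const bool fix_e = !NumericVector::is_na(fix_sigma2[2]);
  if (fix_a) s2a = fix_sigma2[0];
  if (fix_b) s2b = fix_sigma2[1];
  if (fix_e) s2e = fix_sigma2[2];

  // precomputations
  std::vector<double> xtx(p);
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    xtx[j] = s;
  }
  std::vector<int> nb(n_batch, 0);
  if (has_batch) for (int i = 0; i < n; ++i) nb[batch[i]]++;
  std::vector< std::vector<int> > recs(N);
  for (int i = 0; i < n; ++i) recs[animal[i]].push_back(i);

  std::vector<double> e(n);
  for (int i = 0; i < n; ++i) e[i] = y[i];

  const int n_store = (n_iter - burn_in) / thin;
  NumericMatrix var_samples(n_store, 3);
  NumericMatrix b_samples(n_store, p);
  NumericVector a_mean(N), h_mean(std::max(n_batch, 1));
  int stored = 0;

  const double* Hp = Hinv.begin();

  for (int it = 1; it <= n_iter; ++it) {
    // fixed effects, flat prior
    for (int j = 0; j < p; ++j) {
      if (xtx[j] <= 0) continue;
      double rhs = 0.0;
      for (int i = 0; i < n; ++i) rhs += X(i, j) * e[i];
      rhs += xtx[j] * b[j];
      double mean = rhs / xtx[j];
      double bnew = R::rnorm(mean, std::sqrt(s2e / xtx[j]));
      double del = bnew - b[j];
      if (del != 0.0) for (int i = 0; i < n; ++i) e[i] -= X(i, j) * del;
      b[j] = bnew;
    }
    // batch effects
    if (has_batch) {
      for (int k = 0; k < n_batch; ++k) {
        double rhs = nb[k] * h[k];
        for (int i = 0; i < n; ++i) if (batch[i] == k) rhs += e[i];
        double prec = nb[k] / s2e + 1.0 / s2b;
        double mean = (rhs / s2e) / prec;
        double hnew = R::rnorm(mean, std::sqrt(1.0 / prec));
        double del = hnew - h[k];
        if (del != 0.0) for (int i = 0; i < n; ++i) if (batch[i] == k) e[i] -= del;
        h[k] = hnew;
      }
    }
    // animal effects with incremental u = Hinv a
    {
      double* __restrict__ ud = u.data();
      double* __restrict__ ad = a.data();
      double* __restrict__ ed = e.data();
      for (int i = 0; i < N; ++i) {
        const double* __restrict__ col = Hp + (size_t)i * N;  // symmetric
        const double hii = col[i];
        const std::vector<int>& ri = recs[i];
        double rhs = 0.0;
        for (size_t r = 0; r < ri.size(); ++r) rhs += ed[ri[r]] + ad[i];
        rhs /= s2e;
        rhs -= (ud[i] - hii * ad[i]) / s2a;
        double prec = ri.size() / s2e + hii / s2a;
        double mean = rhs / prec;
        double anew = R::rnorm(mean, std::sqrt(1.0 / prec));
        double del = anew - ad[i];
        for (size_t r = 0; r < ri.size(); ++r) ed[ri[r]] -= del;
        for (int j2 = 0; j2 < N; ++j2) ud[j2] += col[j2] * del;
        ad[i] = anew;
      }
    }
    // periodic refresh against floating-point drift
    if (it % 1000 == 0) {
      for (int j2 = 0; j2 < N; ++j2) {
        double s = 0.0;
        const double* row = Hp + (size_t)j2 * N;
        for (int k2 = 0; k2 < N; ++k2) s += row[k2] * a[k2];
        u[j2] = s;
      }
      for (int i = 0; i < n; ++i) {
        double fit = 0.0;
        for (int j = 0; j < p; ++j) fit += X(i, j) * b[j];
        if (has_batch) fit += h[batch[i]];
        fit += a[animal[i]];
        e[i] = y[i] - fit;
      }
    }
    // variances
    if (!fix_a) {
      double aqf = 0.0;
      for (int j2 = 0; j2 < N; ++j2) aqf += a[j2] * u[j2];
      s2a = (aqf + nu_a * S_a) / R::rchisq(N + nu_a);
    }
    if (has_batch && !fix_b) {
      double hss = 0.0;
      for (int k = 0; k < n_batch; ++k) hss += h[k] * h[k];
      s2b = (hss + nu_b * S_b) / R::rchisq(n_batch + nu_b);
    }
    if (!fix_e) {
      double ess = 0.0;
      for (int i = 0; i < n; ++i) ess += e[i] * e[i];
      s2e = (ess + nu_e * S_e) / R::rchisq(n + nu_e);
    }
    // store
    if (it > burn_in && (it - burn_in) % thin == 0 && stored < n_store) {
      var_samples(stored, 0) = s2a;
      var_samples(stored, 1) = has_batch ? s2b : NA_REAL;
      var_samples(stored, 2) = s2e;
      for (int j = 0; j < p; ++j) b_samples(stored, j) = b[j];
      for (int j2 = 0; j2 < N; ++j2) a_mean[j2] += a[j2];
      if (has_batch) for (int k = 0; k < n_batch; ++k) h_mean[k] += h[k];
      ++stored;
    }
  }
  if (stored > 0) {
    for (int j2 = 0; j2 < N; ++j2) a_mean[j2] /= stored;
    if (has_batch) for (int k = 0; k < n_batch; ++k) h_mean[k] /= stored;
  }
  return List::create(_["var_samples"] = var_samples,
                      _["b_samples"] = b_samples,
                      _["a_mean"] = a_mean,
                      _["h_mean"] = h_mean,
                      _["n_stored"] = stored);
}
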