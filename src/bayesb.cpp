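#include <Rcpp.h>
using namespace Rcpp;

// Marginal log-likelihood score of a candidate marker variance s2 against the
// locus-corrected data, up to terms independent of s2 (they cancel in the MH
// ratio). V = I*sige2 + w w' * s2, so via the matrix determinant lemma and
// Sherman-Morrison only w'w and w'y* enter.
static inline double var_score(double s2, double ww, double wy, double sige2) {
  if (s2 <= 0.0) return 0.0;
  double d = sige2 + ww * s2;
  return -0.5 * std::log(d / sige2) + 0.5 * wy * wy * s2 / (sige2 * d);
}

// BayesB Gibbs chain with Metropolis-Hastings locus-variance updates
// (proposal = the mixture prior, so prior terms cancel in the ratio).
// W must be column-centered; y is modeled as mu + W a + e.
// [[Rcpp::export]]
List bayesb_mcmc(NumericVector y, NumericMatrix W, double pi_zero, double nu,
                 double S, double nu_e, double S_e, int chain_length,
                 int burn_in, int mh_iters, int thinning) {
  const int n = y.size(), m = W.ncol();
  if (W.nrow() != n) stop("W and y dimensions differ");

  std::vector<double> ww(m);
  for (int j = 0; j < m; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += W(i, j) * W(i, j);
    ww[j] = s;
  }

  double mu = mean(y);
  std::vector<double> a(m, 0.0), varg(m, 0.0), e(n);
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;
  double sige2 = 0.0;
  for (int i = 0; i < n; ++i) sige2 += e[i] * e[i];
  sige2 = std::max(sige2 / n, 1e-12);

  std::vector<double> sum_a(m, 0.0), sum_incl(m, 0.0);
  double sum_mu = 0.0, sum_sige2 = 0.0;
  int kept = 0;
  IntegerVector fitted_count(chain_length);
  NumericVector sige2_trace(chain_length);

  for (int it = 0; it < chain_length; ++it) {
    // mu | rest
    double rbar = 0.0;
    for (int i = 0; i < n; ++i) rbar += e[i] + mu;
    rbar /= n;
    double mu_new = R::rnorm(rbar, std::sqrt(sige2 / n));
    for (int i = 0; i < n; ++i) e[i] += mu - mu_new;
    mu = mu_new;

    // loci
    for (int j = 0; j < m; ++j) {
      if (ww[j] <= 0.0) continue;  // constant column carries no signal
      double aj = a[j];
      double wy = ww[j] * aj;
      for (int i = 0; i < n; ++i) wy += W(i, j) * e[i];

      double cur = varg[j];
      double cur_score = var_score(cur, ww[j], wy, sige2);
      for (int t = 0; t < mh_iters; ++t) {
        double prop;
        if (R::runif(0.0, 1.0) < pi_zero) {
          if (cur == 0.0) continue;  // 0 -> 0: no change
          prop = 0.0;
        } else {
          prop = nu * S / R::rchisq(nu);
        }
        double prop_score = var_score(prop, ww[j], wy, sige2);
        if (std::log(R::runif(0.0, 1.0)) < prop_score - cur_score) {
          cur = prop;
          cur_score = prop_score;
        }
      }
      varg[j] = cur;

      double a_new;
      if (cur == 0.0) {
        a_new = 0.0;
      } else {
        double prec = ww[j] / sige2 + 1.0 / cur;
        a_new = R::rnorm((wy / sige2) / prec, std::sqrt(1.0 / prec));
      }
      if (a_new != aj) {
        double d = aj - a_new;
        for (int i = 0; i < n; ++i) e[i] += W(i, j) * d;
        a[j] = a_new;
      }
    }

    // residual variance | rest (scaled inverse chi-square)
    double sse = 0.0;
    for (int i = 0; i < n; ++i) sse += e[i] * e[i];
    sige2 = (sse + nu_e * S_e) / R::rchisq((double)n + nu_e);
    if (!R_finite(sige2) || sige2 <= 0.0) {
      stop("residual variance diverged at iteration %d", it + 1);
    }

    int nf = 0;
    for (int j = 0; j < m; ++j) if (varg[j] > 0.0) ++nf;
    fitted_count[it] = nf;
    sige2_trace[it] = sige2;

    if (it >= burn_in && ((it - burn_in) % thinning == 0)) {
      ++kept;
      sum_mu += mu;
      sum_sige2 += sige2;
      for (int j = 0; j < m; ++j) {
        sum_a[j] += a[j];
        if (varg[j] > 0.0) sum_incl[j] += 1.0;
      }
    }
  }

  NumericVector pm_a(m), incl(m);
  for (int j = 0; j < m; ++j) {
    pm_a[j] = sum_a[j] / kept;
    incl[j] = sum_incl[j] / kept;
  }
  return List::create(
    _["effects"] = pm_a, _["inclusion"] = incl,
    _["mu"] = sum_mu / kept, _["sigma_e2"] = sum_sige2 / kept,
    _["n_retained"] = kept, _["fitted_count"] = fitted_count,
    _["sigma_e2_trace"] = sige2_trace);
}
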