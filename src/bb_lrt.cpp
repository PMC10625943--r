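// Per-CpG beta-binomial likelihood-ratio test kernel.
//
// For one CpG site with replicate-level (methylated, total) counts in two
// tissues, the counts are modelled as beta-binomial with mean mu and
// precision s (alpha = mu*s, beta = (1-mu)*s).  H0: one shared mu across
// tissues; H1: tissue-specific mu's; s shared between hypotheses and
// profiled on a fixed grid under H1.  The statistic 2*(llH1 - llH0) is
// referred to chi-square(1) in R.

#include <Rcpp.h>
using namespace Rcpp;

static double bb_ll(double mu, double s, const double* m, const double* t,
                    int n) {
  double a = mu * s, b = (1.0 - mu) * s;
  double lab = R::lbeta(a, b), ll = 0.0;
  for (int i = 0; i < n; ++i) {
    if (t[i] <= 0) continue;
    ll += R::lbeta(m[i] + a, t[i] - m[i] + b) - lab;
  }
  return ll;
}

// golden-section maximization of bb_ll over mu in (eps, 1-eps)
static double opt_mu(double s, const double* m, const double* t, int n,
                     double* ll_out) {
  const double gr = 0.6180339887498949;
  double lo = 1e-6, hi = 1.0 - 1e-6;
  double x1 = hi - gr * (hi - lo), x2 = lo + gr * (hi - lo);
  double f1 = bb_ll(x1, s, m, t, n), f2 = bb_ll(x2, s, m, t, n);
  for (int it = 0; it < 60; ++it) {
    if (f1 < f2) {
      lo = x1; x1 = x2; f1 = f2;
      x2 = lo + gr * (hi - lo); f2 = bb_ll(x2, s, m, t, n);
    } else {
      hi = x2; x2 = x1; f2 = f1;
      x1 = hi - gr * (hi - lo); f1 = bb_ll(x1, s, m, t, n);
    }
  }
  double mu = 0.5 * (lo + hi);
  *ll_out = bb_ll(mu, s, m, t, n);
  return mu;
}

// [[Rcpp::export(name = ".bb_lrt_cpp")]]
List bb_lrt_cpp(NumericMatrix meth_a, NumericMatrix tot_a,
                NumericMatrix meth_b, NumericMatrix tot_b,
                NumericVector s_grid) {
  int nsite = meth_a.nrow();
  int na = meth_a.ncol(), nb = meth_b.ncol();
  int ns = s_grid.size();
  NumericVector stat(nsite), mu_a(nsite), mu_b(nsite), s_hat(nsite);
  std::vector<double> ma(na), ta(na), mb(nb), tb(nb), mp(na + nb), tp(na + nb);
  for (int i = 0; i < nsite; ++i) {
    for (int j = 0; j < na; ++j) {
      ma[j] = meth_a(i, j); ta[j] = tot_a(i, j);
      mp[j] = ma[j]; tp[j] = ta[j];
    }
    for (int j = 0; j < nb; ++j) {
      mb[j] = meth_b(i, j); tb[j] = tot_b(i, j);
      mp[na + j] = mb[j]; tp[na + j] = tb[j];
    }
    // profile the shared precision on the grid under H1
    double best_ll = R_NegInf, best_s = s_grid[0];
    double best_mua = 0.5, best_mub = 0.5;
    for (int k = 0; k < ns; ++k) {
      double lla, llb;
      double mua = opt_mu(s_grid[k], ma.data(), ta.data(), na, &lla);
      double mub = opt_mu(s_grid[k], mb.data(), tb.data(), nb, &llb);
      if (lla + llb > best_ll) {
        best_ll = lla + llb; best_s = s_grid[k];
        best_mua = mua; best_mub = mub;
      }
    }
    double ll0;
    opt_mu(best_s, mp.data(), tp.data(), na + nb, &ll0);
    double lr = 2.0 * (best_ll - ll0);
    stat[i] = lr > 0 ? lr : 0.0;
    mu_a[i] = best_mua; mu_b[i] = best_mub; s_hat[i] = best_s;
  }
  return List::create(_["stat"] = stat, _["mu_a"] = mu_a, _["mu_b"] = mu_b,
                      _["s"] = s_hat);
}
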