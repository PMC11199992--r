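#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Weighted pool-adjacent-violators (increasing). Only the fitted value of
// the final block is needed (the amalgamated mean at the top dose), so the
// merged levels are not expanded back.
static double pava_top(const std::vector<double>& m,
                       const std::vector<double>& w) {
  int n = (int)m.size();
  std::vector<double> lm(n), lw(n);
  int top = -1;
  for (int i = 0; i < n; ++i) {
    ++top;
    lm[top] = m[i];
    lw[top] = w[i];
    while (top > 0 && lm[top - 1] > lm[top]) {
      double tw = lw[top - 1] + lw[top];
      lm[top - 1] = (lm[top - 1] * lw[top - 1] + lm[top] * lw[top]) / tw;
      lw[top - 1] = tw;
      --top;
    }
  }
  return lm[top];
}

// Williams-type trend statistic, two-directional: isotonic amalgamation of
// the dose-group means (control excluded), t-like contrast of the top
// amalgamated mean against the control mean with the pooled within-group
// SD. Returns NA when the pooled variance is zero.
static double williams_stat(const double* y, const int* grp, int ns, int k) {
  std::vector<double> sum(k + 1, 0.0), ss(k + 1, 0.0);
  std::vector<int> n(k + 1, 0);
  for (int i = 0; i < ns; ++i) {
    int g = grp[i];
    sum[g] += y[i];
    ss[g] += y[i] * y[i];
    n[g]++;
  }
  double sse = 0.0;
  int df = 0;
  std::vector<double> mean(k + 1);
  for (int g = 0; g <= k; ++g) {
    if (n[g] == 0) return NA_REAL;
    mean[g] = sum[g] / n[g];
    sse += ss[g] - sum[g] * sum[g] / n[g];
    df += n[g] - 1;
  }
  if (df <= 0) return NA_REAL;
  double s2 = sse / df;
  if (s2 <= 0.0) return NA_REAL;
  double s = std::sqrt(s2);
  double denom = s * std::sqrt(1.0 / n[k] + 1.0 / n[0]);

  std::vector<double> dm(k), dw(k);
  for (int g = 1; g <= k; ++g) {
    dm[g - 1] = mean[g];
    dw[g - 1] = (double)n[g];
  }
  double t_up = (pava_top(dm, dw) - mean[0]) / denom;
  for (int g = 0; g < k; ++g) dm[g] = -dm[g];
  double t_dn = (pava_top(dm, dw) + mean[0]) / denom;
  return t_up > t_dn ? t_up : t_dn;
}

// Permutation p-values per gene. A fresh set of permutations is drawn for
// each gene from R's RNG (Fisher-Yates with unif_rand), so p-values are
// independent across genes and fully determined by the R-side seed.
// [[Rcpp::export]]
List williams_perm_core(NumericMatrix Y, IntegerVector grp, int n_perm) {
  int ng = Y.nrow(), ns = Y.ncol();
  if (grp.size() != ns) stop("group vector length mismatch");
  if (n_perm < 1) stop("n_perm must be positive");
  int k = 0;
  for (int i = 0; i < ns; ++i) if (grp[i] > k) k = grp[i];
  NumericVector pval(ng), stat(ng);
  std::vector<double> y(ns), yp(ns);
  std::vector<int> g(ns);
  for (int i = 0; i < ns; ++i) g[i] = grp[i];
  RNGScope scope;
  for (int r = 0; r < ng; ++r) {
    for (int i = 0; i < ns; ++i) y[i] = Y(r, i);
    double obs = williams_stat(y.data(), g.data(), ns, k);
    if (ISNAN(obs)) {           // degenerate (e.g. all-constant): p = 1
      stat[r] = NA_REAL;
      pval[r] = 1.0;
      continue;
    }
    int count = 0;
    for (int p = 0; p < n_perm; ++p) {
      for (int i = 0; i < ns; ++i) yp[i] = y[i];
      for (int i = ns - 1; i > 0; --i) {
        int j = (int)(unif_rand() * (i + 1));
        if (j > i) j = i;
        double tmp = yp[i]; yp[i] = yp[j]; yp[j] = tmp;
      }
      double st = williams_stat(yp.data(), g.data(), ns, k);
      if (!ISNAN(st) && st >= obs - 1e-12) ++count;
    }
    stat[r] = obs;
    pval[r] = (1.0 + count) / (1.0 + n_perm);
  }
  return List::create(Named("stat") = stat, Named("pvalue") = pval);
}
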