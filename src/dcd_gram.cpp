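// Same dual coordinate descent as dcd.cpp but on a precomputed linear
// Gram matrix (with the intercept's constant feature already folded in
// as +1 on every entry). With n samples in d >> n dimensions this makes
// each sweep O(n^2) instead of O(n d), and one Gram matrix serves every
// cost value and every cross-validation fold of a dataset.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
List dcd_gram_svm(NumericMatrix K, NumericVector y, double C,
                  int max_epochs, double tol) {
  const int n = K.nrow();
  std::vector<double> alpha(n, 0.0), ay(n, 0.0);
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  int epoch = 0;
  RNGScope scope;
  for (epoch = 1; epoch <= max_epochs; ++epoch) {
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(idx[i], idx[j]);
    }
    double maxpg = 0.0;
    for (int t = 0; t < n; ++t) {
      int i = idx[t];
      const double* ki = &K(0, i);
      double f = 0.0;
      for (int j = 0; j < n; ++j) f += ki[j] * ay[j];
      double g = y[i] * f - 1.0;
      double pg = g;
      if (alpha[i] <= 0.0) pg = std::min(g, 0.0);
      else if (alpha[i] >= C) pg = std::max(g, 0.0);
      if (std::fabs(pg) > maxpg) maxpg = std::fabs(pg);
      double qii = ki[i];
      if (std::fabs(pg) > 1e-12 && qii > 0.0) {
        double a_new = alpha[i] - g / qii;
        if (a_new < 0.0) a_new = 0.0;
        else if (a_new > C) a_new = C;
        alpha[i] = a_new;
        ay[i] = a_new * y[i];
      }
    }
    if (maxpg < tol) break;
  }
  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["epochs"] = std::min(epoch, max_epochs));
}
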