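// Dual coordinate descent for the linear L1 (hinge) soft-margin SVM:
//   min_w 0.5 ||w||^2 + C sum_i max(0, 1 - y_i w'x_i)
// solved in the dual with random permutation sweeps (Hsieh et al. style).
// The intercept is handled by the caller through an appended constant
// feature. Xt is d x n (one column per sample) for contiguous access.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
List dcd_linear_svm(NumericMatrix Xt, NumericVector y, double C,
                    int max_epochs, double tol) {
  const int d = Xt.nrow(), n = Xt.ncol();
  std::vector<double> alpha(n, 0.0), w(d, 0.0), Qii(n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    const double* xi = &Xt(0, i);
    for (int j = 0; j < d; ++j) s += xi[j] * xi[j];
    Qii[i] = s;
  }
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  int epoch = 0;
  RNGScope scope;
  for (epoch = 1; epoch <= max_epochs; ++epoch) {
    // Fisher-Yates with R's RNG for reproducibility under set.seed()
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(idx[i], idx[j]);
    }
    double maxpg = 0.0;
    for (int t = 0; t < n; ++t) {
      int i = idx[t];
      const double* xi = &Xt(0, i);
      double g = 0.0;
      for (int j = 0; j < d; ++j) g += w[j] * xi[j];
      g = y[i] * g - 1.0;
      double pg = g;
      if (alpha[i] <= 0.0) pg = std::min(g, 0.0);
      else if (alpha[i] >= C) pg = std::max(g, 0.0);
      if (std::fabs(pg) > maxpg) maxpg = std::fabs(pg);
      if (std::fabs(pg) > 1e-12 && Qii[i] > 0.0) {
        double a_old = alpha[i];
        double a_new = alpha[i] - g / Qii[i];
        if (a_new < 0.0) a_new = 0.0;
        else if (a_new > C) a_new = C;
        alpha[i] = a_new;
        double delta = (a_new - a_old) * y[i];
        if (delta != 0.0)
          for (int j = 0; j < d; ++j) w[j] += delta * xi[j];
      }
    }
    if (maxpg < tol) break;
  }
  return List::create(_["w"] = NumericVector(w.begin(), w.end()),
                      _["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["epochs"] = std::min(epoch, max_epochs));
}
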