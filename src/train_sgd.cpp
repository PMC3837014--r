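#include <Rcpp.h>
using namespace Rcpp;

// Online SGD on squared error 0.5*(o-y)^2 for the 780-3-1 sigmoid network.
// Windows are one-hot and passed sparsely: idx is a 39 x n integer matrix of
// active input indices (1-based; 0 marks an inactive slot, e.g. an unknown
// residue). Example order is reshuffled each epoch with R's RNG, so the
// caller's seed controls the whole run. Returns the per-epoch mean squared
// error; parameters are updated in place on copies returned as a list.
static inline double sigmoid(double z) { return 1.0 / (1.0 + std::exp(-z)); }

// [[Rcpp::export(name = ".train_sgd")]]
List train_sgd(NumericMatrix W0, NumericVector bh0, NumericVector wo0,
               double bo, IntegerMatrix idx, NumericVector y,
               int epochs, double lr) {
  const int n = idx.ncol(), slots = idx.nrow(), H = W0.ncol();
  NumericMatrix W = clone(W0);
  NumericVector bh = clone(bh0), wo = clone(wo0);
  NumericVector mse(epochs);
  std::vector<double> h(H), gh(H);
  for (int ep = 0; ep < epochs; ++ep) {
    IntegerVector ord = sample(n, n, false);  // R's RNG: reproducible
    double se = 0.0;
    for (int k = 0; k < n; ++k) {
      const int e = ord[k] - 1;
      for (int j = 0; j < H; ++j) {
        double z = bh[j];
        for (int s = 0; s < slots; ++s) {
          const int i = idx(s, e);
          if (i > 0) z += W(i - 1, j);
        }
        h[j] = sigmoid(z);
      }
      double zo = bo;
      for (int j = 0; j < H; ++j) zo += wo[j] * h[j];
      const double o = sigmoid(zo);
      const double d = o - y[e];
      se += d * d;
      const double go = d * o * (1.0 - o);
      for (int j = 0; j < H; ++j) {
        gh[j] = go * wo[j] * h[j] * (1.0 - h[j]);
        wo[j] -= lr * go * h[j];
        bh[j] -= lr * gh[j];
      }
      bo -= lr * go;
      for (int s = 0; s < slots; ++s) {
        const int i = idx(s, e);
        if (i > 0)
          for (int j = 0; j < H; ++j) W(i - 1, j) -= lr * gh[j];
      }
    }
    mse[ep] = se / n;
    if (!std::isfinite(mse[ep]))
      stop("non-finite training loss in epoch %d", ep + 1);
  }
  return List::create(_["W"] = W, _["b_h"] = bh, _["w_o"] = wo,
                      _["b_o"] = bo, _["mse"] = mse);
}
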