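#include <Rcpp.h>
using namespace Rcpp;

// Sequential SOM training loop. All randomness (sample order) and the
// per-iteration learning rate / neighborhood radius are precomputed in R,
// so this core is deterministic. The update is
//   w_j <- w_j + alpha * h(j) * (x - w_j),
// with Gaussian neighborhood h(j) = exp(-d_grid(j, bmu)^2 / (2 radius^2));
// a vanishing radius degenerates to updating the BMU only (h = 1 there).
// [[Rcpp::export]]
NumericMatrix som_train_c(NumericMatrix weights, NumericMatrix x,
                          NumericMatrix grid_coords, IntegerVector order,
                          NumericVector alpha, NumericVector radius) {
  const int n_nodes = weights.nrow();
  const int p = weights.ncol();
  const int n_iter = order.size();
  NumericMatrix w = clone(weights);

  for (int it = 0; it < n_iter; ++it) {
    const int row = order[it];
    // best matching unit: argmin squared distance, ties to lowest index
    int bmu = 0;
    double best = R_PosInf;
    for (int j = 0; j < n_nodes; ++j) {
      double d2 = 0.0;
      for (int k = 0; k < p; ++k) {
        const double diff = x(row, k) - w(j, k);
        d2 += diff * diff;
      }
      if (d2 < best) {
        best = d2;
        bmu = j;
      }
    }
    const double a = alpha[it];
    const double r = radius[it];
    if (r < 1e-12) {
      for (int k = 0; k < p; ++k) {
        w(bmu, k) += a * (x(row, k) - w(bmu, k));
      }
    } else {
      const double denom = 2.0 * r * r;
      for (int j = 0; j < n_nodes; ++j) {
        const double dr = grid_coords(j, 0) - grid_coords(bmu, 0);
        const double dc = grid_coords(j, 1) - grid_coords(bmu, 1);
        const double h = std::exp(-(dr * dr + dc * dc) / denom);
        if (h < 1e-12) continue;
        const double ah = a * h;
        for (int k = 0; k < p; ++k) {
          w(j, k) += ah * (x(row, k) - w(j, k));
        }
      }
    }
  }
  return w;
}
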