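#include <Rcpp.h>
using namespace Rcpp;

// Online SOM training pass. Presentation order is precomputed in R (seeded
// shuffles, 1-based indices) so the loop is fully deterministic and
// single-threaded: bit-reproducibility under a fixed seed is a contract.
//
// w       : m x p weight matrix (modified copy returned)
// x       : n x p data matrix
// ord     : E x n matrix of 1-based row indices, one shuffled pass per epoch
// gx, gy  : grid coordinates per neuron (length m)
// alpha0/1, sigma0/1 : linear schedules over epochs
//
// Returns list(weights, qe) where qe[e] is the mean Euclidean BMU distance
// over the presentations of epoch e (measured at presentation time).
// [[Rcpp::export]]
List som_train_cpp(NumericMatrix w, NumericMatrix x, IntegerMatrix ord,
                   NumericVector gx, NumericVector gy,
                   double alpha0, double alpha1,
                   double sigma0, double sigma1) {
  const int m = w.nrow(), p = w.ncol(), n = x.nrow(), E = ord.nrow();
  NumericMatrix wt = clone(w);
  NumericVector qe(E);

  for (int e = 0; e < E; ++e) {
    const double f = (E > 1) ? (double)e / (double)(E - 1) : 0.0;
    const double alpha = alpha0 + (alpha1 - alpha0) * f;
    const double sigma = sigma0 + (sigma1 - sigma0) * f;
    const double s2 = 2.0 * sigma * sigma;
    double qsum = 0.0;

    for (int t = 0; t < n; ++t) {
      const int i = ord(e, t) - 1;

      // best matching unit: minimal Euclidean distance, ties to lowest index
      int bmu = 0;
      double best = R_PosInf;
      for (int j = 0; j < m; ++j) {
        double d = 0.0;
        for (int k = 0; k < p; ++k) {
          const double diff = x(i, k) - wt(j, k);
          d += diff * diff;
        }
        if (d < best) { best = d; bmu = j; }
      }
      qsum += std::sqrt(best);

      // neighborhood-decayed update toward the input
      for (int j = 0; j < m; ++j) {
        const double dx = gx[j] - gx[bmu];
        const double dy = gy[j] - gy[bmu];
        const double h = std::exp(-(dx * dx + dy * dy) / s2);
        const double ah = alpha * h;
        if (ah < 1e-12) continue;  // sigma -> 0 limit: BMU-only moves
        for (int k = 0; k < p; ++k)
          wt(j, k) += ah * (x(i, k) - wt(j, k));
      }
    }
    qe[e] = qsum / n;
    if (E > 0 && !R_FINITE(wt(0, 0)))
      stop("non-finite weights at epoch %d", e + 1);
  }

  // full NaN check once at the end (cheap relative to training)
  for (int j = 0; j < m; ++j)
    for (int k = 0; k < p; ++k)
      if (!R_FINITE(wt(j, k)))
        stop("training produced non-finite weights");

  return List::create(_["weights"] = wt, _["qe"] = qe);
}
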