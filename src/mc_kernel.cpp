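#include <Rcpp.h>
using namespace Rcpp;

// Single-site-flip Metropolis chain over the binary occupancy microstates of
// a coupled titration system at one solution condition. g holds the
// occupied-state energies (meV) at this condition; W the pairwise
// interaction matrix (meV). Uses the R RNG so results are reproducible from
// set.seed(). Occupancy is recorded after every post-burn-in step and
// aggregated into batch means for standard-error estimation.
// [[Rcpp::export]]
List mc_chain(NumericVector g, NumericMatrix W, double kT, int n_steps,
              double burn_frac, int n_batches) {
  const int n = g.size();
  std::vector<int> x(n, 0);
  std::vector<double> field(n, 0.0);  // sum_j x_j W_ij

  const int burn = (int)std::floor(n_steps * burn_frac);
  const int keep = n_steps - burn;
  const int batch_len = keep / n_batches;

  NumericMatrix batch_means(n_batches, n);
  std::vector<double> acc(n, 0.0);
  int batch = 0, in_batch = 0;

  for (int step = 0; step < n_steps; ++step) {
    int i = (int)(unif_rand() * n);
    if (i == n) i = n - 1;
    double dG = (1 - 2 * x[i]) * (g[i] + field[i]);
    if (dG <= 0.0 || unif_rand() < std::exp(-dG / kT)) {
      int delta = 1 - 2 * x[i];
      x[i] += delta;
      for (int j = 0; j < n; ++j)
        if (j != i) field[j] += delta * W(i, j);
    }
    if (step >= burn && batch < n_batches) {
      for (int j = 0; j < n; ++j) acc[j] += x[j];
      if (++in_batch == batch_len) {
        for (int j = 0; j < n; ++j) {
          batch_means(batch, j) = acc[j] / batch_len;
          acc[j] = 0.0;
        }
        ++batch;
        in_batch = 0;
      }
    }
  }

  NumericVector mean_occ(n), se(n);
  for (int j = 0; j < n; ++j) {
    double m = 0.0;
    for (int b = 0; b < n_batches; ++b) m += batch_means(b, j);
    m /= n_batches;
    double v = 0.0;
    for (int b = 0; b < n_batches; ++b) {
      double d = batch_means(b, j) - m;
      v += d * d;
    }
    v /= (n_batches - 1);
    mean_occ[j] = m;
    se[j] = std::sqrt(v / n_batches);
  }
  return List::create(_["mean"] = mean_occ, _["se"] = se,
                      _["batch_means"] = batch_means);
}
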