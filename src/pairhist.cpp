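#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Weighted pair-distance histogram: for all i < j accumulate f_i*f_j into
// bins of width `bin`. Returns bin centers (nonempty bins only) and summed
// weights. O(N^2) but allocation-free, which keeps Debye-formula evaluation
// on 1e4-1e5 point models practical.
// [[Rcpp::export(name = ".pairHistCpp")]]
List pairHistCpp(NumericMatrix coords, NumericVector f, double bin) {
  const int n = coords.nrow();
  const double *x = &coords(0, 0), *y = &coords(0, 1), *z = &coords(0, 2);
  // upper bound on distance from the bounding box diagonal
  double mn[3], mx[3];
  for (int k = 0; k < 3; ++k) {
    mn[k] = mx[k] = coords(0, k);
    for (int i = 1; i < n; ++i) {
      double v = coords(i, k);
      if (v < mn[k]) mn[k] = v;
      if (v > mx[k]) mx[k] = v;
    }
  }
  double span2 = 0.0;
  for (int k = 0; k < 3; ++k) span2 += (mx[k] - mn[k]) * (mx[k] - mn[k]);
  const int nb = (int)std::ceil(std::sqrt(span2) / bin) + 2;
  std::vector<double> W(nb, 0.0);
  for (int i = 0; i < n - 1; ++i) {
    const double xi = x[i], yi = y[i], zi = z[i], fi = f[i];
    for (int j = i + 1; j < n; ++j) {
      const double dx = x[j] - xi, dy = y[j] - yi, dz = z[j] - zi;
      const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      int b = (int)(d / bin);
      if (b >= nb) b = nb - 1;
      W[b] += fi * f[j];
    }
  }
  std::vector<double> dc, wc;
  for (int b = 0; b < nb; ++b) {
    if (W[b] != 0.0) {
      dc.push_back((b + 0.5) * bin);
      wc.push_back(W[b]);
    }
  }
  return List::create(Named("d") = wrap(dc), Named("w") = wrap(wc));
}
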