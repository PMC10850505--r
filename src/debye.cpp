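#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Debye sum over a bead model with constant per-bead form factors:
//   I(q) = sum_i sum_j f_i f_j sin(q d_ij)/(q d_ij),  sinc(0) = 1.
// Pair distances are precomputed once; the q loop reuses them.
// [[Rcpp::export]]
NumericVector debye_profile_cpp(NumericMatrix xyz, NumericVector w, NumericVector q) {
  const int n = xyz.nrow();
  const int nq = q.size();
  const int npair = n * (n - 1) / 2;
  std::vector<double> d(npair), ww(npair);
  double self = 0.0;
  int k = 0;
  for (int i = 0; i < n; ++i) {
    self += w[i] * w[i];
    for (int j = i + 1; j < n; ++j, ++k) {
      double dx = xyz(i, 0) - xyz(j, 0);
      double dy = xyz(i, 1) - xyz(j, 1);
      double dz = xyz(i, 2) - xyz(j, 2);
      d[k] = std::sqrt(dx * dx + dy * dy + dz * dz);
      ww[k] = w[i] * w[j];
    }
  }
  NumericVector I(nq);
  for (int m = 0; m < nq; ++m) {
    double qm = q[m], s = 0.0;
    if (qm == 0.0) {
      for (int k2 = 0; k2 < npair; ++k2) s += ww[k2];
    } else {
      for (int k2 = 0; k2 < npair; ++k2) {
        double x = qm * d[k2];
        s += (x == 0.0) ? ww[k2] : ww[k2] * std::sin(x) / x;
      }
    }
    I[m] = self + 2.0 * s;
  }
  return I;
}
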