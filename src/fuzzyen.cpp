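#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Mean similarity Phi^m over all ordered pairs of mean-removed embedding
// vectors of window size m, Chebyshev distance, Gaussian-like membership
// exp(-ln2 * (d/r)^2). `nvec` is the number of embedding vectors to use
// (N - m + 1 for window m, N - m for window m + 1, matching the published
// counting convention).
static double phi_m(const NumericVector& x, int m, int nvec, double r) {
  std::vector<double> emb((size_t)nvec * m);
  for (int i = 0; i < nvec; ++i) {
    double mu = 0.0;
    for (int k = 0; k < m; ++k) mu += x[i + k];
    mu /= m;
    for (int k = 0; k < m; ++k) emb[(size_t)i * m + k] = x[i + k] - mu;
  }
  const double c = -M_LN2 / (r * r);
  double acc = 0.0;
  for (int i = 0; i < nvec; ++i) {
    const double* ei = &emb[(size_t)i * m];
    for (int j = i + 1; j < nvec; ++j) {
      const double* ej = &emb[(size_t)j * m];
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double a = std::fabs(ei[k] - ej[k]);
        if (a > d) d = a;
      }
      acc += std::exp(c * d * d);
    }
  }
  // ordered pairs i != j: twice the upper triangle
  return 2.0 * acc / ((double)nvec * (nvec - 1));
}

// [[Rcpp::export]]
double fuzzyen_cpp(NumericVector x, int m, double r) {
  int N = x.size();
  double pm  = phi_m(x, m,     N - m + 1, r);
  double pm1 = phi_m(x, m + 1, N - m,     r);
  return std::log(pm) - std::log(pm1);
}
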