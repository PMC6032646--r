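#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Approximate entropy (Pincus), self-matches included, Chebyshev distance,
// inclusive tolerance. Phi_m = mean_i log(C_i), C_i = (# matching templates
// of length m) / (N - m + 1); ApEn = Phi_m - Phi_{m+1}.
//
// Single O(N^2) pass: a pair (i, j) matching at length m is extended by one
// comparison to decide the length-(m + 1) match, so the quadratic loop is not
// run twice. Early exit on the first coordinate that exceeds r prunes most
// pairs for physiological r (~0.1-0.5 SD).

// [[Rcpp::export]]
double apen_cpp(NumericVector x, int m, double r) {
  const int n = x.size();
  if (m < 1) stop("`m` must be >= 1");
  if (n < m + 2) stop("series too short for embedding length m");
  if (!(r > 0)) stop("`r` must be > 0");

  const int nm = n - m + 1;   // templates of length m
  const int nm1 = n - m;      // templates of length m + 1
  std::vector<double> B(nm, 0.0), A(nm1, 0.0);

  const double *xs = REAL(x);
  if (m == 2) {
    // specialised hot path: hoist the template into scalars
    for (int i = 0; i < nm; ++i) {
      const double xi0 = xs[i], xi1 = xs[i + 1];
      const double xi2 = (i < nm1) ? xs[i + 2] : 0.0;
      const bool ext_i = i < nm1;
      double b = 0.0, a = 0.0;
      for (int j = 0; j < nm; ++j) {
        if (std::fabs(xi0 - xs[j]) > r) continue;
        if (std::fabs(xi1 - xs[j + 1]) > r) continue;
        b += 1.0;
        if (ext_i && j < nm1 && std::fabs(xi2 - xs[j + 2]) <= r) a += 1.0;
      }
      B[i] = b;
      if (ext_i) A[i] = a;
    }
  } else {
    for (int i = 0; i < nm; ++i) {
      for (int j = 0; j < nm; ++j) {
        bool match = true;
        for (int k = 0; k < m; ++k) {
          if (std::fabs(xs[i + k] - xs[j + k]) > r) { match = false; break; }
        }
        if (!match) continue;
        B[i] += 1.0;
        if (i < nm1 && j < nm1 && std::fabs(xs[i + m] - xs[j + m]) <= r)
          A[i] += 1.0;
      }
    }
  }

  double phi_m = 0.0, phi_m1 = 0.0;
  for (int i = 0; i < nm; ++i)  phi_m  += std::log(B[i] / nm);
  phi_m /= nm;
  for (int i = 0; i < nm1; ++i) {
    if (A[i] <= 0.0) return R_PosInf; // cannot happen with self-matches
    phi_m1 += std::log(A[i] / nm1);
  }
  phi_m1 /= nm1;
  return phi_m - phi_m1;
}
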