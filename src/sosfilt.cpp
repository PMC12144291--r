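#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// One zero-phase pass (forward or backward in time) of a second-order-
// section cascade over the rows of a column-major matrix. All sections are
// chained within a single sweep over the data, so each sample is read and
// written once regardless of the cascade length; per-section filter states
// are kept per channel (direct form II transposed).
static void sos_pass(double* y, const int nr, const int nc,
                     const double* b, const double* a, const int ns,
                     const bool forward) {
  std::vector<double> w1(static_cast<size_t>(ns) * nr, 0.0);
  std::vector<double> w2(static_cast<size_t>(ns) * nr, 0.0);
  for (int k = 0; k < nc; ++k) {
    const int t = forward ? k : nc - 1 - k;
    double* __restrict__ col = y + static_cast<size_t>(t) * nr;
    for (int s = 0; s < ns; ++s) {
      const double b0 = b[s], b1 = b[s + ns], b2 = b[s + 2 * ns];
      const double a1 = a[s + ns], a2 = a[s + 2 * ns];
      double* __restrict__ w1s = w1.data() + static_cast<size_t>(s) * nr;
      double* __restrict__ w2s = w2.data() + static_cast<size_t>(s) * nr;
      for (int r = 0; r < nr; ++r) {
        const double xt = col[r];
        const double yt = b0 * xt + w1s[r];
        w1s[r] = b1 * xt - a1 * yt + w2s[r];
        w2s[r] = b2 * xt - a2 * yt;
        col[r] = yt;
      }
    }
  }
}

// Zero-phase (forward-backward) SOS filtering of each row of x.
// b and a are n_sections x 3 coefficient matrices with a[, 1] == 1.
// [[Rcpp::export]]
NumericMatrix sos_filtfilt_rows(NumericMatrix x, NumericMatrix b,
                                NumericMatrix a) {
  NumericMatrix y = clone(x);
  const int ns = b.nrow();
  sos_pass(REAL(y), y.nrow(), y.ncol(), REAL(b), REAL(a), ns, true);
  sos_pass(REAL(y), y.nrow(), y.ncol(), REAL(b), REAL(a), ns, false);
  return y;
}
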