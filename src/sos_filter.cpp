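#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Zero-phase cascade of second-order sections applied down the rows of a
// samples x series matrix, with odd-reflection padding of `padlen` samples
// at both ends. sos: n_sections x 6 (b0 b1 b2 a0 a1 a2), a0 == 1.
// [[Rcpp::export(name = ".sos_filtfilt_cpp")]]
NumericMatrix sos_filtfilt_cpp(NumericMatrix x, NumericMatrix sos, int padlen) {
  const int n = x.nrow(), m = x.ncol(), ns = sos.nrow();
  if (n < 2) stop("need at least 2 samples");
  if (padlen < 0 || padlen > n - 1) stop("invalid padlen");
  const int N = n + 2 * padlen;
  std::vector<double> buf(N);
  NumericMatrix out(n, m);
  for (int j = 0; j < m; ++j) {
    for (int i = 0; i < padlen; ++i) buf[i] = 2.0 * x(0, j) - x(padlen - i, j);
    for (int i = 0; i < n; ++i) buf[padlen + i] = x(i, j);
    for (int i = 0; i < padlen; ++i)
      buf[padlen + n + i] = 2.0 * x(n - 1, j) - x(n - 2 - i, j);
    for (int pass = 0; pass < 2; ++pass) {
      for (int s = 0; s < ns; ++s) {
        const double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2);
        const double a1 = sos(s, 4), a2 = sos(s, 5);
        double x1 = 0.0, x2 = 0.0, y1 = 0.0, y2 = 0.0;
        for (int i = 0; i < N; ++i) {
          const double xi = buf[i];
          const double yi = b0 * xi + b1 * x1 + b2 * x2 - a1 * y1 - a2 * y2;
          x2 = x1; x1 = xi;
          y2 = y1; y1 = yi;
          buf[i] = yi;
        }
      }
      std::reverse(buf.begin(), buf.end());
    }
    for (int i = 0; i < n; ++i) out(i, j) = buf[padlen + i];
  }
  return out;
}
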