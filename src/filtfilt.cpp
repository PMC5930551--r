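// Zero-phase IIR filtering of every column of a matrix: forward filter with
// 2*max(na,nb) zeros appended, then reverse filtering, then truncation --
// the classic forward-backward scheme, applied column-wise in one pass.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

// Direct-form II transposed difference equation, zero initial conditions.
void iir(const std::vector<double>& b, const std::vector<double>& a,
         const double* x, double* y, int n) {
  int nb = b.size(), na = a.size();
  int ns = std::max(na, nb);
  std::vector<double> w(ns, 0.0);
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = b[0] * xi + w[0];
    for (int k = 1; k < ns; ++k) {
      double bk = (k < nb) ? b[k] : 0.0;
      double ak = (k < na) ? a[k] : 0.0;
      w[k - 1] = bk * xi - ak * yi + (k < ns - 1 ? w[k] : 0.0);
    }
    y[i] = yi;
  }
}

} // namespace

// [[Rcpp::export(name = ".filtfilt_cpp")]]
NumericMatrix filtfilt_cpp(NumericVector b, NumericVector a,
                           NumericMatrix x) {
  std::vector<double> bb(b.begin(), b.end()), aa(a.begin(), a.end());
  double a0 = aa[0];
  for (auto& v : bb) v /= a0;
  for (auto& v : aa) v /= a0;
  int n = x.nrow(), m = x.ncol();
  int pad = 2 * std::max(aa.size(), bb.size());
  int np = n + pad;
  std::vector<double> buf(np), fwd(np), bwd(np);
  NumericMatrix out(n, m);
  for (int j = 0; j < m; ++j) {
    for (int i = 0; i < n; ++i) buf[i] = x(i, j);
    std::fill(buf.begin() + n, buf.end(), 0.0);
    iir(bb, aa, buf.data(), fwd.data(), np);
    std::reverse(fwd.begin(), fwd.end());
    iir(bb, aa, fwd.data(), bwd.data(), np);
    std::reverse(bwd.begin(), bwd.end());
    for (int i = 0; i < n; ++i) out(i, j) = bwd[i];
  }
  return out;
}
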