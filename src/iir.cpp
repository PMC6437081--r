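#include <Rcpp.h>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// One causal pass of a direct form II transposed IIR filter over [x, x+n),
// writing into y (may alias x). Coefficients must be normalised (a[0] == 1)
// and zero-padded to common length m >= 2.
static void df2t_pass(const double* b, const double* a, int m,
                      const double* x, double* y, int n) {
  std::vector<double> z(m - 1, 0.0);
  const int mz = m - 1;
  for (int i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = b[0] * xi + z[0];
    for (int j = 1; j < mz; ++j) z[j - 1] = b[j] * xi + z[j] - a[j] * yi;
    z[mz - 1] = b[mz] * xi - a[mz] * yi;
    y[i] = yi;
  }
}

static void pack_coefs(NumericVector b, NumericVector a,
                       std::vector<double>& bb, std::vector<double>& aa) {
  const int m = std::max((int)b.size(), std::max((int)a.size(), 2));
  bb.assign(m, 0.0);
  aa.assign(m, 0.0);
  const double a0 = a[0];
  for (int i = 0; i < b.size(); ++i) bb[i] = b[i] / a0;
  for (int i = 0; i < a.size(); ++i) aa[i] = a[i] / a0;
}

// [[Rcpp::export]]
NumericVector iir_filter_cpp(NumericVector b, NumericVector a, NumericVector x) {
  std::vector<double> bb, aa;
  pack_coefs(b, a, bb, aa);
  const int n = x.size();
  NumericVector y(n);
  df2t_pass(bb.data(), aa.data(), (int)bb.size(), x.begin(), y.begin(), n);
  return y;
}

// Zero-phase (forward-backward) filtering with odd point-symmetric
// reflection padding of `pad` samples at both ends.
// [[Rcpp::export]]
NumericVector zero_phase_cpp(NumericVector b, NumericVector a, NumericVector x,
                             int pad) {
  std::vector<double> bb, aa;
  pack_coefs(b, a, bb, aa);
  const int m = (int)bb.size();
  const int n = x.size();
  if (pad > n - 1) pad = n - 1;
  if (pad < 0) pad = 0;
  const int nt = n + 2 * pad;
  std::vector<double> w(nt);
  for (int i = 0; i < pad; ++i) w[i] = 2.0 * x[0] - x[pad - i];
  std::copy(x.begin(), x.end(), w.begin() + pad);
  for (int i = 0; i < pad; ++i) w[pad + n + i] = 2.0 * x[n - 1] - x[n - 2 - i];

  df2t_pass(bb.data(), aa.data(), m, w.data(), w.data(), nt);
  std::reverse(w.begin(), w.end());
  df2t_pass(bb.data(), aa.data(), m, w.data(), w.data(), nt);
  std::reverse(w.begin(), w.end());

  NumericVector y(n);
  std::copy(w.begin() + pad, w.begin() + pad + n, y.begin());
  return y;
}
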