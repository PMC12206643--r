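#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter, one pass, in place on a working buffer.
static void iir_pass(const std::vector<double>& b, const std::vector<double>& a,
                     std::vector<double>& x) {
  const int nb = (int)b.size(), na = (int)a.size();
  const int nz = std::max(nb, na) - 1;
  std::vector<double> z(nz, 0.0);
  const int n = (int)x.size();
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = b[0] * xi + z[0];
    for (int j = 1; j < nz; ++j) {
      double bj = (j < nb) ? b[j] : 0.0;
      double aj = (j < na) ? a[j] : 0.0;
      z[j - 1] = bj * xi + z[j] - aj * yi;
    }
    double bl = (nz < nb) ? b[nz] : 0.0;
    double al = (nz < na) ? a[nz] : 0.0;
    z[nz - 1] = bl * xi - al * yi;
    x[i] = yi;
  }
}

// Zero-phase (forward-backward) filtering along columns of X, with odd
// reflection padding of `padlen` samples at each end to suppress edge
// transients. Coefficients must be normalized so a[0] == 1.
// [[Rcpp::export(name = ".filtfilt_mat")]]
NumericMatrix filtfilt_mat(NumericVector b, NumericVector a, NumericMatrix X,
                           int padlen) {
  const int n = X.nrow(), nc = X.ncol();
  if (n < 2) stop("signal too short to filter");
  if (padlen >= n) padlen = n - 1;
  if (padlen < 0) padlen = 0;
  std::vector<double> bb(b.begin(), b.end()), aa(a.begin(), a.end());
  if (aa.empty() || aa[0] == 0.0) stop("a[1] must be non-zero");
  for (size_t j = 0; j < bb.size(); ++j) bb[j] /= aa[0];
  for (size_t j = 0; j < aa.size(); ++j) aa[j] /= aa[0];

  NumericMatrix out(n, nc);
  const int m = n + 2 * padlen;
  std::vector<double> w((size_t)m);
  for (int c = 0; c < nc; ++c) {
    // odd reflection: 2*x[0] - x[k] at the head, 2*x[n-1] - x[n-1-k] at the tail
    for (int k = 0; k < padlen; ++k)
      w[k] = 2.0 * X(0, c) - X(padlen - k, c);
    for (int i = 0; i < n; ++i) w[padlen + i] = X(i, c);
    for (int k = 0; k < padlen; ++k)
      w[padlen + n + k] = 2.0 * X(n - 1, c) - X(n - 2 - k, c);

    iir_pass(bb, aa, w);
    std::reverse(w.begin(), w.end());
    iir_pass(bb, aa, w);
    std::reverse(w.begin(), w.end());
    for (int i = 0; i < n; ++i) out(i, c) = w[padlen + i];
  }
  return out;
}
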