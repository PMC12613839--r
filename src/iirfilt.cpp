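#include <Rcpp.h>
using namespace Rcpp;

// One-pass IIR filter, direct form II transposed. Coefficients a, b as from
// signal::butter (a[0] assumed 1 after normalisation).
static void iir_inplace(const std::vector<double>& b,
                        const std::vector<double>& a,
                        double* x, int n, bool reverse) {
  int nb = b.size(), na = a.size();
  int nz = std::max(nb, na) - 1;
  std::vector<double> z(nz, 0.0);
  for (int k = 0; k < n; ++k) {
    int i = reverse ? n - 1 - k : k;
    double xi = x[i];
    double yi = b[0] * xi + z[0];
    for (int j = 1; j <= nz; ++j) {
      double bj = j < nb ? b[j] : 0.0;
      double aj = j < na ? a[j] : 0.0;
      double znext = (j < nz) ? z[j] : 0.0;
      z[j - 1] = bj * xi + znext - aj * yi;
    }
    x[i] = yi;
  }
}

// Zero-phase (forward-backward) IIR filtering of each matrix row, with
// odd-symmetric reflect padding of `pad` samples on both ends to suppress
// edge transients.
// [[Rcpp::export]]
NumericMatrix iir_filtfilt_rows(NumericVector b, NumericVector a,
                                NumericMatrix x, int pad = 0) {
  std::vector<double> bv = as<std::vector<double>>(b);
  std::vector<double> av = as<std::vector<double>>(a);
  if (av.empty() || av[0] == 0.0) stop("a[1] must be non-zero");
  for (size_t j = 0; j < bv.size(); ++j) bv[j] /= av[0];
  for (size_t j = 0; j < av.size(); ++j) av[j] /= av[0];
  int n = x.ncol();
  if (pad < 0 || pad > n - 1) stop("invalid pad length");
  NumericMatrix out(x.nrow(), n);
  std::vector<double> buf(n + 2 * pad);
  for (int i = 0; i < x.nrow(); ++i) {
    for (int k = 0; k < pad; ++k) buf[k] = 2.0 * x(i, 0) - x(i, pad - k);
    for (int k = 0; k < n; ++k) buf[pad + k] = x(i, k);
    for (int k = 0; k < pad; ++k) {
      buf[pad + n + k] = 2.0 * x(i, n - 1) - x(i, n - 2 - k);
    }
    iir_inplace(bv, av, buf.data(), buf.size(), false);
    iir_inplace(bv, av, buf.data(), buf.size(), true);
    for (int k = 0; k < n; ++k) out(i, k) = buf[pad + k];
  }
  return out;
}
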