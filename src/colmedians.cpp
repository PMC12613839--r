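#include <Rcpp.h>
using namespace Rcpp;

// Per-sample median across channels (columns of a channels x samples matrix
// seen column-wise). Columns are short (<= 60 channels), so nth_element per
// column beats a full sort. Even counts: mean of the two central values.
// [[Rcpp::export]]
NumericVector col_medians(NumericMatrix x) {
  int nr = x.nrow(), nc = x.ncol();
  NumericVector out(nc);
  std::vector<double> buf(nr);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) buf[i] = x(i, j);
    int h = nr / 2;
    std::nth_element(buf.begin(), buf.begin() + h, buf.end());
    double m = buf[h];
    if (nr % 2 == 0) {
      double lo = *std::max_element(buf.begin(), buf.begin() + h);
      m = (m + lo) / 2.0;
    }
    out[j] = m;
  }
  return out;
}
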