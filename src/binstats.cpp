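#include <Rcpp.h>
using namespace Rcpp;

// Grouped count and sum over dense integer bins 1..nb, one pass.
// [[Rcpp::export]]
List binStats_cpp(NumericVector z, IntegerVector bin, int nb) {
  NumericVector sums(nb);
  IntegerVector cnts(nb);
  const R_xlen_t n = z.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    int b = bin[i] - 1;
    if (b < 0 || b >= nb) continue;
    sums[b] += z[i];
    cnts[b] += 1;
  }
  return List::create(_["count"] = cnts, _["sum"] = sums);
}
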