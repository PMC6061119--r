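#include <Rcpp.h>
using namespace Rcpp;

// Pair counts for Harrell's concordance over censored data.
// A pair is comparable when the member with the strictly shorter follow-up
// time had the event; tied follow-up times are never comparable. Within a
// comparable pair, concordance means the shorter-time member has the higher
// predictor; predictor ties count half.
// [[Rcpp::export(name = ".concordance_counts")]]
NumericVector concordance_counts(NumericVector pred, NumericVector time,
                                 LogicalVector event) {
  const R_xlen_t n = pred.size();
  double comparable = 0.0, concordant = 0.0, tied = 0.0;
  for (R_xlen_t i = 0; i < n; ++i) {
    for (R_xlen_t j = i + 1; j < n; ++j) {
      R_xlen_t s, l; // shorter, longer follow-up
      if (time[i] < time[j]) { s = i; l = j; }
      else if (time[j] < time[i]) { s = j; l = i; }
      else continue;
      if (!event[s]) continue;
      comparable += 1.0;
      if (pred[s] > pred[l]) concordant += 1.0;
      else if (pred[s] == pred[l]) tied += 1.0;
    }
  }
  return NumericVector::create(_["comparable"] = comparable,
                               _["concordant"] = concordant,
                               _["tied"] = tied);
}
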