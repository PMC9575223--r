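// AdamW update for one parameter tensor: returns updated (p, m, v) in a
// single pass without R-level intermediates.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".adamLeafCpp")]]
List adamLeafCpp(NumericVector p, NumericVector g, NumericVector m,
                 NumericVector v, int t, double lr, double wd,
                 double b1, double b2, double eps) {
  const R_xlen_t n = p.size();
  NumericVector pOut(n), mOut(n), vOut(n);
  const double bc1 = 1.0 - std::pow(b1, (double)t);
  const double bc2 = 1.0 - std::pow(b2, (double)t);
  for (R_xlen_t i = 0; i < n; ++i) {
    const double mi = b1 * m[i] + (1.0 - b1) * g[i];
    const double vi = b2 * v[i] + (1.0 - b2) * g[i] * g[i];
    mOut[i] = mi;
    vOut[i] = vi;
    pOut[i] = p[i] - lr * ((mi / bc1) / (std::sqrt(vi / bc2) + eps))
              - lr * wd * p[i];
  }
  pOut.attr("dim") = p.attr("dim");
  return List::create(_["p"] = pOut, _["m"] = mOut, _["v"] = vOut);
}
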