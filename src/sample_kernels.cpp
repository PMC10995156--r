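#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Per-block clipped-sample counts: block b spans sample indices
// [bounds[b], bounds[b + 1]) (0-based). A sample is clipped when any axis
// reaches thr in absolute value.
// [[Rcpp::export(name = ".clip_block_counts_cpp")]]
List clip_block_counts_cpp(NumericVector x, NumericVector y, NumericVector z,
                           double thr, NumericVector bounds) {
  const int nb = bounds.size() - 1;
  IntegerVector nclip(nb), ntot(nb);
  for (int b = 0; b < nb; ++b) {
    const R_xlen_t lo = (R_xlen_t)bounds[b], hi = (R_xlen_t)bounds[b + 1];
    int c = 0;
    for (R_xlen_t i = lo; i < hi; ++i)
      if (std::fabs(x[i]) >= thr || std::fabs(y[i]) >= thr ||
          std::fabs(z[i]) >= thr) ++c;
    nclip[b] = c;
    ntot[b] = (int)(hi - lo);
  }
  return List::create(_["n_clipped"] = nclip, _["n_total"] = ntot);
}
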