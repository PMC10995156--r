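#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Fused sample-level synthesis: expands the per-second gravity matrix G
// (ns x 3) and dynamic SD s_tot (ns) to `rate` samples per second, adds
// N(0, s_tot) noise per axis (R's RNG, so seeded runs reproduce), applies
// the per-axis distortion gain * (v + offset), and quantizes with clipping
// to [-half, half] counts. Draw order: per sample, axes x, y, z.
// [[Rcpp::export(name = ".synth_quantize_cpp")]]
List synth_quantize_cpp(NumericMatrix G, NumericVector s_tot, int rate,
                        NumericVector gain, NumericVector offset,
                        double step, int half) {
  const R_xlen_t ns = G.nrow();
  const R_xlen_t n = ns * (R_xlen_t)rate;
  NumericMatrix q(n, 3);
  IntegerVector cx(n), cy(n), cz(n);
  R_xlen_t nclip = 0;
  R_xlen_t i = 0;
  for (R_xlen_t s = 0; s < ns; ++s) {
    const double sd = s_tot[s];
    const double gx = G(s, 0), gy = G(s, 1), gz = G(s, 2);
    for (int r = 0; r < rate; ++r, ++i) {
      double vx = gx, vy = gy, vz = gz;
      if (sd > 0) {
        vx += norm_rand() * sd;
        vy += norm_rand() * sd;
        vz += norm_rand() * sd;
      }
      vx = gain[0] * (vx + offset[0]);
      vy = gain[1] * (vy + offset[1]);
      vz = gain[2] * (vz + offset[2]);
      long ix = std::lround(vx / step);
      long iy = std::lround(vy / step);
      long iz = std::lround(vz / step);
      if (std::labs(ix) > half || std::labs(iy) > half ||
          std::labs(iz) > half) ++nclip;
      if (ix > half) ix = half; else if (ix < -half) ix = -half;
      if (iy > half) iy = half; else if (iy < -half) iy = -half;
      if (iz > half) iz = half; else if (iz < -half) iz = -half;
      cx[i] = (int)ix; cy[i] = (int)iy; cz[i] = (int)iz;
      q(i, 0) = ix * step; q(i, 1) = iy * step; q(i, 2) = iz * step;
    }
  }
  return List::create(_["data"] = q,
                      _["cx"] = cx, _["cy"] = cy, _["cz"] = cz,
                      _["n_clipped"] = (double)nclip);
}

// integer ADC counts -> n x 3 matrix in g, one pass
// [[Rcpp::export(name = ".counts_to_g_cpp")]]
NumericMatrix counts_to_g_cpp(IntegerVector cx, IntegerVector cy,
                              IntegerVector cz, double step) {
  const R_xlen_t n = cx.size();
  NumericMatrix out(n, 3);
  for (R_xlen_t i = 0; i < n; ++i) {
    out(i, 0) = cx[i] * step;
    out(i, 1) = cy[i] * step;
    out(i, 2) = cz[i] * step;
  }
  return out;
}
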