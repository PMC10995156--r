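#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// One pass over a triaxial recording, summarising disjoint epochs of k
// samples. Everything downstream (non-wear windows, clipping score, posture
// angles) is assembled from these per-epoch statistics, so this is the only
// loop that touches every sample.
//
// Returns per epoch:
//   enmo      mean over samples of max(||a|| - 1, 0)          [g]
//   enmo_raw  mean over samples of (||a|| - 1), untruncated   [g]
//   mad       mean over samples of |(||a||) - epoch mean norm| [g]
//   mean_*    per-axis mean
//   sd_*      per-axis sample SD (denominator n - 1)
//   min_*/max_* per-axis extrema
//   med_*     per-axis median (the 5-s posture-angle input)
//   n_clip    samples with |a| >= clip_abs on any axis
// The per-axis affine map gain * a + offset is applied on the fly, so a
// calibration correction costs nothing extra and the raw matrix is never
// copied.
// [[Rcpp::export(name = ".epoch_stats_cpp")]]
List epoch_stats_cpp(NumericVector x, NumericVector y, NumericVector z,
                     int k, double clip_abs, bool medians,
                     NumericVector gain, NumericVector offset) {
  const R_xlen_t n = x.size();
  if (y.size() != n || z.size() != n)
    stop("axis vectors must have equal length");
  if (k < 1) stop("epoch must contain at least one sample");
  const R_xlen_t ne = n / k;

  NumericVector enmo(ne), enmo_raw(ne), mad(ne);
  NumericVector mx(ne), my(ne), mz(ne), sx(ne), sy(ne), sz(ne);
  NumericVector lox(ne), loy(ne), loz(ne), hix(ne), hiy(ne), hiz(ne);
  NumericVector medx(ne), medy(ne), medz(ne);
  IntegerVector nclip(ne);

  std::vector<double> r(k), buf(k);

  for (R_xlen_t e = 0; e < ne; ++e) {
    const R_xlen_t off = e * (R_xlen_t)k;
    double sumx = 0, sumy = 0, sumz = 0, sum2x = 0, sum2y = 0, sum2z = 0;
    double minx = x[off], maxx = x[off], miny = y[off], maxy = y[off];
    double minz = z[off], maxz = z[off];
    double sumr = 0, sumpos = 0;
    int clip = 0;

    for (int i = 0; i < k; ++i) {
      const double xi = gain[0] * x[off + i] + offset[0];
      const double yi = gain[1] * y[off + i] + offset[1];
      const double zi = gain[2] * z[off + i] + offset[2];
      sumx += xi; sumy += yi; sumz += zi;
      sum2x += xi * xi; sum2y += yi * yi; sum2z += zi * zi;
      if (xi < minx) minx = xi; if (xi > maxx) maxx = xi;
      if (yi < miny) miny = yi; if (yi > maxy) maxy = yi;
      if (zi < minz) minz = zi; if (zi > maxz) maxz = zi;
      const double ri = std::sqrt(xi * xi + yi * yi + zi * zi);
      r[i] = ri;
      sumr += ri;
      const double d = ri - 1.0;
      if (d > 0) sumpos += d;
      if (std::fabs(xi) >= clip_abs || std::fabs(yi) >= clip_abs ||
          std::fabs(zi) >= clip_abs) ++clip;
    }

    const double rbar = sumr / k;
    double sumabs = 0;
    for (int i = 0; i < k; ++i) sumabs += std::fabs(r[i] - rbar);

    enmo[e] = sumpos / k;
    enmo_raw[e] = rbar - 1.0;
    mad[e] = sumabs / k;
    mx[e] = sumx / k; my[e] = sumy / k; mz[e] = sumz / k;
    if (k > 1) {
      // guard tiny negative values from cancellation
      sx[e] = std::sqrt(std::max(0.0, (sum2x - sumx * sumx / k) / (k - 1)));
      sy[e] = std::sqrt(std::max(0.0, (sum2y - sumy * sumy / k) / (k - 1)));
      sz[e] = std::sqrt(std::max(0.0, (sum2z - sumz * sumz / k) / (k - 1)));
    } else {
      sx[e] = sy[e] = sz[e] = NA_REAL;
    }
    lox[e] = minx; hix[e] = maxx; loy[e] = miny; hiy[e] = maxy;
    loz[e] = minz; hiz[e] = maxz;
    nclip[e] = clip;

    if (!medians) continue;
    const int h = k / 2;
    for (int a = 0; a < 3; ++a) {
      const NumericVector &v = (a == 0) ? x : (a == 1) ? y : z;
      for (int i = 0; i < k; ++i) buf[i] = gain[a] * v[off + i] + offset[a];
      std::nth_element(buf.begin(), buf.begin() + h, buf.end());
      double med = buf[h];
      if (k % 2 == 0) {
        const double lower = *std::max_element(buf.begin(), buf.begin() + h);
        med = (med + lower) / 2.0;
      }
      if (a == 0) medx[e] = med; else if (a == 1) medy[e] = med;
      else medz[e] = med;
    }
  }

  return List::create(
    _["enmo"] = enmo, _["enmo_raw"] = enmo_raw, _["mad"] = mad,
    _["mean_x"] = mx, _["mean_y"] = my, _["mean_z"] = mz,
    _["sd_x"] = sx, _["sd_y"] = sy, _["sd_z"] = sz,
    _["min_x"] = lox, _["min_y"] = loy, _["min_z"] = loz,
    _["max_x"] = hix, _["max_y"] = hiy, _["max_z"] = hiz,
    _["med_x"] = medx, _["med_y"] = medy, _["med_z"] = medz,
    _["n_clip"] = nclip);
}
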