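#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Global 3D gamma index between a reference and an evaluated dose on the
// same grid. The evaluated distribution is probed by trilinear
// interpolation on a subvoxel offset lattice (step = spacing/step_div)
// out to radius_mm; offsets are visited in order of increasing distance
// and the search stops once the distance term alone exceeds the current
// best gamma, so the result equals the minimum over the whole search
// ball. Reference voxels below threshold_abs are returned as NA.
// [[Rcpp::export]]
NumericVector cpp_gamma_map(NumericVector ref, NumericVector eval,
                            IntegerVector dim, NumericVector spacing,
                            double dose_tol, double dta,
                            double threshold_abs, double radius_mm,
                            int step_div) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  NumericVector out(n, NA_REAL);

  struct Off {
    double dist2;       // squared physical distance (mm^2)
    double f1, f2, f3;  // fractional index offsets
  };
  std::vector<Off> offs;
  const double s1 = spacing[0] / step_div, s2 = spacing[1] / step_div,
               s3 = spacing[2] / step_div;
  const int m1 = (int)std::floor(radius_mm / s1);
  const int m2 = (int)std::floor(radius_mm / s2);
  const int m3 = (int)std::floor(radius_mm / s3);
  const double r2 = radius_mm * radius_mm;
  for (int a = -m1; a <= m1; ++a)
    for (int b = -m2; b <= m2; ++b)
      for (int c = -m3; c <= m3; ++c) {
        double dx = a * s1, dy = b * s2, dz = c * s3;
        double dd = dx * dx + dy * dy + dz * dz;
        if (dd > r2) continue;
        offs.push_back({dd, (double)a / step_div, (double)b / step_div,
                        (double)c / step_div});
      }
  std::sort(offs.begin(), offs.end(),
            [](const Off &a, const Off &b) { return a.dist2 < b.dist2; });

  const double *ev = eval.begin();
  const double dta2 = dta * dta;

  for (R_xlen_t v = 0; v < n; ++v) {
    double dr = ref[v];
    if (dr < threshold_abs) continue;
    int i1 = (int)(v % d1);
    int i2 = (int)((v / d1) % d2);
    int i3 = (int)(v / ((R_xlen_t)d1 * d2));
    double best2 = R_PosInf;
    for (size_t k = 0; k < offs.size(); ++k) {
      double dist_term = offs[k].dist2 / dta2;
      if (dist_term >= best2) break;  // sorted: no farther offset can win
      double p1 = i1 + offs[k].f1, p2 = i2 + offs[k].f2, p3 = i3 + offs[k].f3;
      if (p1 < 0 || p2 < 0 || p3 < 0 || p1 > d1 - 1 || p2 > d2 - 1 ||
          p3 > d3 - 1)
        continue;  // no evaluated dose defined outside the grid
      int j1 = (int)std::floor(p1), j2 = (int)std::floor(p2),
          j3 = (int)std::floor(p3);
      if (j1 == d1 - 1 && d1 > 1) j1--;
      if (j2 == d2 - 1 && d2 > 1) j2--;
      if (j3 == d3 - 1 && d3 > 1) j3--;
      double f1 = p1 - j1, f2 = p2 - j2, f3 = p3 - j3;
      const int q2 = d1, q3 = d1 * d2;
      int k1 = (d1 == 1) ? j1 : j1 + 1;
      int k2 = (d2 == 1) ? j2 : j2 + 1;
      int k3 = (d3 == 1) ? j3 : j3 + 1;
      double c00 = ev[j1 + j2 * q2 + j3 * q3] * (1 - f1) +
                   ev[k1 + j2 * q2 + j3 * q3] * f1;
      double c10 = ev[j1 + k2 * q2 + j3 * q3] * (1 - f1) +
                   ev[k1 + k2 * q2 + j3 * q3] * f1;
      double c01 = ev[j1 + j2 * q2 + k3 * q3] * (1 - f1) +
                   ev[k1 + j2 * q2 + k3 * q3] * f1;
      double c11 = ev[j1 + k2 * q2 + k3 * q3] * (1 - f1) +
                   ev[k1 + k2 * q2 + k3 * q3] * f1;
      double de = (c00 * (1 - f2) + c10 * f2) * (1 - f3) +
                  (c01 * (1 - f2) + c11 * f2) * f3;
      double diff = (de - dr) / dose_tol;
      double g2 = dist_term + diff * diff;
      if (g2 < best2) best2 = g2;
    }
    out[v] = std::sqrt(best2);
  }
  return out;
}
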