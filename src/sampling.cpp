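#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Fractional voxel coordinates are snapped to the nearest integer when the
// residual is below this tolerance, so that sampling a volume at its own
// grid points reproduces the stored values bit-for-bit.
static const double SNAP_TOL = 1e-7;

static inline double snap(double p) {
  double r = std::round(p);
  return (std::fabs(p - r) < SNAP_TOL) ? r : p;
}

// Trilinear sampling of a 3D array at 0-based fractional voxel indices.
// Points outside the voxel-centre hull [0, d-1] return 0.
// [[Rcpp::export]]
NumericVector cpp_sample_trilinear(NumericVector vals, IntegerVector dim,
                                   NumericMatrix pts) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const R_xlen_t n = pts.nrow();
  NumericVector out(n);
  const double *v = vals.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    double p1 = snap(pts(i, 0)), p2 = snap(pts(i, 1)), p3 = snap(pts(i, 2));
    if (p1 < 0 || p2 < 0 || p3 < 0 ||
        p1 > d1 - 1 || p2 > d2 - 1 || p3 > d3 - 1) {
      out[i] = 0.0;
      continue;
    }
    int i1 = (int)std::floor(p1), i2 = (int)std::floor(p2),
        i3 = (int)std::floor(p3);
    if (i1 == d1 - 1) i1--;
    if (i2 == d2 - 1) i2--;
    if (i3 == d3 - 1) i3--;
    if (d1 == 1) i1 = 0;
    if (d2 == 1) i2 = 0;
    if (d3 == 1) i3 = 0;
    double f1 = p1 - i1, f2 = p2 - i2, f3 = p3 - i3;
    if (d1 == 1) f1 = 0;
    if (d2 == 1) f2 = 0;
    if (d3 == 1) f3 = 0;
    const int s2 = d1, s3 = d1 * d2;
    const int j1 = (d1 == 1) ? i1 : i1 + 1;
    const int j2 = (d2 == 1) ? i2 : i2 + 1;
    const int j3 = (d3 == 1) ? i3 : i3 + 1;
    double c000 = v[i1 + i2 * s2 + i3 * s3];
    double c100 = v[j1 + i2 * s2 + i3 * s3];
    double c010 = v[i1 + j2 * s2 + i3 * s3];
    double c110 = v[j1 + j2 * s2 + i3 * s3];
    double c001 = v[i1 + i2 * s2 + j3 * s3];
    double c101 = v[j1 + i2 * s2 + j3 * s3];
    double c011 = v[i1 + j2 * s2 + j3 * s3];
    double c111 = v[j1 + j2 * s2 + j3 * s3];
    double c00 = c000 * (1 - f1) + c100 * f1;
    double c10 = c010 * (1 - f1) + c110 * f1;
    double c01 = c001 * (1 - f1) + c101 * f1;
    double c11 = c011 * (1 - f1) + c111 * f1;
    double c0 = c00 * (1 - f2) + c10 * f2;
    double c1 = c01 * (1 - f2) + c11 * f2;
    out[i] = c0 * (1 - f3) + c1 * f3;
  }
  return out;
}

// Nearest-neighbour sampling; points rounding outside the array return 0.
// [[Rcpp::export]]
NumericVector cpp_sample_nearest(NumericVector vals, IntegerVector dim,
                                 NumericMatrix pts) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const R_xlen_t n = pts.nrow();
  NumericVector out(n);
  const double *v = vals.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    int i1 = (int)std::round(pts(i, 0));
    int i2 = (int)std::round(pts(i, 1));
    int i3 = (int)std::round(pts(i, 2));
    if (i1 < 0 || i2 < 0 || i3 < 0 || i1 >= d1 || i2 >= d2 || i3 >= d3) {
      out[i] = 0.0;
    } else {
      out[i] = v[i1 + i2 * d1 + i3 * d1 * d2];
    }
  }
  return out;
}
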