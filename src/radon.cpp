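// 3D Radon transform of plane integrals on a regular voxel grid.
//
// Forward: each voxel's mass (value * voxel volume * gradient) is deposited
// onto the field axis at b = g * (r . d) with linear interpolation between the
// two nearest bins, then divided by the bin width, so that
// sum(profile) * db == sum(vol) * voxel_volume * gradient for objects fully
// inside the field of view.  Backward is the exact matrix transpose of the
// forward map (same weights, same skip rules), which is what the FISTA
// gradient and the adjoint dot-product test require.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix radon_project_cpp(NumericVector vol, IntegerVector dim,
                                NumericVector spacing, NumericVector origin,
                                NumericMatrix dirs, double b0, double db,
                                int nfield, double gradient) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int ndir = dirs.nrow();
  const double g = gradient / 1000.0;  // mT/m over mm coordinates -> mT
  const double vv = spacing[0] * spacing[1] * spacing[2];
  const double scale = vv * gradient / db;
  NumericMatrix prof(ndir, nfield);
  long overflow = 0;
  const double *v = vol.begin();

  for (int d = 0; d < ndir; ++d) {
    const double dx = dirs(d, 0), dy = dirs(d, 1), dz = dirs(d, 2);
    const double sx = g * spacing[0] * dx;
    const double sy = g * spacing[1] * dy;
    const double sz = g * spacing[2] * dz;
    const double u00 = (g * (origin[0] * dx + origin[1] * dy + origin[2] * dz)
                        - b0) / db;
    const double ux = sx / db, uy = sy / db, uz = sz / db;
    double *pr = &prof(d, 0);
    long idx = 0;
    for (int k = 0; k < nz; ++k) {
      const double uk = u00 + k * uz;
      for (int j = 0; j < ny; ++j) {
        double u = uk + j * uy;
        for (int i = 0; i < nx; ++i, ++idx, u += ux) {
          const double val = v[idx];
          if (val == 0.0) continue;
          if (u < 0.0 || u > nfield - 1.0) { ++overflow; continue; }
          const int i0 = (int)u;
          const double w1 = u - i0;
          const double m = val * scale;
          // prof is ndir x nfield, column-major: stride ndir between bins
          pr[(long)i0 * ndir] += m * (1.0 - w1);
          if (i0 + 1 < nfield) pr[(long)(i0 + 1) * ndir] += m * w1;
        }
      }
    }
  }
  prof.attr("overflow") = (double)overflow;
  return prof;
}

// [[Rcpp::export]]
NumericVector radon_backproject_cpp(NumericMatrix prof, IntegerVector dim,
                                    NumericVector spacing, NumericVector origin,
                                    NumericMatrix dirs, double b0, double db,
                                    int nfield, double gradient) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int ndir = dirs.nrow();
  const double g = gradient / 1000.0;
  const double vv = spacing[0] * spacing[1] * spacing[2];
  const double scale = vv * gradient / db;
  NumericVector vol((long)nx * ny * nz);
  double *v = vol.begin();

  for (int d = 0; d < ndir; ++d) {
    const double dx = dirs(d, 0), dy = dirs(d, 1), dz = dirs(d, 2);
    const double u00 = (g * (origin[0] * dx + origin[1] * dy + origin[2] * dz)
                        - b0) / db;
    const double ux = g * spacing[0] * dx / db;
    const double uy = g * spacing[1] * dy / db;
    const double uz = g * spacing[2] * dz / db;
    const double *pr = &prof(d, 0);
    long idx = 0;
    for (int k = 0; k < nz; ++k) {
      const double uk = u00 + k * uz;
      for (int j = 0; j < ny; ++j) {
        double u = uk + j * uy;
        for (int i = 0; i < nx; ++i, ++idx, u += ux) {
          if (u < 0.0 || u > nfield - 1.0) continue;
          const int i0 = (int)u;
          const double w1 = u - i0;
          double val = pr[(long)i0 * ndir] * (1.0 - w1);
          if (i0 + 1 < nfield) val += pr[(long)(i0 + 1) * ndir] * w1;
          v[idx] += val * scale;
        }
      }
    }
  }
  return vol;
}
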