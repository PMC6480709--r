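#include <Rcpp.h>
using namespace Rcpp;

// Trilinear interpolation of a 3D grid at a point given in cm relative to
// the first voxel center. Returns NA outside the grid (no extrapolation).
static inline double trilinear(const NumericVector &v, const int *dims,
                               const double *spacing, double x, double y,
                               double z, bool &ok) {
  double fx = x / spacing[0], fy = y / spacing[1], fz = z / spacing[2];
  if (fx < 0 || fy < 0 || fz < 0 || fx > dims[0] - 1 || fy > dims[1] - 1 ||
      fz > dims[2] - 1) {
    ok = false;
    return 0.0;
  }
  ok = true;
  int i0 = (int)std::floor(fx), j0 = (int)std::floor(fy),
      k0 = (int)std::floor(fz);
  if (i0 == dims[0] - 1) i0--;
  if (j0 == dims[1] - 1) j0--;
  if (k0 == dims[2] - 1) k0--;
  double tx = fx - i0, ty = fy - j0, tz = fz - k0;
  const int nx = dims[0], nxy = dims[0] * dims[1];
  const double *p = REAL(v);
  int base = i0 + j0 * nx + k0 * nxy;
  double c000 = p[base], c100 = p[base + 1];
  double c010 = p[base + nx], c110 = p[base + nx + 1];
  double c001 = p[base + nxy], c101 = p[base + nxy + 1];
  double c011 = p[base + nx + nxy], c111 = p[base + nx + nxy + 1];
  double c00 = c000 * (1 - tx) + c100 * tx;
  double c10 = c010 * (1 - tx) + c110 * tx;
  double c01 = c001 * (1 - tx) + c101 * tx;
  double c11 = c011 * (1 - tx) + c111 * tx;
  double c0 = c00 * (1 - ty) + c10 * ty;
  double c1 = c01 * (1 - ty) + c11 * ty;
  return c0 * (1 - tz) + c1 * tz;
}

// Minimum squared gamma per selected reference voxel. The search lattice
// (`offsets`, cm, with squared distances `dist2` sorted ascending) is shared
// by all voxels; the ascending distance order permits early termination as
// soon as the pure distance term exceeds the best squared gamma found.
// [[Rcpp::export]]
NumericVector gamma_min_cpp(NumericVector ref, NumericVector ev,
                            IntegerVector idx, IntegerVector dims,
                            NumericVector spacing, NumericMatrix offsets,
                            NumericVector dist2, double dose_tol,
                            double dta_cm) {
  const int n = idx.size(), m = offsets.nrow();
  const int nx = dims[0], nxy = dims[0] * dims[1];
  int dims_[3] = {dims[0], dims[1], dims[2]};
  double spacing_[3] = {spacing[0], spacing[1], spacing[2]};
  const double dta2 = dta_cm * dta_cm;
  NumericVector out(n);
  const double *offx = &offsets(0, 0);
  const double *offy = &offsets(0, 1);
  const double *offz = &offsets(0, 2);
  for (int q = 0; q < n; q++) {
    const int lin = idx[q];
    const int i = lin % nx;
    const int j = (lin / nx) % dims_[1];
    const int k = lin / nxy;
    const double x0 = i * spacing_[0], y0 = j * spacing_[1],
                 z0 = k * spacing_[2];
    const double dref = ref[lin];
    double best = R_PosInf;
    for (int t = 0; t < m; t++) {
      const double dterm = dist2[t] / dta2;
      if (dterm >= best) break;  // offsets sorted: no further improvement
      bool ok;
      const double de = trilinear(ev, dims_, spacing_, x0 + offx[t],
                                  y0 + offy[t], z0 + offz[t], ok);
      if (!ok) continue;
      const double dd = (dref - de) / dose_tol;
      const double g2 = dd * dd + dterm;
      if (g2 < best) best = g2;
    }
    out[q] = best;
  }
  return out;
}
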