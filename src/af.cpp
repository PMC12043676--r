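// Activating function as the largest-magnitude eigenvalue of the Hessian of
// the electric potential, per voxel.  Second differences are central where
// both neighbours are conductive; at domain edges (or against air) the
// stencil is shifted one voxel inward, and mixed partials fall back to zero
// when a corner is unavailable.  Units: phi in V, spacing in mm; results are
// converted once to V/m^2 (factor 1e6).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// eigenvalues of a symmetric 3x3 matrix, trigonometric method
static void eig_sym3(double a11, double a22, double a33,
                     double a12, double a13, double a23, double ev[3]) {
  const double p1 = a12 * a12 + a13 * a13 + a23 * a23;
  if (p1 == 0.0) { ev[0] = a11; ev[1] = a22; ev[2] = a33; return; }
  const double q = (a11 + a22 + a33) / 3.0;
  const double p2 = (a11 - q) * (a11 - q) + (a22 - q) * (a22 - q) +
                    (a33 - q) * (a33 - q) + 2.0 * p1;
  const double p = std::sqrt(p2 / 6.0);
  const double b11 = (a11 - q) / p, b22 = (a22 - q) / p, b33 = (a33 - q) / p;
  const double b12 = a12 / p, b13 = a13 / p, b23 = a23 / p;
  double detB = b11 * (b22 * b33 - b23 * b23) - b12 * (b12 * b33 - b23 * b13) +
                b13 * (b12 * b23 - b22 * b13);
  double r = detB / 2.0;
  if (r < -1.0) r = -1.0;
  if (r > 1.0) r = 1.0;
  const double phi = std::acos(r) / 3.0;
  ev[0] = q + 2.0 * p * std::cos(phi);
  ev[2] = q + 2.0 * p * std::cos(phi + 2.0943951023931953); // + 2*pi/3
  ev[1] = 3.0 * q - ev[0] - ev[2];
}

// [[Rcpp::export(name = ".cpp_hessian_af")]]
List cpp_hessian_af(NumericVector phi, IntegerVector dim, NumericVector spacing,
                    LogicalVector conductive, bool keep_eigs) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  if (nx < 3 || ny < 3 || nz < 3) stop("grid must be at least 3 voxels on every axis");
  const R_xlen_t ncell = (R_xlen_t)nx * ny * nz;
  const R_xlen_t stride[3] = { 1, nx, (R_xlen_t)nx * ny };
  const double sp[3] = { spacing[0], spacing[1], spacing[2] };

  NumericVector af(ncell, 0.0);
  NumericVector eigs;
  if (keep_eigs) { eigs = NumericVector((R_xlen_t)3 * ncell, 0.0); }

  auto ok = [&](R_xlen_t c) { return conductive[c] != 0; };

  for (R_xlen_t c = 0; c < ncell; ++c) {
    if (!ok(c)) continue;
    int ijk[3] = { (int)(c % nx), (int)((c / nx) % ny), (int)(c / ((R_xlen_t)nx * ny)) };
    const int nmax[3] = { nx, ny, nz };
    double H[3][3] = { { 0 } };

    // pure second derivatives, shifted inward when a neighbour is missing
    for (int ax = 0; ax < 3; ++ax) {
      R_xlen_t s = stride[ax];
      int pos = ijk[ax];
      bool hasm = pos - 1 >= 0 && ok(c - s), hasp = pos + 1 < nmax[ax] && ok(c + s);
      double d2 = 0.0;
      if (hasm && hasp) {
        d2 = phi[c - s] - 2.0 * phi[c] + phi[c + s];
      } else if (hasp && pos + 2 < nmax[ax] && ok(c + 2 * s)) {
        d2 = phi[c] - 2.0 * phi[c + s] + phi[c + 2 * s];
      } else if (hasm && pos - 2 >= 0 && ok(c - 2 * s)) {
        d2 = phi[c - 2 * s] - 2.0 * phi[c - s] + phi[c];
      }
      H[ax][ax] = d2 / (sp[ax] * sp[ax]) * 1e6;
    }

    // mixed partials: central 4-corner stencil, zero if any corner missing
    for (int a = 0; a < 3; ++a) for (int bx = a + 1; bx < 3; ++bx) {
      R_xlen_t sa = stride[a], sb = stride[bx];
      bool in = ijk[a] - 1 >= 0 && ijk[a] + 1 < nmax[a] &&
                ijk[bx] - 1 >= 0 && ijk[bx] + 1 < nmax[bx];
      double d2 = 0.0;
      if (in && ok(c + sa + sb) && ok(c + sa - sb) && ok(c - sa + sb) && ok(c - sa - sb)) {
        d2 = (phi[c + sa + sb] - phi[c + sa - sb] - phi[c - sa + sb] + phi[c - sa - sb]) /
             (4.0 * sp[a] * sp[bx]) * 1e6;
      }
      H[a][bx] = H[bx][a] = d2;
    }

    double ev[3];
    eig_sym3(H[0][0], H[1][1], H[2][2], H[0][1], H[0][2], H[1][2], ev);
    double m = std::fabs(ev[0]);
    if (std::fabs(ev[1]) > m) m = std::fabs(ev[1]);
    if (std::fabs(ev[2]) > m) m = std::fabs(ev[2]);
    af[c] = m;
    if (keep_eigs) {
      eigs[3 * c] = ev[0]; eigs[3 * c + 1] = ev[1]; eigs[3 * c + 2] = ev[2];
    }
  }
  af.attr("dim") = dim;
  List out = List::create(_["af"] = af);
  if (keep_eigs) {
    eigs.attr("dim") = IntegerVector::create(3, nx, ny, nz);
    out["eigenvalues"] = eigs;
  }
  return out;
}
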