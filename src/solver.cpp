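// Finite-difference quasi-static volume conductor on a regular voxel grid.
//
// Discretization: cell-centered 7-point stencil with harmonic-mean face
// conductivities (exact for layered media, conservative at tissue jumps).
// Air voxels (sigma == 0) are excluded from the linear system; electrode
// voxels carry Dirichlet values.  The system is SPD and solved with
// Jacobi-preconditioned conjugate gradients, matrix-free.
//
// Units: sigma in S/m, spacing in mm, potentials in V, currents in A
// internally (reported as mA from R).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <queue>
using namespace Rcpp;

static inline double hmean(double a, double b) {
  if (a <= 0.0 || b <= 0.0) return 0.0;
  return 2.0 * a * b / (a + b);
}

// [[Rcpp::export(name = ".cpp_solve_potential")]]
List cpp_solve_potential(NumericVector sigma, IntegerVector dim,
                         NumericVector spacing, IntegerVector dirichlet_idx,
                         NumericVector dirichlet_val, double tol, int maxit) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t ncell = (R_xlen_t)nx * ny * nz;
  const double dx = spacing[0], dy = spacing[1], dz = spacing[2];
  // face geometry factor: area/dist * 1e-3 converts S/m * mm -> S
  const double fgeo[3] = { dy * dz / dx * 1e-3,
                           dx * dz / dy * 1e-3,
                           dx * dy / dz * 1e-3 };
  const R_xlen_t stride[3] = { 1, nx, (R_xlen_t)nx * ny };

  // state: -1 air, -2 Dirichlet, >=0 unknown id
  std::vector<R_xlen_t> state(ncell);
  std::vector<double> dval(ncell, 0.0);
  for (R_xlen_t c = 0; c < ncell; ++c) state[c] = sigma[c] > 0.0 ? 0 : -1;
  for (R_xlen_t k = 0; k < dirichlet_idx.size(); ++k) {
    R_xlen_t c = (R_xlen_t)dirichlet_idx[k] - 1; // 1-based from R
    if (c < 0 || c >= ncell) stop("Dirichlet index out of range");
    if (sigma[c] <= 0.0) stop("Dirichlet node placed on a non-conductive voxel");
    state[c] = -2;
    dval[c] = dirichlet_val[k];
  }
  R_xlen_t nun = 0;
  for (R_xlen_t c = 0; c < ncell; ++c) if (state[c] == 0) state[c] = nun++;
  // note: a Dirichlet cell has state -2, air -1; unknown ids start at 0 but a
  // cell that kept state 0 is unknown id 0 -- handled by assignment order above
  // (state[c] == 0 test happens before overwrite, ids assigned sequentially).

  if (nun == 0) stop("no unknown conductive voxels in the system");

  // connectivity: BFS from Dirichlet cells with positive value must reach one
  // with negative (or differing) value through conductive cells
  {
    std::vector<char> seen(ncell, 0);
    std::queue<R_xlen_t> q;
    double v0 = NA_REAL;
    bool two_levels = false;
    for (R_xlen_t k = 0; k < dirichlet_idx.size(); ++k) {
      double v = dirichlet_val[k];
      if (ISNA(v0)) v0 = v; else if (v != v0) two_levels = true;
    }
    if (!two_levels) stop("Dirichlet set has a single voltage level; no current can flow");
    R_xlen_t c0 = (R_xlen_t)dirichlet_idx[0] - 1;
    q.push(c0); seen[c0] = 1;
    bool reached = false;
    while (!q.empty() && !reached) {
      R_xlen_t c = q.front(); q.pop();
      int i = (int)(c % nx), j = (int)((c / nx) % ny), kk = (int)(c / ((R_xlen_t)nx * ny));
      const int ijk[3] = { i, j, kk }, nmax[3] = { nx, ny, nz };
      for (int ax = 0; ax < 3; ++ax) for (int sdir = -1; sdir <= 1; sdir += 2) {
        int pos = ijk[ax] + sdir;
        if (pos < 0 || pos >= nmax[ax]) continue;
        R_xlen_t nb = c + sdir * stride[ax];
        if (seen[nb] || sigma[nb] <= 0.0) continue;
        seen[nb] = 1;
        if (state[nb] == -2 && dval[nb] != dval[c0]) { reached = true; break; }
        q.push(nb);
      }
    }
    if (!reached) stop("electrodes are not connected through the conductive domain");
  }

  // assemble diagonal and RHS
  std::vector<double> diag(nun, 0.0), b(nun, 0.0);
  for (R_xlen_t c = 0; c < ncell; ++c) {
    if (state[c] < 0) continue;
    R_xlen_t u = state[c];
    int i = (int)(c % nx), j = (int)((c / nx) % ny), kk = (int)(c / ((R_xlen_t)nx * ny));
    const int ijk[3] = { i, j, kk }, nmax[3] = { nx, ny, nz };
    for (int ax = 0; ax < 3; ++ax) for (int sdir = -1; sdir <= 1; sdir += 2) {
      int pos = ijk[ax] + sdir;
      if (pos < 0 || pos >= nmax[ax]) continue;      // insulating outer boundary
      R_xlen_t nb = c + sdir * stride[ax];
      double g = hmean(sigma[c], sigma[nb]) * fgeo[ax];
      if (g <= 0.0) continue;                        // air face: no current
      diag[u] += g;
      if (state[nb] == -2) b[u] += g * dval[nb];
    }
  }

  // matrix-free CG with Jacobi preconditioner
  std::vector<double> x(nun, 0.0), r(b), z(nun), p(nun), Ap(nun);
  double bnorm = 0.0;
  for (R_xlen_t u = 0; u < nun; ++u) bnorm += b[u] * b[u];
  bnorm = std::sqrt(bnorm);
  if (bnorm == 0.0) stop("zero right-hand side: electrodes carry no drive");

  auto applyA = [&](const std::vector<double>& v, std::vector<double>& out) {
    for (R_xlen_t c = 0; c < ncell; ++c) {
      if (state[c] < 0) continue;
      R_xlen_t u = state[c];
      int i = (int)(c % nx), j = (int)((c / nx) % ny), kk = (int)(c / ((R_xlen_t)nx * ny));
      const int ijk[3] = { i, j, kk }, nmax[3] = { nx, ny, nz };
      double acc = diag[u] * v[u];
      for (int ax = 0; ax < 3; ++ax) for (int sdir = -1; sdir <= 1; sdir += 2) {
        int pos = ijk[ax] + sdir;
        if (pos < 0 || pos >= nmax[ax]) continue;
        R_xlen_t nb = c + sdir * stride[ax];
        if (state[nb] < 0) continue;
        double g = hmean(sigma[c], sigma[nb]) * fgeo[ax];
        acc -= g * v[state[nb]];
      }
      out[u] = acc;
    }
  };

  double rz = 0.0;
  for (R_xlen_t u = 0; u < nun; ++u) { z[u] = r[u] / diag[u]; p[u] = z[u]; rz += r[u] * z[u]; }
  double relres = 1.0;
  int it = 0;
  for (it = 0; it < maxit; ++it) {
    applyA(p, Ap);
    double pAp = 0.0;
    for (R_xlen_t u = 0; u < nun; ++u) pAp += p[u] * Ap[u];
    double alpha = rz / pAp;
    double rnorm = 0.0;
    for (R_xlen_t u = 0; u < nun; ++u) {
      x[u] += alpha * p[u];
      r[u] -= alpha * Ap[u];
      rnorm += r[u] * r[u];
    }
    relres = std::sqrt(rnorm) / bnorm;
    if (relres <= tol) { ++it; break; }
    double rz_new = 0.0;
    for (R_xlen_t u = 0; u < nun; ++u) { z[u] = r[u] / diag[u]; rz_new += r[u] * z[u]; }
    double beta = rz_new / rz;
    rz = rz_new;
    for (R_xlen_t u = 0; u < nun; ++u) p[u] = z[u] + beta * p[u];
  }

  NumericVector phi(ncell, 0.0);
  for (R_xlen_t c = 0; c < ncell; ++c) {
    if (state[c] >= 0) phi[c] = x[state[c]];
    else if (state[c] == -2) phi[c] = dval[c];
  }
  phi.attr("dim") = dim;
  return List::create(_["phi"] = phi, _["iterations"] = it,
                      _["relres"] = relres, _["converged"] = relres <= tol);
}

// Current (A) leaving a voxel set through faces to conductive voxels outside
// the set.  Used with the Dirichlet node set of one electrode.
// [[Rcpp::export(name = ".cpp_set_current")]]
double cpp_set_current(NumericVector phi, NumericVector sigma, IntegerVector dim,
                       NumericVector spacing, IntegerVector set_idx) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t ncell = (R_xlen_t)nx * ny * nz;
  const double dx = spacing[0], dy = spacing[1], dz = spacing[2];
  const double fgeo[3] = { dy * dz / dx * 1e-3, dx * dz / dy * 1e-3, dx * dy / dz * 1e-3 };
  const R_xlen_t stride[3] = { 1, nx, (R_xlen_t)nx * ny };
  std::vector<char> inset(ncell, 0);
  for (R_xlen_t k = 0; k < set_idx.size(); ++k) inset[(R_xlen_t)set_idx[k] - 1] = 1;
  double I = 0.0;
  for (R_xlen_t k = 0; k < set_idx.size(); ++k) {
    R_xlen_t c = (R_xlen_t)set_idx[k] - 1;
    int i = (int)(c % nx), j = (int)((c / nx) % ny), kk = (int)(c / ((R_xlen_t)nx * ny));
    const int ijk[3] = { i, j, kk }, nmax[3] = { nx, ny, nz };
    for (int ax = 0; ax < 3; ++ax) for (int sdir = -1; sdir <= 1; sdir += 2) {
      int pos = ijk[ax] + sdir;
      if (pos < 0 || pos >= nmax[ax]) continue;
      R_xlen_t nb = c + sdir * stride[ax];
      if (inset[nb]) continue;
      double g = hmean(sigma[c], sigma[nb]) * fgeo[ax];
      if (g <= 0.0) continue;
      I += g * (phi[c] - phi[nb]);
    }
  }
  return I;
}
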