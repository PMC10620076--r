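#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Harmonic mean of two conductivities; zero if either side is non-conductive.
// The harmonic mean is the exact series conductance of two half-voxels and is
// robust at high-contrast interfaces (skull/CSF).
static inline double face_sigma(double a, double b) {
  if (a <= 0.0 || b <= 0.0) return 0.0;
  return 2.0 * a * b / (a + b);
}

// Solve div(sigma grad phi) = 0 on a regular voxel grid with Dirichlet values
// on electrode patch voxels and natural (zero-flux) boundaries elsewhere
// (air voxels have sigma = 0, so tissue/air faces carry no current).
//
// sigma:  conductivity per voxel (S/m), length nx*ny*nz, column-major
// h:      isotropic voxel edge (m)
// dirichlet_idx/val: 0-based voxel indices and their fixed potentials (V)
//
// Jacobi-preconditioned conjugate gradients on the free (conductive,
// non-Dirichlet) voxels; the 7-point operator is applied matrix-free.
// [[Rcpp::export]]
List pcg_solve_potential(NumericVector sigma, IntegerVector dims, double h,
                         IntegerVector dirichlet_idx, NumericVector dirichlet_val,
                         double tol, int max_iter) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t N = (R_xlen_t)nx * ny * nz;
  if (sigma.size() != N) stop("sigma length does not match dims");
  const double inv_h2 = 1.0 / (h * h);

  // status: 0 free, 1 Dirichlet, -1 excluded (air)
  std::vector<signed char> status(N, 0);
  for (R_xlen_t v = 0; v < N; ++v) if (sigma[v] <= 0.0) status[v] = -1;
  NumericVector phi(N, 0.0);
  for (R_xlen_t k = 0; k < dirichlet_idx.size(); ++k) {
    R_xlen_t v = dirichlet_idx[k];
    if (v < 0 || v >= N) stop("dirichlet index out of range");
    if (sigma[v] <= 0.0) stop("Dirichlet voxel has zero conductivity");
    status[v] = 1;
    phi[v] = dirichlet_val[k];
  }

  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;

  // Per-voxel neighbour walk shared by diagonal, rhs and operator assembly.
  std::vector<double> diag(N, 0.0), b(N, 0.0);
  double bnorm2 = 0.0;
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        R_xlen_t v = i + sy * j + sz * k;
        if (status[v] != 0) continue;
        double d = 0.0, rhs = 0.0;
        const double sv = sigma[v];
        const int  ii[6] = {i - 1, i + 1, j - 1, j + 1, k - 1, k + 1};
        const R_xlen_t off[6] = {-sx, sx, -sy, sy, -sz, sz};
        const int  lim[6] = {-1, nx, -1, ny, -1, nz};
        for (int f = 0; f < 6; ++f) {
          if (ii[f] == lim[f]) continue;
          R_xlen_t n = v + off[f];
          double w = face_sigma(sv, sigma[n]);
          if (w <= 0.0) continue;
          d += w * inv_h2;
          if (status[n] == 1) rhs += w * inv_h2 * phi[n];
        }
        diag[v] = d;
        b[v] = rhs;
        bnorm2 += rhs * rhs;
      }
    }
  }

  if (bnorm2 == 0.0) {
    return List::create(_["phi"] = phi, _["iterations"] = 0,
                        _["relative_residual"] = 0.0, _["converged"] = true);
  }

  // CG vectors over the full grid; untouched entries stay zero.
  std::vector<double> x(N, 0.0), r(N, 0.0), z(N, 0.0), p(N, 0.0), Ap(N, 0.0);
  double rz = 0.0;
  for (R_xlen_t v = 0; v < N; ++v) {
    if (status[v] != 0) continue;
    r[v] = b[v];                       // x = 0 initial guess
    z[v] = (diag[v] > 0.0) ? r[v] / diag[v] : 0.0;
    p[v] = z[v];
    rz += r[v] * z[v];
  }

  const double bnorm = std::sqrt(bnorm2);
  double relres = 1.0;
  int iter = 0;
  bool converged = false;

  for (iter = 0; iter < max_iter; ++iter) {
    // Ap = A p (matrix-free 7-point stencil over free voxels)
    double pAp = 0.0;
    for (int k = 0; k < nz; ++k) {
      for (int j = 0; j < ny; ++j) {
        for (int i = 0; i < nx; ++i) {
          R_xlen_t v = i + sy * j + sz * k;
          if (status[v] != 0) continue;
          double acc = diag[v] * p[v];
          const double sv = sigma[v];
          const int  ii[6] = {i - 1, i + 1, j - 1, j + 1, k - 1, k + 1};
          const R_xlen_t off[6] = {-sx, sx, -sy, sy, -sz, sz};
          const int  lim[6] = {-1, nx, -1, ny, -1, nz};
          for (int f = 0; f < 6; ++f) {
            if (ii[f] == lim[f]) continue;
            R_xlen_t n = v + off[f];
            if (status[n] != 0) continue;
            double w = face_sigma(sv, sigma[n]);
            if (w <= 0.0) continue;
            acc -= w * inv_h2 * p[n];
          }
          Ap[v] = acc;
          pAp += p[v] * acc;
        }
      }
    }
    if (pAp <= 0.0) stop("CG breakdown: operator not positive definite (singular system?)");
    double alpha = rz / pAp;
    double rnorm2 = 0.0, rz_new = 0.0;
    for (R_xlen_t v = 0; v < N; ++v) {
      if (status[v] != 0) continue;
      x[v] += alpha * p[v];
      r[v] -= alpha * Ap[v];
      rnorm2 += r[v] * r[v];
    }
    relres = std::sqrt(rnorm2) / bnorm;
    if (relres <= tol) { converged = true; ++iter; break; }
    for (R_xlen_t v = 0; v < N; ++v) {
      if (status[v] != 0) continue;
      z[v] = (diag[v] > 0.0) ? r[v] / diag[v] : 0.0;
      rz_new += r[v] * z[v];
    }
    double beta = rz_new / rz;
    rz = rz_new;
    for (R_xlen_t v = 0; v < N; ++v) {
      if (status[v] != 0) continue;
      p[v] = z[v] + beta * p[v];
    }
  }

  for (R_xlen_t v = 0; v < N; ++v) if (status[v] == 0) phi[v] = x[v];

  return List::create(_["phi"] = phi, _["iterations"] = iter,
                      _["relative_residual"] = relres, _["converged"] = converged);
}

// E = -grad(phi): central differences where both axis neighbours are
// conductive, one-sided into tissue at tissue/air boundaries, zero in air.
// Returns an (nx, ny, nz, 3) array flattened column-major; units V/m.
// [[Rcpp::export]]
NumericVector efield_from_potential(NumericVector phi, NumericVector sigma,
                                    IntegerVector dims, double h) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t N = (R_xlen_t)nx * ny * nz;
  if (phi.size() != N || sigma.size() != N) stop("phi/sigma length mismatch");
  NumericVector E(N * 3, 0.0);
  const R_xlen_t stride[3] = {1, nx, (R_xlen_t)nx * ny};

  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        R_xlen_t v = i + stride[1] * j + stride[2] * k;
        if (sigma[v] <= 0.0) continue;
        const int pos[3] = {i, j, k};
        const int ndim[3] = {nx, ny, nz};
        for (int a = 0; a < 3; ++a) {
          bool has_m = pos[a] > 0           && sigma[v - stride[a]] > 0.0;
          bool has_p = pos[a] < ndim[a] - 1 && sigma[v + stride[a]] > 0.0;
          double g;
          if (has_m && has_p)      g = (phi[v + stride[a]] - phi[v - stride[a]]) / (2.0 * h);
          else if (has_p)          g = (phi[v + stride[a]] - phi[v]) / h;
          else if (has_m)          g = (phi[v] - phi[v - stride[a]]) / h;
          else                     g = 0.0;
          E[v + (R_xlen_t)a * N] = -g;
        }
      }
    }
  }
  return E;
}

// Net ohmic current leaving a Dirichlet patch: sum of face currents from
// patch voxels into conductive non-patch neighbours. Units: amperes for
// phi in V, sigma in S/m, h in m.
// [[Rcpp::export]]
double patch_current(NumericVector phi, NumericVector sigma, IntegerVector dims,
                     double h, IntegerVector patch_idx) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t N = (R_xlen_t)nx * ny * nz;
  std::vector<char> inpatch(N, 0);
  for (R_xlen_t k = 0; k < patch_idx.size(); ++k) {
    R_xlen_t v = patch_idx[k];
    if (v < 0 || v >= N) stop("patch index out of range");
    inpatch[v] = 1;
  }
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  double I = 0.0;
  for (R_xlen_t q = 0; q < patch_idx.size(); ++q) {
    R_xlen_t v = patch_idx[q];
    int i = (int)(v % nx), j = (int)((v / nx) % ny), k = (int)(v / ((R_xlen_t)nx * ny));
    const int  ii[6] = {i - 1, i + 1, j - 1, j + 1, k - 1, k + 1};
    const R_xlen_t off[6] = {-sx, sx, -sy, sy, -sz, sz};
    const int  lim[6] = {-1, nx, -1, ny, -1, nz};
    for (int f = 0; f < 6; ++f) {
      if (ii[f] == lim[f]) continue;
      R_xlen_t n = v + off[f];
      if (inpatch[n]) continue;
      double w = face_sigma(sigma[v], sigma[n]);
      if (w <= 0.0) continue;
      I += w * (phi[v] - phi[n]) / h * h * h;  // sigma * dphi/dx * face area
    }
  }
  return I;
}
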