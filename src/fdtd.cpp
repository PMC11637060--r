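// First-order velocity-pressure acoustic solver on a 2D staggered grid.
// 4th-order accurate in space, leapfrog (2nd-order) in time, with a graded
// multiplicative absorbing sponge standing in for a PML. Heterogeneous sound
// speed and mass density; optional uniform amplitude damping per step
// (frequency-independent absorption evaluated at the transmit frequency).
//
// Grid convention: matrices are (nz rows, nx cols); p lives at cell centres,
// ux at (i, j+1/2), uz at (i+1/2, j).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

static inline double d4(double fm1, double f0, double f1, double f2,
                        double inv24dx) {
  // 4th-order staggered first derivative at the half point between f0 and f1
  return (27.0 * (f1 - f0) - (f2 - fm1)) * inv24dx;
}

// source_mode: 0 = none, 1 = additive pressure, 2 = Dirichlet pressure
// source_sig: (nt x nsrc) matrix (nsrc = length(source_idx)); for mode 1 a
// single column is recycled across all source points.
// [[Rcpp::export(name = ".fdtd_run")]]
Rcpp::List fdtd_run(const arma::mat& c2rho,   // rho * c^2 at p points
                    const arma::mat& inv_rho_x, // 1/rho at ux points
                    const arma::mat& inv_rho_z, // 1/rho at uz points
                    const arma::mat& sponge,  // per-cell decay factor (<= 1)
                    const arma::mat& damp,    // absorption factor (<= 1)
                    const arma::mat& p0,      // initial pressure
                    const arma::uvec& source_idx,
                    const arma::mat& source_sig,
                    int source_mode,
                    const arma::uvec& sensor_idx,
                    double dt, double dx, int nt,
                    bool record_energy) {
  const uword nz = c2rho.n_rows, nx = c2rho.n_cols;
  const double inv24dx = 1.0 / (24.0 * dx);

  mat p = p0, ux(nz, nx, fill::zeros), uz(nz, nx, fill::zeros);
  mat dive(nz, nx, fill::zeros);

  const uword ns = sensor_idx.n_elem;
  mat rf(ns, nt, fill::zeros);
  vec energy;
  if (record_energy) energy.zeros(nt);

  const bool recycle = (source_mode == 1 && source_sig.n_cols == 1);

  for (int t = 0; t < nt; ++t) {
    // velocity updates from pressure gradients
    for (uword j = 1; j + 2 < nx; ++j) {
      const double* pm1 = p.colptr(j - 1);
      const double* p0c = p.colptr(j);
      const double* pp1 = p.colptr(j + 1);
      const double* pp2 = p.colptr(j + 2);
      double* u = ux.colptr(j);
      const double* ir = inv_rho_x.colptr(j);
      const double* sp = sponge.colptr(j);
      for (uword i = 0; i < nz; ++i) {
        double g = d4(pm1[i], p0c[i], pp1[i], pp2[i], inv24dx);
        u[i] = sp[i] * (u[i] - dt * ir[i] * g);
      }
    }
    for (uword j = 0; j < nx; ++j) {
      const double* pc = p.colptr(j);
      double* u = uz.colptr(j);
      const double* ir = inv_rho_z.colptr(j);
      const double* sp = sponge.colptr(j);
      for (uword i = 1; i + 2 < nz; ++i) {
        double g = d4(pc[i - 1], pc[i], pc[i + 1], pc[i + 2], inv24dx);
        u[i] = sp[i] * (u[i] - dt * ir[i] * g);
      }
    }

    // divergence of velocity at pressure points
    for (uword j = 2; j + 1 < nx; ++j) {
      const double* um2 = ux.colptr(j - 2);
      const double* um1 = ux.colptr(j - 1);
      const double* u0 = ux.colptr(j);
      const double* up1 = ux.colptr(j + 1);
      const double* vz = uz.colptr(j);
      double* dv = dive.colptr(j);
      for (uword i = 2; i + 1 < nz; ++i) {
        double gx = d4(um2[i], um1[i], u0[i], up1[i], inv24dx);
        double gz = d4(vz[i - 2], vz[i - 1], vz[i], vz[i + 1], inv24dx);
        dv[i] = gx + gz;
      }
    }

    // pressure update with sponge + absorption
    for (uword j = 0; j < nx; ++j) {
      double* pc = p.colptr(j);
      const double* dv = dive.colptr(j);
      const double* cr = c2rho.colptr(j);
      const double* sp = sponge.colptr(j);
      const double* dm = damp.colptr(j);
      for (uword i = 0; i < nz; ++i)
        pc[i] = dm[i] * sp[i] * (pc[i] - dt * cr[i] * dv[i]);
    }

    // sources
    if (source_mode == 1) {
      for (uword k = 0; k < source_idx.n_elem; ++k)
        p(source_idx[k]) += recycle ? source_sig(t, 0) : source_sig(t, k);
    } else if (source_mode == 2) {
      for (uword k = 0; k < source_idx.n_elem; ++k)
        p(source_idx[k]) = source_sig(t, k);
    }

    // record
    for (uword k = 0; k < ns; ++k) rf(k, t) = p(sensor_idx[k]);
    if (record_energy) energy(t) = accu(square(p));
  }

  Rcpp::List out = Rcpp::List::create(Rcpp::Named("rf") = rf,
                                      Rcpp::Named("p_final") = p);
  if (record_energy) out["energy"] = energy;
  return out;
}
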