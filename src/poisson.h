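#ifndef EULFSI_POISSON_H
#define EULFSI_POISSON_H
#include <RcppArmadillo.h>
#include "core.h"

// Direct pressure solver for domains whose wall mask is invariant along x
// (straight pipe, cavity, periodic boxes): eigen-transform along x of the
// 1D second-difference operator (periodic or homogeneous Neumann), then one
// banded Cholesky solve per x-mode over the fluid cells of the cross-section.
struct PoissonTransform {
  int nx = 0, nf = 0, bw = 0;
  arma::mat Q;        // orthogonal eigenbasis of the x operator
  arma::vec lam;      // eigenvalues (include 1/dx^2)
  std::vector<int> csmap;   // (j + ny*k) -> cross-section fluid index or -1
  std::vector<int> cells;   // fluid index -> j + ny*k
  std::vector<arma::mat> Lband; // per-mode banded Cholesky factor of -(Lyz+lam)
  int mode0 = -1;           // index of the (single) zero eigenvalue, if any
  // xbc: 0 periodic, 1 homogeneous Neumann, 2 homogeneous Dirichlet
  void setup(const Mesh& m, int xbc);
  // rhs and phi are full cell fields; wall cells ignored / set to zero
  void solve(const std::vector<double>& rhs, std::vector<double>& phi,
             const Mesh& m);
};

// Matrix-free Jacobi-preconditioned conjugate gradients for general masked
// domains, with optional Dirichlet pressure values on the x-lo / x-hi
// boundaries (ghost-cell form) and homogeneous Neumann elsewhere.
struct PoissonPCG {
  bool dir_xlo = false, dir_xhi = false;
  double val_xlo = 0.0, val_xhi = 0.0;
  std::vector<double> phi_prev;
  int last_iters = 0;
  // optional preconditioner: the analogous x-invariant (straight-duct)
  // direct solver, applied as a fictitious-domain preconditioner
  PoissonTransform* precond = nullptr;
  Mesh precond_mesh; // same grid, x-invariant mask
  // solves to ||residual||_inf <= tol; returns 0 on success
  int solve(const std::vector<double>& rhs, std::vector<double>& phi,
            const Mesh& m, double tol, int maxit);
};

#endif
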