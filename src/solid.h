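#ifndef EULFSI_SOLID_H
#define EULFSI_SOLID_H
#include "core.h"

// component order of the symmetric tensor storage
enum { BXX = 0, BXY = 1, BYY = 2, BXZ = 3, BYZ = 4, BZZ = 5 };

// cell-centered velocity components from the staggered arrays
void cell_center_velocity(const std::vector<double>& ux,
                          const std::vector<double>& uy,
                          const std::vector<double>& uz, const Mesh& m,
                          std::vector<double>& ucx, std::vector<double>& ucy,
                          std::vector<double>& ucz);

// full velocity-gradient tensor L[i][j] = d u_i / d x_j at cell centers
void velocity_gradient_cc(const std::vector<double>& ux,
                          const std::vector<double>& uy,
                          const std::vector<double>& uz, const Mesh& m,
                          std::vector<double> L[3][3],
                          const std::vector<unsigned char>* active = nullptr);

// advection (third-order WENO upwind, flux form) plus the stretching source
// L.B + B.L^T integrated with trapezoidal weighting via one fixed-point
// corrector pass; returns the largest absolute tensor component.
// When `alpha` is given, evolution is restricted to the band of cells within
// Chebyshev distance 3 of the solid (alpha > 1e-9); everything outside ends
// up at the clip reset value regardless, so the restriction is exact.
double evolve_btilde(std::vector<double> B[6], const std::vector<double>& ux,
                     const std::vector<double>& uy,
                     const std::vector<double>& uz, const Mesh& m, double dt,
                     int weno_order,
                     const std::vector<double>* alpha = nullptr);

// paper clipping rule: cells with alpha < alpha_min get the reset tensor
// (unit or zero); optionally alpha is zeroed there too
void clip_btilde(std::vector<double> B[6], std::vector<double>& alpha,
                 const Mesh& m, double alpha_min, bool reset_unit,
                 bool zero_alpha);

// conservative elastic force (1/rho) div( G sqrt(alpha) dev(Btilde) ) on faces
void elastic_force(const std::vector<double> B[6],
                   const std::vector<double>& alpha, const Mesh& m, double G,
                   std::vector<double>& fx, std::vector<double>& fy,
                   std::vector<double>& fz);

#endif
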