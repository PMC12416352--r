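#ifndef EULFSI_PLIC_H
#define EULFSI_PLIC_H
#include "core.h"

// Piecewise linear interface construction state: a unit normal (pointing from
// solid into fluid) and a signed plane constant per cell. Only entries of
// interface cells (0 < alpha < 1) are meaningful; is_int flags them.
struct PlicState {
  std::vector<double> nxv, nyv, nzv, cv;
  std::vector<unsigned char> is_int;
  std::vector<long> cells;   // current interface-cell list
  long nfallback = 0;
  void resize(long N) {
    nxv.assign(N, 0.0); nyv.assign(N, 0.0); nzv.assign(N, 0.0);
    cv.assign(N, 0.0); is_int.assign(N, 0);
  }
};

// fraction of the unit cube below the plane sum(m_i xi_i) <= s, m_i >= 0
double cut_unit(double m1, double m2, double m3, double s);
// inverse: plane constant s achieving a given fraction
double invert_cut(double m1, double m2, double m3, double frac);
// solid fraction of the axis-aligned sub-box [lo, hi] (unit-cell coordinates)
// for the plane {n . (x - xc) + c <= 0} of a cell with spacing dx
double plane_box_fraction(const double n[3], double c, const double lo[3],
                          const double hi[3], double dx);

void plic_reconstruct(const std::vector<double>& alpha, const Mesh& m,
                      int rdf_iters, PlicState& ps, bool warm_start);

// one full multidimensional advection step (directionally split geometric
// fluxes with the divergence-consistent volume-tracking correction); the
// interface is re-reconstructed before every sweep. Returns clamped-away
// volume (absolute, cell-volume units) through *lost.
void vof_advect(std::vector<double>& alpha,
                const std::vector<double>& ux, const std::vector<double>& uy,
                const std::vector<double>& uz, const Mesh& m, double dt,
                int step_parity, int rdf_iters, PlicState& ps, double* lost);

#endif
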