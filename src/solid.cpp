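// Evolution of the corrected left Cauchy-Green tensor Btilde and the solid's
// elastic Cauchy stress contribution.
#include <Rcpp.h>
#include "solid.h"

void cell_center_velocity(const std::vector<double>& ux,
                          const std::vector<double>& uy,
                          const std::vector<double>& uz, const Mesh& m,
                          std::vector<double>& ucx, std::vector<double>& ucy,
                          std::vector<double>& ucz) {
  FaceDims fx(m, 0), fy(m, 1), fz(m, 2);
  long N = m.N();
  ucx.assign(N, 0.0); ucy.assign(N, 0.0); ucz.assign(N, 0.0);
  for (int k = 0; k < m.nz; ++k)
    for (int j = 0; j < m.ny; ++j)
      for (int i = 0; i < m.nx; ++i) {
        long c = m.cidx(i, j, k);
        ucx[c] = 0.5 * (ux[fx.idx(i, j, k)] + ux[fx.idx(i + 1, j, k)]);
        ucy[c] = 0.5 * (uy[fy.idx(i, j, k)] + uy[fy.idx(i, j + 1, k)]);
        if (m.nz > 1)
          ucz[c] = 0.5 * (uz[fz.idx(i, j, k)] + uz[fz.idx(i, j, k + 1)]);
      }
}

void velocity_gradient_cc(const std::vector<double>& ux,
                          const std::vector<double>& uy,
                          const std::vector<double>& uz, const Mesh& m,
                          std::vector<double> L[3][3],
                          const std::vector<unsigned char>* active) {
  long N = m.N();
  std::vector<double> uc[3];
  cell_center_velocity(ux, uy, uz, m, uc[0], uc[1], uc[2]);
  FaceDims fd0(m, 0), fd1(m, 1), fd2(m, 2);
  for (int a = 0; a < 3; ++a) for (int b = 0; b < 3; ++b) L[a][b].assign(N, 0.0);
  double dx = m.dx;
  for (int k = 0; k < m.nz; ++k)
    for (int j = 0; j < m.ny; ++j)
      for (int i = 0; i < m.nx; ++i) {
        long c = m.cidx(i, j, k);
        if (active && !(*active)[c]) continue;
        // own-axis derivatives from the staggered differences (exact)
        L[0][0][c] = (ux[fd0.idx(i + 1, j, k)] - ux[fd0.idx(i, j, k)]) / dx;
        L[1][1][c] = (uy[fd1.idx(i, j + 1, k)] - uy[fd1.idx(i, j, k)]) / dx;
        if (m.nz > 1)
          L[2][2][c] = (uz[fd2.idx(i, j, k + 1)] - uz[fd2.idx(i, j, k)]) / dx;
        // cross derivatives: central differences of cell-centered values
        // (one-sided at non-periodic domain boundaries)
        auto cderiv = [&](const std::vector<double>& f, int ax) {
          int q[3] = {i, j, k};
          int hi = q[ax] + 1, lo = q[ax] - 1;
          double den = 2 * dx;
          if (!m.per[ax]) {
            if (lo < 0) { lo = 0; den = dx; }
            if (hi >= m.n(ax)) { hi = m.n(ax) - 1; den = dx; }
          }
          int qh[3] = {i, j, k}; qh[ax] = hi;
          int ql[3] = {i, j, k}; ql[ax] = lo;
          return (cget(f, m, qh[0], qh[1], qh[2]) -
                  cget(f, m, ql[0], ql[1], ql[2])) / den;
        };
        for (int a = 0; a < 3; ++a) {
          if (a == 2 && m.nz == 1) continue;
          if (a != 0) L[a][0][c] = cderiv(uc[a], 0);
          if (a != 1) L[a][1][c] = cderiv(uc[a], 1);
          if (m.nz > 1 && a != 2) L[a][2][c] = cderiv(uc[a], 2);
        }
      }
}

// third-order WENO face reconstruction, upwind biased
static inline double weno3_face(double fm2, double fm1, double f0) {
  // reconstruct at the downwind face of cell "m1" using {m2, m1, 0}
  const double eps = 1e-6;
  double b1 = (fm1 - fm2) * (fm1 - fm2);
  double b2 = (f0 - fm1) * (f0 - fm1);
  double w1 = (1.0 / 3.0) / ((eps + b1) * (eps + b1));
  double w2 = (2.0 / 3.0) / ((eps + b2) * (eps + b2));
  double v1 = -0.5 * fm2 + 1.5 * fm1;
  double v2 = 0.5 * (fm1 + f0);
  return (w1 * v1 + w2 * v2) / (w1 + w2);
}

// flux divergence of one cell-centered component with staggered face velocity
static void weno_flux_div(const std::vector<double>& f, const Mesh& m, int d,
                          const std::vector<double>& u,
                          std::vector<double>& div, double dx,
                          const std::vector<unsigned char>* factive) {
  FaceDims fd(m, d);
  long N = m.N();
  std::vector<double> flux(fd.size(), 0.0);
  for (int k = 0; k < fd.fn[2]; ++k)
    for (int j = 0; j < fd.fn[1]; ++j)
      for (int i = 0; i < fd.fn[0]; ++i) {
        long fi = fd.idx(i, j, k);
        if (factive && !(*factive)[fi]) continue;
        double uf = u[fi];
        if (uf == 0.0) { flux[fi] = 0.0; continue; }
        int q = (d == 0 ? i : (d == 1 ? j : k)); // face index along d
        int c0[3] = {i, j, k};
        double fv;
        if (uf > 0.0) {
          int a[3] = {c0[0], c0[1], c0[2]}; a[d] = q - 3 + 2; // q-1 donor
          double fm2, fm1, f0;
          int t[3];
          t[0]=c0[0]; t[1]=c0[1]; t[2]=c0[2]; t[d]=q-3+1; fm2 = cget(f, m, t[0], t[1], t[2]);
          t[d]=q-1; fm1 = cget(f, m, t[0], t[1], t[2]);
          t[d]=q;   f0  = cget(f, m, t[0], t[1], t[2]);
          (void)a;
          fv = weno3_face(fm2, fm1, f0);
        } else {
          int t[3] = {c0[0], c0[1], c0[2]};
          t[d]=q+1; double fm2b = cget(f, m, t[0], t[1], t[2]);
          t[d]=q;   double fm1b = cget(f, m, t[0], t[1], t[2]);
          t[d]=q-1; double f0b  = cget(f, m, t[0], t[1], t[2]);
          fv = weno3_face(fm2b, fm1b, f0b);
        }
        flux[fi] = uf * fv;
      }
  for (int k = 0; k < m.nz; ++k)
    for (int j = 0; j < m.ny; ++j)
      for (int i = 0; i < m.nx; ++i) {
        long c = m.cidx(i, j, k);
        int hi[3] = {i, j, k}; hi[d] += 1;
        div[c] += (flux[fd.idx(hi[0], hi[1], hi[2])] - flux[fd.idx(i, j, k)]) / dx;
      }
  (void)N;
}

// dilate the solid support by `rad` cells (Chebyshev) with 1D max sweeps
static void dilate_mask(std::vector<unsigned char>& msk, const Mesh& m,
                        int rad) {
  std::vector<unsigned char> tmp(msk.size());
  for (int d = 0; d < (m.nz > 1 ? 3 : 2); ++d) {
    tmp.assign(msk.size(), 0);
    for (int k = 0; k < m.nz; ++k)
      for (int j = 0; j < m.ny; ++j)
        for (int i = 0; i < m.nx; ++i) {
          if (!msk[m.cidx(i, j, k)]) continue;
          for (int s = -rad; s <= rad; ++s) {
            int q[3] = {i, j, k};
            q[d] += s;
            q[d] = m.wrap(q[d], d);
            tmp[m.cidx(q[0], q[1], q[2])] = 1;
          }
        }
    msk.swap(tmp);
  }
}

// stretching source L.B + B.L^T for the symmetric component storage
static inline void stretch_source(const double l[3][3], const double b[6],
                                  double s[6]) {
  double Bm[3][3] = {{b[BXX], b[BXY], b[BXZ]},
                     {b[BXY], b[BYY], b[BYZ]},
                     {b[BXZ], b[BYZ], b[BZZ]}};
  double R[3][3];
  for (int a = 0; a < 3; ++a)
    for (int c2 = 0; c2 < 3; ++c2) {
      double acc = 0.0;
      for (int k = 0; k < 3; ++k)
        acc += l[a][k] * Bm[k][c2] + Bm[a][k] * l[c2][k];
      R[a][c2] = acc;
    }
  s[BXX] = R[0][0]; s[BXY] = 0.5 * (R[0][1] + R[1][0]); s[BYY] = R[1][1];
  s[BXZ] = 0.5 * (R[0][2] + R[2][0]); s[BYZ] = 0.5 * (R[1][2] + R[2][1]);
  s[BZZ] = R[2][2];
}

double evolve_btilde(std::vector<double> B[6], const std::vector<double>& ux,
                     const std::vector<double>& uy,
                     const std::vector<double>& uz, const Mesh& m, double dt,
                     int weno_order,
                     const std::vector<double>* alpha) {
  (void)weno_order; // third order implemented; argument kept for the contract
  long N = m.N();
  double dx = m.dx;
  // active band: within 3 cells of the solid (everything else is reset by
  // the clip immediately after this call, so skipping it is exact)
  std::vector<unsigned char> active;
  std::vector<unsigned char> fact[3];
  const std::vector<unsigned char>* actp = nullptr;
  const std::vector<unsigned char>* factp[3] = {nullptr, nullptr, nullptr};
  if (alpha) {
    active.assign(N, 0);
    for (long c = 0; c < N; ++c) active[c] = (*alpha)[c] > 1e-9 ? 1 : 0;
    dilate_mask(active, m, 3);
    actp = &active;
    for (int d = 0; d < (m.nz > 1 ? 3 : 2); ++d) {
      FaceDims fd(m, d);
      fact[d].assign(fd.size(), 0);
      for (int k = 0; k < fd.fn[2]; ++k)
        for (int j = 0; j < fd.fn[1]; ++j)
          for (int i = 0; i < fd.fn[0]; ++i) {
            int lo[3] = {i, j, k}; lo[d] -= 1;
            bool a1 = false, a2 = false;
            int q = (d == 0 ? i : (d == 1 ? j : k));
            if (q - 1 >= 0 || m.per[d]) {
              a1 = active[m.cidx(m.wrap(lo[0], 0), m.wrap(lo[1], 1),
                                 m.wrap(lo[2], 2))] != 0;
            }
            if (q < m.n(d) || m.per[d]) {
              a2 = active[m.cidx(m.wrap(i, 0), m.wrap(j, 1),
                                 m.wrap(k, 2))] != 0;
            }
            if (a1 || a2) fact[d][fd.idx(i, j, k)] = 1;
          }
      factp[d] = &fact[d];
    }
  }
  std::vector<double> L[3][3];
  velocity_gradient_cc(ux, uy, uz, m, L, actp);
  // advection predictor: B* = B - dt div(u B)
  std::vector<double> Bstar[6];
  for (int c2 = 0; c2 < 6; ++c2) {
    std::vector<double> div(N, 0.0);
    weno_flux_div(B[c2], m, 0, ux, div, dx, factp[0]);
    weno_flux_div(B[c2], m, 1, uy, div, dx, factp[1]);
    if (m.nz > 1) weno_flux_div(B[c2], m, 2, uz, div, dx, factp[2]);
    Bstar[c2].resize(N);
    for (long c = 0; c < N; ++c) Bstar[c2][c] = B[c2][c] - dt * div[c];
  }
  // trapezoidal source with one fixed-point pass (Heun)
  double bmax = 0.0;
  for (int k = 0; k < m.nz; ++k)
    for (int j = 0; j < m.ny; ++j)
      for (int i = 0; i < m.nx; ++i) {
        long c = m.cidx(i, j, k);
        if (actp && !active[c]) continue;
        double l[3][3];
        for (int a = 0; a < 3; ++a)
          for (int b2 = 0; b2 < 3; ++b2) l[a][b2] = L[a][b2][c];
        double b0[6], s0[6], bh[6], s1[6];
        for (int c2 = 0; c2 < 6; ++c2) b0[c2] = Bstar[c2][c];
        stretch_source(l, b0, s0);
        for (int c2 = 0; c2 < 6; ++c2) bh[c2] = b0[c2] + dt * s0[c2];
        stretch_source(l, bh, s1);
        for (int c2 = 0; c2 < 6; ++c2) {
          double v = b0[c2] + 0.5 * dt * (s0[c2] + s1[c2]);
          B[c2][c] = v;
          double av = std::fabs(v);
          if (av > bmax) bmax = av;
        }
      }
  return bmax;
}

void clip_btilde(std::vector<double> B[6], std::vector<double>& alpha,
                 const Mesh& m, double alpha_min, bool reset_unit,
                 bool zero_alpha) {
  long N = m.N();
  double diag = reset_unit ? 1.0 : 0.0;
  for (long c = 0; c < N; ++c) {
    bool w = m.has_wall() && m.wall[c];
    if (alpha[c] < alpha_min || w) {
      B[BXX][c] = diag; B[BYY][c] = diag; B[BZZ][c] = diag;
      B[BXY][c] = 0.0; B[BXZ][c] = 0.0; B[BYZ][c] = 0.0;
      if (zero_alpha || w) alpha[c] = 0.0;
    }
  }
}

void elastic_force(const std::vector<double> B[6],
                   const std::vector<double>& alpha, const Mesh& m, double G,
                   std::vector<double>& fx, std::vector<double>& fy,
                   std::vector<double>& fz) {
  long N = m.N();
  double dx = m.dx;
  // cell-centered stress tau = G sqrt(alpha) dev(Btilde)
  std::vector<double> t[6];
  for (int c2 = 0; c2 < 6; ++c2) t[c2].assign(N, 0.0);
  for (long c = 0; c < N; ++c) {
    double a = alpha[c];
    if (a <= 0.0) continue;
    if (m.has_wall() && m.wall[c]) continue;
    double s = G * std::sqrt(a);
    double tr3 = (B[BXX][c] + B[BYY][c] + B[BZZ][c]) / 3.0;
    t[BXX][c] = s * (B[BXX][c] - tr3);
    t[BYY][c] = s * (B[BYY][c] - tr3);
    t[BZZ][c] = s * (B[BZZ][c] - tr3);
    t[BXY][c] = s * B[BXY][c];
    t[BXZ][c] = s * B[BXZ][c];
    t[BYZ][c] = s * B[BYZ][c];
  }
  FaceDims fdx(m, 0), fdy(m, 1), fdz(m, 2);
  fx.assign(fdx.size(), 0.0);
  fy.assign(fdy.size(), 0.0);
  fz.assign(fdz.size(), 0.0);
  auto corner4 = [&](const std::vector<double>& f, int i, int j, int k,
                     int a, int b) {
    // average over the 4 cells sharing the edge/corner displaced along a,b
    int t0[3] = {i, j, k};
    double acc = 0.0;
    for (int s1 = -1; s1 <= 0; ++s1)
      for (int s2 = -1; s2 <= 0; ++s2) {
        int q[3] = {t0[0], t0[1], t0[2]};
        q[a] += s1; q[b] += s2;
        acc += cget(f, m, q[0], q[1], q[2]);
      }
    return 0.25 * acc;
  };
  // x-faces: d/dx tau_xx + d/dy tau_xy + d/dz tau_xz
  for (int k = 0; k < m.nz; ++k)
    for (int j = 0; j < m.ny; ++j)
      for (int i = 0; i <= m.nx; ++i) {
        double v = (cget(t[BXX], m, i, j, k) - cget(t[BXX], m, i - 1, j, k)) / dx;
        double cyp = corner4(t[BXY], i, j + 1, k, 0, 1);
        double cym = corner4(t[BXY], i, j, k, 0, 1);
        v += (cyp - cym) / dx;
        if (m.nz > 1) {
          double czp = corner4(t[BXZ], i, j, k + 1, 0, 2);
          double czm = corner4(t[BXZ], i, j, k, 0, 2);
          v += (czp - czm) / dx;
        }
        fx[fdx.idx(i, j, k)] = v;
      }
  // y-faces: d/dx tau_xy + d/dy tau_yy + d/dz tau_yz
  for (int k = 0; k < m.nz; ++k)
    for (int j = 0; j <= m.ny; ++j)
      for (int i = 0; i < m.nx; ++i) {
        double v = (cget(t[BYY], m, i, j, k) - cget(t[BYY], m, i, j - 1, k)) / dx;
        double cxp = corner4(t[BXY], i + 1, j, k, 1, 0);
        double cxm = corner4(t[BXY], i, j, k, 1, 0);
        v += (cxp - cxm) / dx;
        if (m.nz > 1) {
          double czp = corner4(t[BYZ], i, j, k + 1, 1, 2);
          double czm = corner4(t[BYZ], i, j, k, 1, 2);
          v += (czp - czm) / dx;
        }
        fy[fdy.idx(i, j, k)] = v;
      }
  if (m.nz > 1) {
    for (int k = 0; k <= m.nz; ++k)
      for (int j = 0; j < m.ny; ++j)
        for (int i = 0; i < m.nx; ++i) {
          double v = (cget(t[BZZ], m, i, j, k) - cget(t[BZZ], m, i, j, k - 1)) / dx;
          double cxp = corner4(t[BXZ], i + 1, j, k, 2, 0);
          double cxm = corner4(t[BXZ], i, j, k, 2, 0);
          v += (cxp - cxm) / dx;
          double cyp = corner4(t[BYZ], i, j + 1, k, 2, 1);
          double cym = corner4(t[BYZ], i, j, k, 2, 1);
          v += (cyp - cym) / dx;
          fz[fdz.idx(i, j, k)] = v;
        }
  }
}
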