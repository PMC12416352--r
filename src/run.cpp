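// One-field momentum equation with pressure projection, coupled to the
// volume-of-fluid interface transport and the corrected left Cauchy-Green
// tensor evolution (interface advection -> Btilde evolution -> momentum,
// with optional PIMPLE-style outer correctors and the mean-flow forcing
// controller for periodic pipes).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
#include "core.h"
#include "plic.h"
#include "solid.h"
#include "poisson.h"

void isosurface_vertices(const std::vector<double>& f, const Mesh& m,
                         double level, std::vector<double>& X,
                         std::vector<double>& Y, std::vector<double>& Z);

// positive remainder (floor-based; avoids the versioned libm fmod)
static inline double pmod(double a, double b) {
  return a - std::floor(a / b) * b;
}

// padded copy of a staggered component (ghost = 2) ----------------------
struct Pad3 {
  int g, n0, n1, n2;
  std::vector<double> a;
  long s1, s2;
  void init(int g_, int m0, int m1, int m2) {
    g = g_; n0 = m0; n1 = m1; n2 = m2;
    s1 = n0 + 2 * g; s2 = s1 * (n1 + 2 * g);
    a.assign(s2 * (n2 + 2 * g), 0.0);
  }
  inline double& at(int i, int j, int k) {
    return a[(i + g) + s1 * (j + g) + s2 * (k + g)];
  }
  inline double at(int i, int j, int k) const {
    return a[(i + g) + s1 * (j + g) + s2 * (k + g)];
  }
};

static void pad_component(const std::vector<double>& u, const Mesh& m,
                          const VelBCs& bc, int d, Pad3& out) {
  FaceDims fd(m, d);
  out.init(2, fd.fn[0], fd.fn[1], fd.fn[2]);
  for (int k = 0; k < fd.fn[2]; ++k)        // interior: straight copy
    for (int j = 0; j < fd.fn[1]; ++j)
      std::memcpy(&out.at(0, j, k), &u[fd.idx(0, j, k)],
                  sizeof(double) * fd.fn[0]);
  for (int k = -2; k < fd.fn[2] + 2; ++k)   // ghost shells only
    for (int j = -2; j < fd.fn[1] + 2; ++j) {
      bool jk_in = j >= 0 && j < fd.fn[1] && k >= 0 && k < fd.fn[2];
      for (int i = -2; i < fd.fn[0] + 2; ++i) {
        if (jk_in && i >= 0 && i < fd.fn[0]) { i = fd.fn[0] - 1; continue; }
        out.at(i, j, k) = fget(u, fd, m, bc, d, i, j, k);
      }
    }
}

static void pad_cells(const std::vector<double>& f, const Mesh& m, Pad3& out) {
  out.init(2, m.nx, m.ny, m.nz);
  for (int k = 0; k < m.nz; ++k)
    for (int j = 0; j < m.ny; ++j)
      std::memcpy(&out.at(0, j, k), &f[m.cidx(0, j, k)],
                  sizeof(double) * m.nx);
  for (int k = -2; k < m.nz + 2; ++k)
    for (int j = -2; j < m.ny + 2; ++j) {
      bool jk_in = j >= 0 && j < m.ny && k >= 0 && k < m.nz;
      for (int i = -2; i < m.nx + 2; ++i) {
        if (jk_in && i >= 0 && i < m.nx) { i = m.nx - 1; continue; }
        out.at(i, j, k) = cget(f, m, i, j, k);
      }
    }
}

static inline double muscl(double um1, double u0, double up1, double up2,
                           double vel) {
  if (vel > 0.0) return u0 + 0.5 * minmod(u0 - um1, up1 - u0);
  if (vel < 0.0) return up1 - 0.5 * minmod(up1 - u0, up2 - up1);
  return 0.5 * (u0 + up1);
}

// explicit momentum right-hand side (advection + viscous + elastic + source)
// for component d on its face grid; rhs must be pre-sized
static void momentum_rhs_comp(int d, const Pad3 upad[3], const Pad3& nupad,
                              const std::vector<double>& fel, const Mesh& m,
                              double Sforce, int force_axis,
                              std::vector<double>& rhs) {
  FaceDims fd(m, d);
  double dx = m.dx;
  double idx = 1.0 / dx, idx2 = 1.0 / (dx * dx);
  int ndim = m.nz > 1 ? 3 : 2;
  int own_hi = m.per[d] ? m.n(d) - 1 : m.n(d); // periodic: face n synced later
  const Pad3& U = upad[d];
  const double* Ua = U.a.data();
  const double* Na = nupad.a.data();
  long us[3] = {1, U.s1, U.s2};
  long ns[3] = {1, nupad.s1, nupad.s2};
  for (int k = 0; k < fd.fn[2]; ++k)
    for (int j = 0; j < fd.fn[1]; ++j) {
      long urow = (0 + U.g) + U.s1 * (j + U.g) + U.s2 * (k + U.g);
      long nrow = (0 + nupad.g) + nupad.s1 * (j + nupad.g) +
                  nupad.s2 * (k + nupad.g);
      long frow = fd.idx(0, j, k);
      int q3r[3] = {0, j, k};
      for (int i = 0; i < fd.fn[0]; ++i) {
        q3r[0] = i;
        if (q3r[d] > own_hi) continue;
        long ub = urow + i;        // padded index of this face in U
        long nb = nrow + i;        // padded index of cell (i,j,k) in nu
        double adv = 0.0, visc = 0.0;
        for (int e = 0; e < ndim; ++e) {
          long se = us[e];
          if (e == d) {
            double u0 = Ua[ub];
            double um1 = Ua[ub - se], up1 = Ua[ub + se], up2 = Ua[ub + 2 * se];
            double um2 = Ua[ub - 2 * se];
            double ubh = 0.5 * (u0 + up1);
            double Fhi = ubh * muscl(um1, u0, up1, up2, ubh);
            double ubl = 0.5 * (um1 + u0);
            double Flo = ubl * muscl(um2, um1, u0, up1, ubl);
            adv += (Fhi - Flo) * idx;
            double nu_hi = Na[nb];                 // cell on + side of face
            double nu_lo = Na[nb - ns[d]];
            visc += 2.0 * (nu_hi * (up1 - u0) - nu_lo * (u0 - um1)) * idx2;
          } else {
            const Pad3& W = upad[e];
            const double* Wa = W.a.data();
            long wb = (q3r[0] + W.g) + W.s1 * (q3r[1] + W.g) +
                      W.s2 * (q3r[2] + W.g);
            long wse = (e == 0 ? 1 : (e == 1 ? W.s1 : W.s2));
            long wsd = (d == 0 ? 1 : (d == 1 ? W.s1 : W.s2));
            long nse = ns[e], nsd = ns[d];
            // advecting u_e at the low/high edges bounding this face
            double wlo = 0.5 * (Wa[wb - wsd] + Wa[wb]);
            double whi = 0.5 * (Wa[wb + wse - wsd] + Wa[wb + wse]);
            double um2 = Ua[ub - 2 * se], um1 = Ua[ub - se], u0 = Ua[ub];
            double up1 = Ua[ub + se], up2 = Ua[ub + 2 * se];
            double Fhi = whi * muscl(um1, u0, up1, up2, whi);
            double Flo = wlo * muscl(um2, um1, u0, up1, wlo);
            adv += (Fhi - Flo) * idx;
            // transverse viscous: d/dx_e ( nu (du_d/dx_e + du_e/dx_d) )
            double nu_lo = 0.25 * (Na[nb] + Na[nb - nsd] + Na[nb - nse] +
                                   Na[nb - nsd - nse]);
            double nu_hi = 0.25 * (Na[nb] + Na[nb - nsd] + Na[nb + nse] +
                                   Na[nb + nse - nsd]);
            double glo = (u0 - um1) * idx + (Wa[wb] - Wa[wb - wsd]) * idx;
            double ghi = (up1 - u0) * idx +
                         (Wa[wb + wse] - Wa[wb + wse - wsd]) * idx;
            visc += (nu_hi * ghi - nu_lo * glo) * idx;
          }
        }
        long fi = frow + i;
        double src = (d == force_axis) ? Sforce : 0.0;
        rhs[fi] = -adv + visc + fel[fi] + src;
      }
    }
}

// options bundle -----------------------------------------------------------
struct RunOpts {
  double co = 0.1, nu_f = 0.01, nu_s = 0.01, G = 0.0;
  double alpha_min = 0.1;
  bool reset_unit = true, zero_alpha_clip = false;
  bool solid_on = true, advect_on = true, evolve_b_on = true;
  int n_outer = 2;
  bool forcing_on = false;
  double target_mean = 0.5;
  int poisson_kind = 0; // 0 transform, 1 pcg
  bool x_periodic = true;
  bool dir_xlo = false, dir_xhi = false;
  double p_xlo = 0.0, p_xhi = 0.0;
  double div_tol = 5e-9;
  int pcg_maxit = 20000;
  int rdf_iters = 2;
  double dt_fixed = 0.0, dt_init = 1e-4;
  double blow_u = 50.0, blow_b = 1e6;
  int record_every = 10, snapshot_every = 0;
  int nsteps = 0;
  double t_end = 0.0;
  bool track_shape = false;
  double iso_level = 0.5;
  VelBCs bc;
};

struct SimState {
  Mesh m;
  std::vector<double> alpha, ux, uy, uz, p;
  std::vector<double> B[6];
  PlicState plic;
  std::vector<double> trx, trY, trz; // Lagrangian tracers
  double t = 0.0, S = 0.0;
  long step = 0;
};

// trilinear interpolation of one staggered component at a point
static double interp_face(const std::vector<double>& u, const Mesh& m, int d,
                          double x, double y, double z) {
  FaceDims fd(m, d);
  // face-grid coordinates: along d faces sit at q*dx, transverse at centers
  double gx = x / m.dx - (d == 0 ? 0.0 : 0.5);
  double gy = y / m.dx - (d == 1 ? 0.0 : 0.5);
  double gz = z / m.dx - (d == 2 ? 0.0 : 0.5);
  if (m.nz == 1) gz = 0.0;
  auto clampi = [&](double g, int lim) {
    int i0 = (int)std::floor(g);
    if (i0 < 0) i0 = 0;
    if (i0 > lim - 2) i0 = lim - 2;
    return i0;
  };
  int i0 = fd.fn[0] > 1 ? clampi(gx, fd.fn[0]) : 0;
  int j0 = fd.fn[1] > 1 ? clampi(gy, fd.fn[1]) : 0;
  int k0 = fd.fn[2] > 1 ? clampi(gz, fd.fn[2]) : 0;
  double fx2 = fd.fn[0] > 1 ? std::min(1.0, std::max(0.0, gx - i0)) : 0.0;
  double fy2 = fd.fn[1] > 1 ? std::min(1.0, std::max(0.0, gy - j0)) : 0.0;
  double fz2 = fd.fn[2] > 1 ? std::min(1.0, std::max(0.0, gz - k0)) : 0.0;
  double acc = 0.0;
  for (int dk = 0; dk <= (fd.fn[2] > 1 ? 1 : 0); ++dk)
    for (int dj = 0; dj <= 1; ++dj)
      for (int di = 0; di <= 1; ++di) {
        double w = (di ? fx2 : 1 - fx2) * (dj ? fy2 : 1 - fy2) *
                   (fd.fn[2] > 1 ? (dk ? fz2 : 1 - fz2) : 1.0);
        acc += w * u[fd.idx(i0 + di, j0 + dj, k0 + dk)];
      }
  return acc;
}

static void advect_tracers(SimState& st, double dt) {
  if (st.trx.empty()) return;
  const Mesh& m = st.m;
  double Lx = m.nx * m.dx, Ly = m.ny * m.dx, Lz = m.nz * m.dx;
  for (size_t p = 0; p < st.trx.size(); ++p) {
    double x = st.trx[p], y = st.trY[p], z = st.trz[p];
    double u1 = interp_face(st.ux, m, 0, x, y, z);
    double v1 = interp_face(st.uy, m, 1, x, y, z);
    double w1 = m.nz > 1 ? interp_face(st.uz, m, 2, x, y, z) : 0.0;
    double xm = x + dt * u1, ym = y + dt * v1, zm = z + dt * w1;
    double u2 = interp_face(st.ux, m, 0, xm, ym, zm);
    double v2 = interp_face(st.uy, m, 1, xm, ym, zm);
    double w2 = m.nz > 1 ? interp_face(st.uz, m, 2, xm, ym, zm) : 0.0;
    x += 0.5 * dt * (u1 + u2);
    y += 0.5 * dt * (v1 + v2);
    z += 0.5 * dt * (w1 + w2);
    if (m.per[0]) x = pmod(x, Lx);
    if (m.per[1]) y = pmod(y, Ly);
    if (m.nz > 1 && m.per[2]) z = pmod(z, Lz);
    st.trx[p] = x; st.trY[p] = y; st.trz[p] = z;
  }
}

static double bulk_velocity(const SimState& st) {
  const Mesh& m = st.m;
  FaceDims fx(m, 0);
  double acc = 0.0; long nfl = 0;
  for (int k = 0; k < m.nz; ++k)
    for (int j = 0; j < m.ny; ++j)
      for (int i = 0; i < m.nx; ++i) {
        if (m.is_wall(i, j, k)) continue;
        acc += 0.5 * (st.ux[fx.idx(i, j, k)] + st.ux[fx.idx(i + 1, j, k)]);
        nfl++;
      }
  return nfl > 0 ? acc / nfl : 0.0;
}

static double max_div(const SimState& st) {
  const Mesh& m = st.m;
  FaceDims fx(m, 0), fy(m, 1), fz(m, 2);
  double md = 0.0;
  for (int k = 0; k < m.nz; ++k)
    for (int j = 0; j < m.ny; ++j)
      for (int i = 0; i < m.nx; ++i) {
        if (m.is_wall(i, j, k)) continue;
        double d = (st.ux[fx.idx(i + 1, j, k)] - st.ux[fx.idx(i, j, k)]) +
                   (st.uy[fy.idx(i, j + 1, k)] - st.uy[fy.idx(i, j, k)]);
        if (m.nz > 1)
          d += (st.uz[fz.idx(i, j, k + 1)] - st.uz[fz.idx(i, j, k)]);
        md = std::max(md, std::fabs(d / m.dx));
      }
  return md;
}

// shape diagnostics: alpha-weighted centroid (periodic x unwrapped by the
// circular mean) and the orientation angle from the gyration tensor of the
// iso-level vertices
static void shape_diag(const SimState& st, double iso_level, double out[4]) {
  const Mesh& m = st.m;
  double dx = m.dx;
  double Lx = m.nx * dx;
  double sa = 0.0, sc = 0.0, ss = 0.0, sy = 0.0, sz = 0.0;
  for (int k = 0; k < m.nz; ++k)
    for (int j = 0; j < m.ny; ++j)
      for (int i = 0; i < m.nx; ++i) {
        double a = st.alpha[m.cidx(i, j, k)];
        if (a <= 0.0) continue;
        double th = 2.0 * M_PI * (i + 0.5) / m.nx;
        sa += a; sc += a * std::cos(th); ss += a * std::sin(th);
        sy += a * ((j + 0.5) * dx);
        sz += a * ((k + 0.5) * dx);
      }
  if (sa <= 0.0) { out[0] = out[1] = out[2] = out[3] = NA_REAL; return; }
  double thc = std::atan2(ss, sc);
  double xc_ref = thc / (2.0 * M_PI) * Lx;
  // refine with unwrapped weighted mean around the circular-mean position
  double sx = 0.0;
  for (int k = 0; k < m.nz; ++k)
    for (int j = 0; j < m.ny; ++j)
      for (int i = 0; i < m.nx; ++i) {
        double a = st.alpha[m.cidx(i, j, k)];
        if (a <= 0.0) continue;
        double x = (i + 0.5) * dx;
        if (m.per[0]) {
          double dxx = pmod(x - xc_ref + 1.5 * Lx, Lx) - 0.5 * Lx;
          x = xc_ref + dxx;
        }
        sx += a * x;
      }
  double xc = sx / sa, yc = sy / sa, zc = sz / sa;
  out[0] = m.per[0] ? pmod(xc + Lx, Lx) : xc;
  out[1] = yc; out[2] = zc;
  out[3] = NA_REAL;
  if (m.nz > 1) {
    std::vector<double> X, Y, Z;
    isosurface_vertices(st.alpha, m, iso_level, X, Y, Z);
    if (X.size() >= 100) {
      // unwrap vertices along periodic x about the centroid
      arma::mat G(3, 3, arma::fill::zeros);
      double mx = 0.0, my = 0.0, mz = 0.0;
      std::vector<double> Xu(X.size());
      for (size_t v = 0; v < X.size(); ++v) {
        double x = X[v];
        if (m.per[0]) {
          double dxx = pmod(x - xc + 1.5 * Lx, Lx) - 0.5 * Lx;
          x = xc + dxx;
        }
        Xu[v] = x; mx += x; my += Y[v]; mz += Z[v];
      }
      mx /= X.size(); my /= X.size(); mz /= X.size();
      for (size_t v = 0; v < X.size(); ++v) {
        double r[3] = {Xu[v] - mx, Y[v] - my, Z[v] - mz};
        for (int a = 0; a < 3; ++a)
          for (int b = 0; b < 3; ++b) G(a, b) += r[a] * r[b];
      }
      G /= (double)X.size();
      arma::vec ev; arma::mat evec;
      if (arma::eig_sym(ev, evec, G)) {
        arma::vec n = evec.col(0);
        double cosp = std::fabs(n[0]);
        if (cosp > 1.0) cosp = 1.0;
        out[3] = std::acos(cosp) * 180.0 / M_PI;
      }
    }
  }
}

// one coupled time step; returns false on divergence
static bool fsi_step(SimState& st, const RunOpts& o, PoissonTransform* ptr,
                     PoissonPCG* pcg, double& dt_out, double& lost_out,
                     std::string& err) {
  const Mesh& m = st.m;
  double dx = m.dx;
  FaceDims fx(m, 0), fy(m, 1), fz(m, 2);
  // time step
  double umax = 0.0;
  for (double v : st.ux) umax = std::max(umax, std::fabs(v));
  for (double v : st.uy) umax = std::max(umax, std::fabs(v));
  for (double v : st.uz) umax = std::max(umax, std::fabs(v));
  if (umax > o.blow_u) { err = "velocity blow-up"; return false; }
  double dt;
  if (o.dt_fixed > 0.0) dt = o.dt_fixed;
  else {
    double numax = std::max(o.nu_f, o.nu_s);
    dt = o.co * dx / std::max(umax, 1e-12);
    // explicit diffusion: stay at half the planar FTCS stability limit
    // (the marginal 0.75 factor leaves a slowly growing oscillatory mode)
    dt = std::min(dt, dx * dx / (12.0 * numax));
    if (o.G > 0.0) dt = std::min(dt, 0.5 * dx / std::sqrt(o.G));
    dt = std::min(dt, o.dt_init * std::pow(1.2, (double)st.step + 1));
  }
  if (dt < 1e-10) { err = "time step collapsed"; return false; }
  dt_out = dt;
  lost_out = 0.0;

  // Scheme: interface advection -> Btilde evolution -> momentum
  if (o.solid_on && o.advect_on) {
    vof_advect(st.alpha, st.ux, st.uy, st.uz, m, dt, (int)(st.step % 3),
               o.rdf_iters, st.plic, &lost_out);
  }
  if (o.solid_on && o.evolve_b_on) {
    double bmax = evolve_btilde(st.B, st.ux, st.uy, st.uz, m, dt, 3,
                                &st.alpha);
    if (bmax > o.blow_b) { err = "deformation tensor blow-up"; return false; }
    clip_btilde(st.B, st.alpha, m, o.alpha_min, o.reset_unit, o.zero_alpha_clip);
  }

  // mixture kinematic viscosity
  std::vector<double> nu(m.N());
  for (long c = 0; c < m.N(); ++c)
    nu[c] = o.nu_f + st.alpha[c] * (o.nu_s - o.nu_f);
  Pad3 nupad; pad_cells(nu, m, nupad);

  // elastic force (fixed over the outer correctors; alpha and B are frozen)
  std::vector<double> felx(fx.size(), 0.0), fely(fy.size(), 0.0),
      felz(fz.size(), 0.0);
  if (o.solid_on && o.G > 0.0)
    elastic_force(st.B, st.alpha, m, o.G, felx, fely, felz);

  std::vector<double> ux0 = st.ux, uy0 = st.uy, uz0 = st.uz;
  int ndim = m.nz > 1 ? 3 : 2;
  for (int outer = 0; outer < std::max(1, o.n_outer); ++outer) {
            Pad3 upad[3];
    pad_component(st.ux, m, o.bc, 0, upad[0]);
    pad_component(st.uy, m, o.bc, 1, upad[1]);
    if (ndim == 3) pad_component(st.uz, m, o.bc, 2, upad[2]);
    else upad[2].init(2, m.nx, m.ny, m.nz + 1);
            std::vector<double> rhs[3];
    rhs[0].assign(fx.size(), 0.0);
    rhs[1].assign(fy.size(), 0.0);
    rhs[2].assign(fz.size(), 0.0);
    momentum_rhs_comp(0, upad, nupad, felx, m, st.S, 0, rhs[0]);
    momentum_rhs_comp(1, upad, nupad, fely, m, st.S, 0, rhs[1]);
    if (ndim == 3) momentum_rhs_comp(2, upad, nupad, felz, m, st.S, 0, rhs[2]);
            // predictor from the step-start velocity
    for (size_t f = 0; f < st.ux.size(); ++f) st.ux[f] = ux0[f] + dt * rhs[0][f];
    for (size_t f = 0; f < st.uy.size(); ++f) st.uy[f] = uy0[f] + dt * rhs[1][f];
    if (ndim == 3)
      for (size_t f = 0; f < st.uz.size(); ++f) st.uz[f] = uz0[f] + dt * rhs[2][f];
    // boundary faces along own axis: walls stay zero
    for (int d = 0; d < ndim; ++d) {
      std::vector<double>& u = d == 0 ? st.ux : (d == 1 ? st.uy : st.uz);
      FaceDims fd(m, d);
      if (!m.per[d]) {
        for (int side = 0; side < 2; ++side) {
          if (o.bc.kind[d][side] != 1) continue;
          int qf = side == 0 ? 0 : fd.fn[d] - 1;
          for (int k = 0; k < fd.fn[2]; ++k)
            for (int j = 0; j < fd.fn[1]; ++j)
              for (int i = 0; i < fd.fn[0]; ++i) {
                int q = (d == 0 ? i : (d == 1 ? j : k));
                if (q == qf) u[fd.idx(i, j, k)] = 0.0;
              }
        }
      }
      zero_wall_faces(u, fd, m, d);
      sync_periodic_faces(u, fd, m, d);
    }
    // projection
    std::vector<double> rhsdiv(m.N(), 0.0);
    for (int k = 0; k < m.nz; ++k)
      for (int j = 0; j < m.ny; ++j)
        for (int i = 0; i < m.nx; ++i) {
          if (m.is_wall(i, j, k)) continue;
          double dv = (st.ux[fx.idx(i + 1, j, k)] - st.ux[fx.idx(i, j, k)]) +
                      (st.uy[fy.idx(i, j + 1, k)] - st.uy[fy.idx(i, j, k)]);
          if (ndim == 3)
            dv += (st.uz[fz.idx(i, j, k + 1)] - st.uz[fz.idx(i, j, k)]);
          rhsdiv[m.cidx(i, j, k)] = dv / dx;
        }
            std::vector<double> psi;
    if (o.poisson_kind == 0) {
      ptr->solve(rhsdiv, psi, m);
    } else {
      pcg->dir_xlo = o.dir_xlo; pcg->dir_xhi = o.dir_xhi;
      pcg->val_xlo = o.p_xlo * dt; pcg->val_xhi = o.p_xhi * dt;
      // warm start from the carried pressure, rescaled to the current dt so
      // the iteration is identical within a run and across a restart
      pcg->phi_prev.assign(m.N(), 0.0);
      for (long c = 0; c < m.N(); ++c) pcg->phi_prev[c] = st.p[c] * dt;
      int rc = pcg->solve(rhsdiv, psi, m, o.div_tol, o.pcg_maxit);
      if (rc != 0) { err = "pressure solver did not converge"; return false; }
    }
            // velocity correction
    for (int k = 0; k < m.nz; ++k)
      for (int j = 0; j < m.ny; ++j)
        for (int i = 0; i <= m.nx; ++i) {
          bool lo_in = i > 0, hi_in = i < m.nx;
          double pl, pr;
          if (!lo_in && !m.per[0]) {
            if (!o.dir_xlo) continue;
            pr = psi[m.cidx(i, j, k)];
            if (m.is_wall(i, j, k)) continue;
            pl = 2.0 * (o.p_xlo * dt) - pr;
          } else if (!hi_in && !m.per[0]) {
            if (!o.dir_xhi) continue;
            pl = psi[m.cidx(i - 1, j, k)];
            if (m.is_wall(i - 1, j, k)) continue;
            pr = 2.0 * (o.p_xhi * dt) - pl;
          } else {
            int il = m.wrap(i - 1, 0), ir = m.wrap(i, 0);
            if (m.is_wall(il, j, k) || m.is_wall(ir, j, k)) continue;
            pl = psi[m.cidx(il, j, k)];
            pr = psi[m.cidx(ir, j, k)];
          }
          st.ux[fx.idx(i, j, k)] -= (pr - pl) / dx;
        }
    for (int k = 0; k < m.nz; ++k)
      for (int j = 0; j <= m.ny; ++j)
        for (int i = 0; i < m.nx; ++i) {
          bool lo_in = j > 0, hi_in = j < m.ny;
          if ((!lo_in || !hi_in) && !m.per[1]) continue;
          int jl = m.wrap(j - 1, 1), jr = m.wrap(j, 1);
          if (m.is_wall(i, jl, k) || m.is_wall(i, jr, k)) continue;
          st.uy[fy.idx(i, j, k)] -=
            (psi[m.cidx(i, jr, k)] - psi[m.cidx(i, jl, k)]) / dx;
        }
    if (ndim == 3)
      for (int k = 0; k <= m.nz; ++k)
        for (int j = 0; j < m.ny; ++j)
          for (int i = 0; i < m.nx; ++i) {
            bool lo_in = k > 0, hi_in = k < m.nz;
            if ((!lo_in || !hi_in) && !m.per[2]) continue;
            int kl = m.wrap(k - 1, 2), kr = m.wrap(k, 2);
            if (m.is_wall(i, j, kl) || m.is_wall(i, j, kr)) continue;
            st.uz[fz.idx(i, j, k)] -=
              (psi[m.cidx(i, j, kr)] - psi[m.cidx(i, j, kl)]) / dx;
          }
    for (int d = 0; d < ndim; ++d) {
      std::vector<double>& u = d == 0 ? st.ux : (d == 1 ? st.uy : st.uz);
      FaceDims fd(m, d);
      zero_wall_faces(u, fd, m, d);
      sync_periodic_faces(u, fd, m, d);
    }
    st.p.assign(psi.begin(), psi.end());
    for (double& v : st.p) v /= dt;
  }

  // mean-flow forcing controller (periodic pipes)
  if (o.forcing_on) {
    double ub = bulk_velocity(st);
    double dS = (o.target_mean - ub) / dt;
    for (int k = 0; k < m.nz; ++k)
      for (int j = 0; j < m.ny; ++j)
        for (int i = 0; i <= m.nx; ++i) {
          int il = m.wrap(i - 1, 0), ir = m.wrap(i, 0);
          if (m.is_wall(il, j, k) || m.is_wall(ir, j, k)) continue;
          st.ux[fx.idx(i, j, k)] += dS * dt;
        }
    sync_periodic_faces(st.ux, fx, m, 0);
    st.S += dS;
  }
  advect_tracers(st, dt);
  st.t += dt;
  st.step += 1;
  return true;
}

// ------------------------------------------------------------------ glue
static Mesh mesh_from_list(const Rcpp::List& gl) {
  Mesh m;
  Rcpp::IntegerVector dim = gl["dim"];
  m.nx = dim[0]; m.ny = dim.size() > 1 ? dim[1] : 1;
  m.nz = dim.size() > 2 ? dim[2] : 1;
  m.dx = Rcpp::as<double>(gl["dx"]);
  Rcpp::LogicalVector per = gl["periodic"];
  for (int d = 0; d < 3; ++d)
    m.per[d] = d < per.size() ? (bool)per[d] : true;
  if (dim.size() == 2) m.per[2] = true;
  if (gl.containsElementNamed("wall") && !Rf_isNull(gl["wall"])) {
    Rcpp::LogicalVector w = gl["wall"];
    if (w.size() == m.N()) {
      bool any = false;
      for (long c = 0; c < (long)w.size(); ++c) if (w[c]) { any = true; break; }
      if (any) {
        m.wall.assign(w.size(), 0);
        for (long c = 0; c < (long)w.size(); ++c) m.wall[c] = w[c] ? 1 : 0;
      }
    }
  }
  return m;
}

static void fill_opts(RunOpts& o, const Rcpp::List& ol) {
  auto getd = [&](const char* n, double dflt) {
    return ol.containsElementNamed(n) ? Rcpp::as<double>(ol[n]) : dflt;
  };
  auto geti = [&](const char* n, int dflt) {
    return ol.containsElementNamed(n) ? Rcpp::as<int>(ol[n]) : dflt;
  };
  auto getb = [&](const char* n, bool dflt) {
    return ol.containsElementNamed(n) ? Rcpp::as<bool>(ol[n]) : dflt;
  };
  o.co = getd("co", o.co);
  o.nu_f = getd("nu_f", o.nu_f);
  o.nu_s = getd("nu_s", o.nu_s);
  o.G = getd("G", o.G);
  o.alpha_min = getd("alpha_min", o.alpha_min);
  o.reset_unit = getb("reset_unit", o.reset_unit);
  o.zero_alpha_clip = getb("zero_alpha_clip", o.zero_alpha_clip);
  o.solid_on = getb("solid_on", o.solid_on);
  o.advect_on = getb("advect_on", o.advect_on);
  o.evolve_b_on = getb("evolve_b_on", o.evolve_b_on);
  o.n_outer = geti("n_outer", o.n_outer);
  o.forcing_on = getb("forcing_on", o.forcing_on);
  o.target_mean = getd("target_mean", o.target_mean);
  o.poisson_kind = geti("poisson_kind", o.poisson_kind);
  o.x_periodic = getb("x_periodic", o.x_periodic);
  o.dir_xlo = getb("dir_xlo", o.dir_xlo);
  o.dir_xhi = getb("dir_xhi", o.dir_xhi);
  o.p_xlo = getd("p_xlo", o.p_xlo);
  o.p_xhi = getd("p_xhi", o.p_xhi);
  o.div_tol = getd("div_tol", o.div_tol);
  o.pcg_maxit = geti("pcg_maxit", o.pcg_maxit);
  o.rdf_iters = geti("rdf_iters", o.rdf_iters);
  o.dt_fixed = getd("dt_fixed", o.dt_fixed);
  o.dt_init = getd("dt_init", o.dt_init);
  o.blow_u = getd("blow_u", o.blow_u);
  o.blow_b = getd("blow_b", o.blow_b);
  o.record_every = geti("record_every", o.record_every);
  o.snapshot_every = geti("snapshot_every", o.snapshot_every);
  o.nsteps = geti("nsteps", o.nsteps);
  o.t_end = getd("t_end", o.t_end);
  o.track_shape = getb("track_shape", o.track_shape);
  o.iso_level = getd("iso_level", o.iso_level);
  if (ol.containsElementNamed("vel_kind")) {
    Rcpp::IntegerMatrix vk = ol["vel_kind"]; // 3 x 2
    for (int a = 0; a < 3; ++a)
      for (int s = 0; s < 2; ++s) o.bc.kind[a][s] = vk(a, s);
  }
  if (ol.containsElementNamed("vel_tang")) {
    Rcpp::NumericMatrix vt = ol["vel_tang"]; // 6 x 3 (xlo,xhi,ylo,yhi,zlo,zhi)
    for (int a = 0; a < 3; ++a)
      for (int s = 0; s < 2; ++s)
        for (int c = 0; c < 3; ++c) o.bc.tang[a][s][c] = vt(2 * a + s, c);
  }
}

static SimState state_from_list(const Rcpp::List& gl, const Rcpp::List& sl) {
  SimState st;
  st.m = mesh_from_list(gl);
  Rcpp::NumericVector a = sl["alpha"];
  st.alpha.assign(a.begin(), a.end());
  Rcpp::List u = sl["u"];
  Rcpp::NumericVector ux = u[0], uy = u[1];
  st.ux.assign(ux.begin(), ux.end());
  st.uy.assign(uy.begin(), uy.end());
  if (u.size() > 2) {
    Rcpp::NumericVector uz = u[2];
    st.uz.assign(uz.begin(), uz.end());
  } else st.uz.assign((long)st.m.nx * st.m.ny * (st.m.nz + 1), 0.0);
  Rcpp::NumericVector p = sl["p"];
  st.p.assign(p.begin(), p.end());
  Rcpp::List B = sl["btilde"];
  for (int c = 0; c < 6; ++c) {
    Rcpp::NumericVector bc = B[c];
    st.B[c].assign(bc.begin(), bc.end());
  }
  st.t = Rcpp::as<double>(sl["t"]);
  st.S = Rcpp::as<double>(sl["S"]);
  st.step = (long)Rcpp::as<double>(sl["step"]);
  if (sl.containsElementNamed("tracers") && !Rf_isNull(sl["tracers"])) {
    Rcpp::NumericMatrix tr = sl["tracers"];
    for (int p = 0; p < tr.nrow(); ++p) {
      st.trx.push_back(tr(p, 0));
      st.trY.push_back(tr.ncol() > 1 ? tr(p, 1) : 0.0);
      st.trz.push_back(tr.ncol() > 2 ? tr(p, 2) : 0.0);
    }
  }
  if (sl.containsElementNamed("plic_normals") && !Rf_isNull(sl["plic_normals"])) {
    Rcpp::NumericMatrix pn = sl["plic_normals"];
    if ((long)pn.nrow() == st.m.N()) {
      st.plic.resize(st.m.N());
      for (long c = 0; c < st.m.N(); ++c) {
        st.plic.nxv[c] = pn(c, 0); st.plic.nyv[c] = pn(c, 1);
        st.plic.nzv[c] = pn(c, 2);
      }
    }
  }
  return st;
}

static Rcpp::List state_to_list(const SimState& st, const Rcpp::List& gl) {
  Rcpp::IntegerVector dim = gl["dim"];
  int ndim = dim.size();
  Rcpp::NumericVector a(st.alpha.begin(), st.alpha.end());
  a.attr("dim") = dim;
  Rcpp::List u;
  {
    Rcpp::NumericVector ux(st.ux.begin(), st.ux.end());
    Rcpp::NumericVector uy(st.uy.begin(), st.uy.end());
    if (ndim == 2) {
      ux.attr("dim") = Rcpp::IntegerVector::create(st.m.nx + 1, st.m.ny);
      uy.attr("dim") = Rcpp::IntegerVector::create(st.m.nx, st.m.ny + 1);
      u = Rcpp::List::create(Rcpp::Named("x") = ux, Rcpp::Named("y") = uy);
    } else {
      Rcpp::NumericVector uz(st.uz.begin(), st.uz.end());
      ux.attr("dim") = Rcpp::IntegerVector::create(st.m.nx + 1, st.m.ny, st.m.nz);
      uy.attr("dim") = Rcpp::IntegerVector::create(st.m.nx, st.m.ny + 1, st.m.nz);
      uz.attr("dim") = Rcpp::IntegerVector::create(st.m.nx, st.m.ny, st.m.nz + 1);
      u = Rcpp::List::create(Rcpp::Named("x") = ux, Rcpp::Named("y") = uy,
                             Rcpp::Named("z") = uz);
    }
  }
  Rcpp::NumericVector p(st.p.begin(), st.p.end());
  p.attr("dim") = dim;
  Rcpp::List B(6);
  for (int c = 0; c < 6; ++c) {
    Rcpp::NumericVector bc(st.B[c].begin(), st.B[c].end());
    bc.attr("dim") = dim;
    B[c] = bc;
  }
  Rcpp::NumericMatrix pn(st.m.N(), 3);
  if ((long)st.plic.nxv.size() == st.m.N()) {
    for (long c = 0; c < st.m.N(); ++c) {
      pn(c, 0) = st.plic.nxv[c]; pn(c, 1) = st.plic.nyv[c];
      pn(c, 2) = st.plic.nzv[c];
    }
  }
  Rcpp::NumericMatrix tr(st.trx.size(), 3);
  for (size_t p2 = 0; p2 < st.trx.size(); ++p2) {
    tr(p2, 0) = st.trx[p2]; tr(p2, 1) = st.trY[p2]; tr(p2, 2) = st.trz[p2];
  }
  return Rcpp::List::create(
    Rcpp::Named("alpha") = a, Rcpp::Named("u") = u, Rcpp::Named("p") = p,
    Rcpp::Named("btilde") = B, Rcpp::Named("t") = st.t,
    Rcpp::Named("S") = st.S, Rcpp::Named("step") = (double)st.step,
    Rcpp::Named("plic_normals") = pn,
    Rcpp::Named("tracers") = tr);
}

// [[Rcpp::export]]
Rcpp::List cpp_fsi_run(Rcpp::List grid, Rcpp::List state, Rcpp::List opts) {
  RunOpts o;
  fill_opts(o, opts);
  SimState st = state_from_list(grid, state);
  const Mesh& m = st.m;
  PoissonTransform ptrans;
  PoissonPCG pcg;
  if (o.poisson_kind == 0) ptrans.setup(m, m.per[0] ? 0 : 1);
  Mesh mprec;
  if (o.poisson_kind == 1) {
    // fictitious-domain preconditioner: same grid with the x-invariant
    // envelope of the fluid region (union over x of fluid cross-sections)
    mprec = m;
    if (m.has_wall()) {
      for (int k = 0; k < m.nz; ++k)
        for (int j = 0; j < m.ny; ++j) {
          bool any_fluid = false;
          for (int i = 0; i < m.nx; ++i)
            if (!m.is_wall(i, j, k)) { any_fluid = true; break; }
          for (int i = 0; i < m.nx; ++i)
            mprec.wall[mprec.cidx(i, j, k)] = any_fluid ? 0 : 1;
        }
    }
    int xbc = m.per[0] ? 0 : ((o.dir_xlo || o.dir_xhi) ? 2 : 1);
    ptrans.setup(mprec, xbc);
    pcg.precond = &ptrans;
    pcg.precond_mesh = mprec;
  }
  int nrec_cols = 16;
  std::vector<double> series;
  std::vector<Rcpp::List> snapshots;
  std::string err;
  bool diverged = false;
  long steps_done = 0;
  auto record = [&](double dt, double lost) {
    double diag[4];
    if (o.track_shape) shape_diag(st, o.iso_level, diag);
    else diag[0] = diag[1] = diag[2] = diag[3] = NA_REAL;
    double vol = 0.0;
    for (double a : st.alpha) vol += a;
    vol *= std::pow(m.dx, m.nz > 1 ? 3 : 2);
    double qin = 0.0, qout = 0.0;
    {
      FaceDims fx(m, 0);
      for (int k = 0; k < m.nz; ++k)
        for (int j = 0; j < m.ny; ++j) {
          qin += st.ux[fx.idx(0, j, k)];
          qout += st.ux[fx.idx(m.nx, j, k)];
        }
      qin *= std::pow(m.dx, m.nz > 1 ? 2 : 1);
      qout *= std::pow(m.dx, m.nz > 1 ? 2 : 1);
    }
    double dpm = 0.0;
    {
      double plo = 0.0, phi2 = 0.0; long nlo = 0, nhi = 0;
      for (int k = 0; k < m.nz; ++k)
        for (int j = 0; j < m.ny; ++j) {
          if (!m.is_wall(0, j, k)) { plo += st.p[m.cidx(0, j, k)]; nlo++; }
          if (!m.is_wall(m.nx - 1, j, k)) {
            phi2 += st.p[m.cidx(m.nx - 1, j, k)]; nhi++;
          }
        }
      if (nlo > 0 && nhi > 0) dpm = plo / nlo - phi2 / nhi;
    }
    double row[16] = {st.t, dt, st.S, bulk_velocity(st), vol, max_div(st),
                      lost, diag[0], diag[1], diag[2], diag[3], qin, qout,
                      dpm, (double)pcg.last_iters, (double)st.step};
    series.insert(series.end(), row, row + nrec_cols);
  };
  record(0.0, 0.0);
  long nmax = o.nsteps;
  while (o.nsteps > 0 || o.t_end > 0.0) {
    if (nmax > 0 && steps_done >= nmax) break;
    if (o.t_end > 0.0 && st.t >= o.t_end) break;
    double dt = 0.0, lost = 0.0;
    bool ok;
    try {
      ok = fsi_step(st, o, &ptrans, &pcg, dt, lost, err);
    } catch (std::exception& e) {
      ok = false; err = e.what();
    }
    if (!ok) { diverged = true; break; }
    steps_done++;
    if (o.record_every > 0 && (st.step % o.record_every == 0)) record(dt, lost);
    if (o.snapshot_every > 0 && (st.step % o.snapshot_every == 0)) {
      Rcpp::List gl2 = grid;
      snapshots.push_back(state_to_list(st, gl2));
    }
    Rcpp::checkUserInterrupt();
  }
  long nrow = series.size() / nrec_cols;
  Rcpp::NumericMatrix ser(nrow, nrec_cols);
  for (long r = 0; r < nrow; ++r)
    for (int c = 0; c < nrec_cols; ++c) ser(r, c) = series[r * nrec_cols + c];
  Rcpp::CharacterVector cn = Rcpp::CharacterVector::create(
    "t", "dt", "S", "bulk_velocity", "solid_volume", "max_div", "vof_lost",
    "xc", "yc", "zc", "psi", "q_in", "q_out", "dp", "poisson_iters", "step");
  Rcpp::colnames(ser) = cn;
  Rcpp::List snaps(snapshots.size());
  for (size_t s = 0; s < snapshots.size(); ++s) snaps[s] = snapshots[s];
  return Rcpp::List::create(
    Rcpp::Named("state") = state_to_list(st, grid),
    Rcpp::Named("series") = ser,
    Rcpp::Named("snapshots") = snaps,
    Rcpp::Named("diverged") = diverged,
    Rcpp::Named("error") = err,
    Rcpp::Named("steps") = (double)steps_done);
}

// single-operation entry points used by the module-level R functions -----

// [[Rcpp::export]]
Rcpp::List cpp_evolve_btilde(Rcpp::List grid, Rcpp::List btilde, Rcpp::List u,
                             double dt) {
  Mesh m = mesh_from_list(grid);
  std::vector<double> B[6];
  for (int c = 0; c < 6; ++c) {
    Rcpp::NumericVector bc = btilde[c];
    B[c].assign(bc.begin(), bc.end());
  }
  Rcpp::NumericVector uxr = u[0], uyr = u[1];
  std::vector<double> ux(uxr.begin(), uxr.end()), uy(uyr.begin(), uyr.end()), uz;
  if (u.size() > 2) {
    Rcpp::NumericVector uzr = u[2];
    uz.assign(uzr.begin(), uzr.end());
  } else uz.assign((long)m.nx * m.ny * (m.nz + 1), 0.0);
  double bmax = evolve_btilde(B, ux, uy, uz, m, dt, 3);
  Rcpp::List out(6);
  for (int c = 0; c < 6; ++c) {
    Rcpp::NumericVector bc(B[c].begin(), B[c].end());
    out[c] = bc;
  }
  return Rcpp::List::create(Rcpp::Named("btilde") = out,
                            Rcpp::Named("bmax") = bmax);
}

// [[Rcpp::export]]
Rcpp::List cpp_elastic_force(Rcpp::List grid, Rcpp::List btilde,
                             Rcpp::NumericVector alpha, double G) {
  Mesh m = mesh_from_list(grid);
  std::vector<double> B[6];
  for (int c = 0; c < 6; ++c) {
    Rcpp::NumericVector bc = btilde[c];
    B[c].assign(bc.begin(), bc.end());
  }
  std::vector<double> a(alpha.begin(), alpha.end());
  std::vector<double> fx, fy, fz;
  elastic_force(B, a, m, G, fx, fy, fz);
  return Rcpp::List::create(
    Rcpp::Named("x") = Rcpp::NumericVector(fx.begin(), fx.end()),
    Rcpp::Named("y") = Rcpp::NumericVector(fy.begin(), fy.end()),
    Rcpp::Named("z") = Rcpp::NumericVector(fz.begin(), fz.end()));
}
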