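#include "poisson.h"

// banded Cholesky: A (SPD, lower bandwidth bw) stored as Ab(r, j) = A(j+r, j),
// r = 0..bw. Factor in place to L with the same layout.
static void band_chol_factor(arma::mat& Ab) {
  int n = Ab.n_cols, bw = Ab.n_rows - 1;
  for (int j = 0; j < n; ++j) {
    double d = Ab(0, j);
    for (int k = std::max(0, j - bw); k < j; ++k) {
      double l = Ab(j - k, k);
      d -= l * l;
    }
    if (d <= 0.0) Rcpp::stop("pressure operator not positive definite (d=%g)", d);
    d = std::sqrt(d);
    Ab(0, j) = d;
    int imax = std::min(n - 1, j + bw);
    for (int i = j + 1; i <= imax; ++i) {
      double s = Ab(i - j, j);
      for (int k = std::max(0, i - bw); k < j; ++k) {
        s -= Ab(i - k, k) * Ab(j - k, k);
      }
      Ab(i - j, j) = s / d;
    }
  }
}

static void band_chol_solve(const arma::mat& Lb, double* x, int n) {
  int bw = Lb.n_rows - 1;
  for (int i = 0; i < n; ++i) { // forward
    double s = x[i];
    for (int k = std::max(0, i - bw); k < i; ++k) s -= Lb(i - k, k) * x[k];
    x[i] = s / Lb(0, i);
  }
  for (int i = n - 1; i >= 0; --i) { // backward
    double s = x[i];
    int imax = std::min(n - 1, i + bw);
    for (int k = i + 1; k <= imax; ++k) s -= Lb(k - i, i) * x[k];
    x[i] = s / Lb(0, i);
  }
}

void PoissonTransform::setup(const Mesh& m, int xbc) {
  bool x_periodic = xbc == 0;
  nx = m.nx;
  double idx2 = 1.0 / (m.dx * m.dx);
  // 1D x operator
  arma::mat Dxx(nx, nx, arma::fill::zeros);
  for (int i = 0; i < nx; ++i) {
    int nb = 0;
    if (i > 0 || x_periodic) { Dxx(i, (i + nx - 1) % nx) += idx2; nb++; }
    if (i < nx - 1 || x_periodic) { Dxx(i, (i + 1) % nx) += idx2; nb++; }
    Dxx(i, i) -= nb * idx2;
    if (xbc == 2 && (i == 0 || i == nx - 1)) Dxx(i, i) -= 2.0 * idx2;
  }
  arma::vec ev; arma::mat evec;
  arma::eig_sym(ev, evec, Dxx);
  lam = ev; Q = evec;
  // cross-section fluid cells (mask must be x-invariant; caller checks)
  csmap.assign((long)m.ny * m.nz, -1);
  cells.clear();
  for (int k = 0; k < m.nz; ++k)
    for (int j = 0; j < m.ny; ++j) {
      if (m.is_wall(0, j, k)) continue;
      csmap[j + (long)m.ny * k] = (int)cells.size();
      cells.push_back(j + m.ny * k);
    }
  nf = (int)cells.size();
  // bandwidth from neighbor index distances
  bw = 1;
  auto fidx = [&](int j, int k) -> int {
    if (j < 0 || k < 0) return -1;
    return csmap[j + (long)m.ny * k];
  };
  for (int f = 0; f < nf; ++f) {
    int j = cells[f] % m.ny, k = cells[f] / m.ny;
    int nb[4][2] = {{j - 1, k}, {j + 1, k}, {j, k - 1}, {j, k + 1}};
    for (auto& q : nb) {
      int jj = q[0], kk = q[1];
      if (m.per[1]) jj = (jj + m.ny) % m.ny;
      if (m.per[2] && m.nz > 1) kk = (kk + m.nz) % m.nz;
      if (jj < 0 || jj >= m.ny || kk < 0 || kk >= m.nz) continue;
      int g = fidx(jj, kk);
      if (g >= 0) bw = std::max(bw, std::abs(g - f));
    }
  }
  // which mode is (numerically) singular
  mode0 = -1;
  for (int i = 0; i < nx; ++i)
    if (std::fabs(lam[i]) < 1e-9 * idx2) { mode0 = i; break; }

  // assemble the cross-section operator once, then factor per mode
  arma::mat A0(bw + 1, nf, arma::fill::zeros);
  std::vector<std::pair<int, int> > offdiag; // (row, col) with row > col
  for (int f = 0; f < nf; ++f) {
    int j = cells[f] % m.ny, k = cells[f] / m.ny;
    int nb[4][2] = {{j - 1, k}, {j + 1, k}, {j, k - 1}, {j, k + 1}};
    for (int s = 0; s < (m.nz > 1 ? 4 : 2); ++s) {
      int jj = nb[s][0], kk = nb[s][1];
      if (m.per[1]) jj = (jj + m.ny) % m.ny;
      if (m.per[2] && m.nz > 1) kk = (kk + m.nz) % m.nz;
      if (jj < 0 || jj >= m.ny || kk < 0 || kk >= (m.nz > 1 ? m.nz : 1)) continue;
      int g = fidx(jj, kk);
      if (g < 0) continue; // wall neighbor: Neumann, no coupling
      A0(0, f) += idx2;    // -(Lyz) diagonal accumulates +1/dx^2 per neighbor
      if (g > f && g - f <= bw) offdiag.push_back(std::make_pair(g, f));
    }
  }
  // accumulate (duplicates possible for tiny periodic cross-sections)
  for (auto& rc : offdiag) A0(rc.first - rc.second, rc.second) += -idx2;

  Lband.clear();
  Lband.reserve(nx);
  for (int mo = 0; mo < nx; ++mo) {
    arma::mat Ab = A0;
    for (int f = 0; f < nf; ++f) Ab(0, f) += -lam[mo]; // -(Lyz + lam I)
    if (mo == mode0) {
      // pin the first fluid cell (Dirichlet zero): drop its couplings
      Ab(0, 0) += 1.0; // make the pinned row safely positive definite
      for (int r = 1; r <= bw && r < (int)Ab.n_rows; ++r) Ab(r, 0) = 0.0;
    }
    band_chol_factor(Ab);
    Lband.push_back(Ab);
  }
}

void PoissonTransform::solve(const std::vector<double>& rhs,
                             std::vector<double>& phi, const Mesh& m) {
  arma::mat B(nx, nf);
  for (int f = 0; f < nf; ++f) {
    int j = cells[f] % m.ny, k = cells[f] / m.ny;
    for (int i = 0; i < nx; ++i) B(i, f) = rhs[m.cidx(i, j, k)];
  }
  arma::mat Bh = Q.t() * B;
  std::vector<double> x(nf);
  for (int mo = 0; mo < nx; ++mo) {
    for (int f = 0; f < nf; ++f) x[f] = -Bh(mo, f);
    if (mo == mode0) {
      // remove the incompatible component, pin cell 0
      double mean = 0.0;
      for (int f = 0; f < nf; ++f) mean += x[f];
      mean /= nf;
      for (int f = 0; f < nf; ++f) x[f] -= mean;
      x[0] = 0.0;
    }
    band_chol_solve(Lband[mo], x.data(), nf);
    for (int f = 0; f < nf; ++f) Bh(mo, f) = x[f];
  }
  arma::mat Phi = Q * Bh;
  phi.assign(m.N(), 0.0);
  for (int f = 0; f < nf; ++f) {
    int j = cells[f] % m.ny, k = cells[f] / m.ny;
    for (int i = 0; i < nx; ++i) phi[m.cidx(i, j, k)] = Phi(i, f);
  }
}

// ---------------------------------------------------------------- PCG ----
static void apply_A(const std::vector<double>& p, std::vector<double>& Ap,
                    const Mesh& m, bool dxlo, bool dxhi) {
  double idx2 = 1.0 / (m.dx * m.dx);
  for (int k = 0; k < m.nz; ++k)
    for (int j = 0; j < m.ny; ++j)
      for (int i = 0; i < m.nx; ++i) {
        long c = m.cidx(i, j, k);
        if (m.is_wall(i, j, k)) { Ap[c] = p[c]; continue; } // identity row
        double acc = 0.0, diag = 0.0;
        static const int off[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
        for (int s = 0; s < 6; ++s) {
          int ax = s / 2;
          int q[3] = {i + off[s][0], j + off[s][1], k + off[s][2]};
          bool inr = m.in_range(q[ax], ax);
          if (!inr) {
            if (m.per[ax]) { q[ax] = m.wrap(q[ax], ax); }
            else if (ax == 0 && ((q[0] < 0 && dxlo) || (q[0] >= m.nx && dxhi))) {
              // Dirichlet ghost: ghost = 2 V - phi; V moved to RHS, so the
              // operator sees ghost = -phi
              diag += 2.0 * idx2;
              continue;
            } else continue; // Neumann: drop
          }
          if (m.is_wall(q[0], q[1], q[2])) continue; // wall: Neumann
          acc += p[m.cidx(q[0], q[1], q[2])] * idx2;
          diag += idx2;
        }
        // A = -(Laplacian): positive definite
        Ap[c] = diag * p[c] - acc;
      }
}

int PoissonPCG::solve(const std::vector<double>& rhs, std::vector<double>& phi,
                      const Mesh& m, double tol, int maxit) {
  long N = m.N();
  double idx2 = 1.0 / (m.dx * m.dx);
  std::vector<double> b(N, 0.0);
  for (int k = 0; k < m.nz; ++k)
    for (int j = 0; j < m.ny; ++j)
      for (int i = 0; i < m.nx; ++i) {
        long c = m.cidx(i, j, k);
        if (m.is_wall(i, j, k)) { b[c] = 0.0; continue; }
        double v = -rhs[c]; // A = -Laplacian
        if (i == 0 && dir_xlo) v += 2.0 * idx2 * val_xlo;
        if (i == m.nx - 1 && dir_xhi) v += 2.0 * idx2 * val_xhi;
        b[c] = v;
      }
  if (phi_prev.size() != (size_t)N) phi_prev.assign(N, 0.0);
  std::vector<double> x = phi_prev, r(N), z(N), p(N), Ap(N);
  apply_A(x, Ap, m, dir_xlo, dir_xhi);
  double rinf = 0.0;
  for (long c = 0; c < N; ++c) { r[c] = b[c] - Ap[c]; rinf = std::max(rinf, std::fabs(r[c])); }
  // Jacobi preconditioner = diagonal of A (recomputed cheaply)
  std::vector<double> dinv(N, 1.0);
  {
    std::vector<double> e(N, 0.0), d(N, 0.0);
    // diagonal via probing is wasteful; assemble directly
    for (int k = 0; k < m.nz; ++k)
      for (int j = 0; j < m.ny; ++j)
        for (int i = 0; i < m.nx; ++i) {
          long c = m.cidx(i, j, k);
          if (m.is_wall(i, j, k)) { dinv[c] = 1.0; continue; }
          double diag = 0.0;
          static const int off[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
          for (int s = 0; s < 6; ++s) {
            int q[3] = {i + off[s][0], j + off[s][1], k + off[s][2]};
            int ax = s / 2;
            if (!m.in_range(q[ax], ax)) {
              if (m.per[ax]) q[ax] = m.wrap(q[ax], ax);
              else if (ax == 0 && ((q[0] < 0 && dir_xlo) || (q[0] >= m.nx && dir_xhi))) {
                diag += 2.0 * idx2; continue;
              } else continue;
            }
            if (m.is_wall(q[0], q[1], q[2])) continue;
            diag += idx2;
          }
          dinv[c] = diag > 0.0 ? 1.0 / diag : 1.0;
        }
    (void)e; (void)d;
  }
  auto apply_M = [&](const std::vector<double>& rr, std::vector<double>& zz) {
    if (precond) {
      // restrict to the true fluid cells, solve on the straight-duct
      // envelope, prolong back; wall rows fall back to the (identity)
      // diagonal so the preconditioner stays symmetric positive definite
      std::vector<double> rmask(rr);
      if (m.has_wall())
        for (long c = 0; c < N; ++c) if (m.wall[c]) rmask[c] = 0.0;
      precond->solve(rmask, zz, precond_mesh);
      for (long c = 0; c < N; ++c) {
        bool w = m.has_wall() && m.wall[c];
        if (w || (zz[c] == 0.0 && rr[c] != 0.0)) zz[c] = dinv[c] * rr[c];
      }
    } else {
      for (long c = 0; c < N; ++c) zz[c] = dinv[c] * rr[c];
    }
  };
  double rz = 0.0;
  apply_M(r, z);
  for (long c = 0; c < N; ++c) rz += r[c] * z[c];
  p = z;
  int it = 0;
  while (rinf > tol && it < maxit) {
    apply_A(p, Ap, m, dir_xlo, dir_xhi);
    double pAp = 0.0;
    for (long c = 0; c < N; ++c) pAp += p[c] * Ap[c];
    if (pAp <= 0.0) break;
    double al = rz / pAp;
    rinf = 0.0;
    for (long c = 0; c < N; ++c) {
      x[c] += al * p[c];
      r[c] -= al * Ap[c];
      rinf = std::max(rinf, std::fabs(r[c]));
    }
    double rz2 = 0.0;
    apply_M(r, z);
    for (long c = 0; c < N; ++c) rz2 += r[c] * z[c];
    double beta = rz2 / rz;
    rz = rz2;
    for (long c = 0; c < N; ++c) p[c] = z[c] + beta * p[c];
    ++it;
  }
  last_iters = it;
  phi = x;
  phi_prev = x;
  return rinf <= tol ? 0 : 1;
}
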