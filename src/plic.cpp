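// Geometric volume-of-fluid transport: PLIC reconstruction with
// reconstruction-distance-function (RDF) normal refinement, and
// directionally split geometric advection with the divergence-consistent
// correction of Weymouth & Yue type (bounded and conservative for
// divergence-free velocity at Courant numbers <= 0.5).
#include <Rcpp.h>
#include "plic.h"

static const double INT_EPS = 1e-9;   // interface-cell detection threshold

// Fraction of the unit cube below the plane sum(m_i xi_i) <= s (m_i >= 0).
// Piecewise closed forms per region (no inclusion-exclusion of near-equal
// cubes, so no catastrophic cancellation for nearly axis-aligned planes),
// evaluated in extended precision.
double cut_unit(double m1, double m2, double m3, double s) {
  double msum = m1 + m2 + m3;
  if (msum <= 0.0) return s > 0.0 ? 1.0 : 0.0;
  double a = m1 / msum, b = m2 / msum, c = m3 / msum;
  double sn = s / msum;
  if (sn <= 0.0) return 0.0;
  if (sn >= 1.0) return 1.0;
  bool flip = sn > 0.5;
  if (flip) sn = 1.0 - sn;
  if (a > b) std::swap(a, b);
  if (b > c) std::swap(b, c);
  if (a > b) std::swap(a, b);
  const double eps = 1e-12;
  double V;
  if (b < eps) {
    V = sn / c;                       // 1D
  } else if (a < eps) {               // 2D (triangle / slab)
    V = sn < b ? sn * sn / (2.0 * b * c) : (sn - 0.5 * b) / c;
  } else {
    double ab = a + b;
    if (sn < a) {
      V = sn * sn * sn / (6.0 * a * b * c);
    } else if (sn < b) {
      V = (3.0 * sn * (sn - a) + a * a) / (6.0 * b * c);
    } else if (sn < (ab < c ? ab : c)) {
      if (a > 1e-4) {
        V = (sn * sn * (3.0 * ab - sn) + a * a * (a - 3.0 * sn) +
             b * b * (b - 3.0 * sn)) / (6.0 * a * b * c);
      } else { // small denominator: evaluate the difference in extended precision
        long double snl = sn, al = a, bl = b;
        long double num = snl * snl * (3.0L * (al + bl) - snl) +
                          al * al * (al - 3.0L * snl) +
                          bl * bl * (bl - 3.0L * snl);
        V = (double)(num / (6.0L * al * bl * (long double)c));
      }
    } else if (c < ab) {
      if (a > 1e-4) {
        V = (sn * sn * (3.0 - 2.0 * sn) + a * a * (a - 3.0 * sn) +
             b * b * (b - 3.0 * sn) + c * c * (c - 3.0 * sn)) /
            (6.0 * a * b * c);
      } else {
        long double snl = sn, al = a, bl = b, cl = c;
        long double num = snl * snl * (3.0L - 2.0L * snl) +
                          al * al * (al - 3.0L * snl) +
                          bl * bl * (bl - 3.0L * snl) +
                          cl * cl * (cl - 3.0L * snl);
        V = (double)(num / (6.0L * al * bl * cl));
      }
    } else {
      V = (sn - 0.5 * ab) / c;        // slab region
    }
  }
  if (flip) V = 1.0 - V;
  if (V < 0.0) V = 0.0;
  if (V > 1.0) V = 1.0;
  return V;
}

// zero out negligible normal components so the positioning and the flux
// evaluation see the identical (possibly degenerate) plane geometry
static inline void clean_normal(const double n[3], double out[3]) {
  double mx = std::max(std::fabs(n[0]),
                       std::max(std::fabs(n[1]), std::fabs(n[2])));
  for (int d = 0; d < 3; ++d)
    out[d] = std::fabs(n[d]) < 1e-9 * mx ? 0.0 : n[d];
}

double invert_cut(double m1, double m2, double m3, double frac) {
  double msum = m1 + m2 + m3;
  if (msum <= 0.0) return 0.0;
  if (frac <= 0.0) return 0.0;
  if (frac >= 1.0) return msum;
  // Illinois (modified regula falsi) on the monotone volume function
  double lo = 0.0, hi = 1.0, flo = -frac, fhi = 1.0 - frac;
  double s = frac; // initial guess: volume fraction itself
  for (int it = 0; it < 80; ++it) {
    double f = cut_unit(m1, m2, m3, s * msum) - frac;
    if (std::fabs(f) < 1e-13) return s * msum;
    if (f < 0.0) {
      if (lo == s) break;
      lo = s; flo = f; fhi *= 0.5;
    } else {
      if (hi == s) break;
      hi = s; fhi = f; flo *= 0.5;
    }
    double denom = fhi - flo;
    double cand = denom != 0.0 ? (lo * fhi - hi * flo) / denom : 0.5 * (lo + hi);
    if (!(cand > lo && cand < hi)) cand = 0.5 * (lo + hi);
    s = cand;
  }
  return s * msum;
}

double plane_box_fraction(const double n[3], double c, const double lo[3],
                          const double hi[3], double dx) {
  // cell-local unit coordinates xi = (x - xc)/dx + 1/2; solid where
  // sum(n_i dx (xi_i - 1/2)) + c <= 0, i.e. sum(m_i xi_i) <= s with
  // m_i = n_i dx and s = sum(m_i)/2 - c
  double nc[3];
  clean_normal(n, nc);
  double m[3], s = -c;
  for (int d = 0; d < 3; ++d) {
    m[d] = nc[d] * dx;
    s += nc[d] * dx * 0.5;
  }
  // restrict to sub-box [lo, hi]: xi_d = lo_d + (hi_d - lo_d) * t_d
  double mm[3], ss = s;
  for (int d = 0; d < 3; ++d) {
    mm[d] = m[d] * (hi[d] - lo[d]);
    ss -= m[d] * lo[d];
  }
  // flip negative coefficients
  for (int d = 0; d < 3; ++d) if (mm[d] < 0.0) { ss -= mm[d]; mm[d] = -mm[d]; }
  return cut_unit(mm[0], mm[1], mm[2], ss);
}

// plane constant from normal + volume fraction for a full cell
static double plane_constant(const double n[3], double alpha, double dx) {
  double nc[3];
  clean_normal(n, nc);
  double m[3], shift = 0.0;
  for (int d = 0; d < 3; ++d) {
    m[d] = nc[d] * dx;
    shift += m[d] * 0.5;
  }
  double neg = 0.0;
  double mm[3];
  for (int d = 0; d < 3; ++d) {
    if (m[d] < 0.0) { neg += m[d]; mm[d] = -m[d]; } else mm[d] = m[d];
  }
  double sflip = invert_cut(mm[0], mm[1], mm[2], alpha);
  double s = sflip + neg;           // un-flip
  return shift - s;                  // c = sum(m_i)/2 - s  (see derivation)
}

// smoothed Youngs gradient normals (27-point 1-2-1 kernel then central diff)
static void youngs_normals(const std::vector<double>& alpha, const Mesh& m,
                           long cell, double n[3]) {
  int k0 = (int)(cell / ((long)m.nx * m.ny));
  int j0 = (int)((cell / m.nx) % m.ny);
  int i0 = (int)(cell % m.nx);
  auto smooth = [&](int i, int j, int k) {
    double acc = 0.0, wsum = 0.0;
    for (int dk = -1; dk <= 1; ++dk)
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di) {
          double w = (2 - std::abs(di)) * (2 - std::abs(dj)) * (2 - std::abs(dk));
          acc += w * cget(alpha, m, i + di, j + dj, k + dk);
          wsum += w;
        }
    return acc / wsum;
  };
  n[0] = -(smooth(i0 + 1, j0, k0) - smooth(i0 - 1, j0, k0));
  n[1] = -(smooth(i0, j0 + 1, k0) - smooth(i0, j0 - 1, k0));
  n[2] = m.nz > 1 ? -(smooth(i0, j0, k0 + 1) - smooth(i0, j0, k0 - 1)) : 0.0;
  double len = std::sqrt(n[0] * n[0] + n[1] * n[1] + n[2] * n[2]);
  if (len > 1e-14) { n[0] /= len; n[1] /= len; n[2] /= len; }
  else { n[0] = 1.0; n[1] = 0.0; n[2] = 0.0; }
}

void plic_reconstruct(const std::vector<double>& alpha, const Mesh& m,
                      int rdf_iters, PlicState& ps, bool warm_start) {
  long N = m.N();
  bool warm = warm_start && (long)ps.nxv.size() == N;
  if ((long)ps.nxv.size() != N) {
    ps.resize(N);
    ps.cells.clear();
  } else {
    // incremental update: clear only the previous interface flags
    for (long c : ps.cells) ps.is_int[c] = 0;
  }
  ps.nfallback = 0;
  std::vector<long> cells;
  cells.reserve(ps.cells.size() + 64);
  for (long c = 0; c < N; ++c) {
    if (alpha[c] > INT_EPS && alpha[c] < 1.0 - INT_EPS) {
      cells.push_back(c);
      ps.is_int[c] = 1;
    }
  }
  // cells that left the interface set lose their stored plane
  for (long c : ps.cells) {
    if (!ps.is_int[c]) { ps.nxv[c] = 0.0; ps.nyv[c] = 0.0; ps.nzv[c] = 0.0; ps.cv[c] = 0.0; }
  }
  ps.cells = cells;
  double dx = m.dx;
  // initial normals: previous values in place where valid, else smoothed
  // Youngs gradients
  for (long c : cells) {
    double n[3];
    bool used_prev = false;
    if (warm) {
      double l = std::sqrt(ps.nxv[c] * ps.nxv[c] + ps.nyv[c] * ps.nyv[c] +
                           ps.nzv[c] * ps.nzv[c]);
      if (l > 0.5) {
        n[0] = ps.nxv[c] / l; n[1] = ps.nyv[c] / l; n[2] = ps.nzv[c] / l;
        used_prev = true;
      }
    }
    if (!used_prev) youngs_normals(alpha, m, c, n);
    ps.nxv[c] = n[0]; ps.nyv[c] = n[1]; ps.nzv[c] = n[2];
    ps.cv[c] = plane_constant(n, alpha[c], dx);
  }
  if (cells.empty()) return;

  auto center = [&](long c, double x[3]) {
    x[0] = ((int)(c % m.nx) + 0.5) * dx;
    x[1] = ((int)((c / m.nx) % m.ny) + 0.5) * dx;
    x[2] = ((int)(c / ((long)m.nx * m.ny)) + 0.5) * dx;
  };

  // band: interface cells plus their 27-neighborhoods (fixed over the
  // refinement iterations)
  std::vector<int> bmap((size_t)N, -1);
  std::vector<long> band;
  band.reserve(cells.size() * 4);
  for (long c : cells) {
    int i0 = (int)(c % m.nx), j0 = (int)((c / m.nx) % m.ny),
        k0 = (int)(c / ((long)m.nx * m.ny));
    for (int dk = -1; dk <= 1; ++dk)
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di) {
          int i = i0 + di, j = j0 + dj, k = k0 + dk;
          if (!m.per[0] && !m.in_range(i, 0)) continue;
          if (!m.per[1] && !m.in_range(j, 1)) continue;
          if (!m.per[2] && !m.in_range(k, 2)) continue;
          long q = m.cidx(m.wrap(i, 0), m.wrap(j, 1), m.wrap(k, 2));
          if (bmap[q] < 0) { bmap[q] = (int)band.size(); band.push_back(q); }
        }
  }
  std::vector<double> psiv(band.size(), 0.0);
  for (int it = 0; it < rdf_iters; ++it) {
    // distance-weighted average of signed distances to neighboring planes,
    // accumulated by scattering each interface plane to its neighborhood;
    // weights fall off with the squared distance to the plane's interface
    // center (the foot of the cell center on its own plane)
    double eps2 = 1e-6 * dx * dx;
    std::vector<double> accw(band.size(), 0.0), accwd(band.size(), 0.0);
    for (long q : cells) {
      int iq = (int)(q % m.nx), jq = (int)((q / m.nx) % m.ny),
          kq = (int)(q / ((long)m.nx * m.ny));
      double nqx = ps.nxv[q], nqy = ps.nyv[q], nqz = ps.nzv[q], cq = ps.cv[q];
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            int i = iq + di, j = jq + dj, k = kq + dk;
            if (!m.per[0] && !m.in_range(i, 0)) continue;
            if (!m.per[1] && !m.in_range(j, 1)) continue;
            if (!m.per[2] && !m.in_range(k, 2)) continue;
            long p = m.cidx(m.wrap(i, 0), m.wrap(j, 1), m.wrap(k, 2));
            int bi = bmap[p];
            if (bi < 0) continue;
            double rx = di * dx, ry = dj * dx, rz = dk * dx; // xp - xq
            double dsig = nqx * rx + nqy * ry + nqz * rz + cq;
            double fx = rx + cq * nqx, fy = ry + cq * nqy, fz = rz + cq * nqz;
            double w = 1.0 / (fx * fx + fy * fy + fz * fz + eps2);
            accw[bi] += w;
            accwd[bi] += w * dsig;
          }
    }
    for (size_t bidx = 0; bidx < band.size(); ++bidx)
      psiv[bidx] = accw[bidx] > 0.0 ? accwd[bidx] / accw[bidx] : 0.0;

    // refreshed normals: weighted least-squares gradient of the RDF over
    // the 27-neighborhood (smoother than a 7-point central difference on a
    // narrow band)
    for (long c : cells) {
      int i0 = (int)(c % m.nx), j0 = (int)((c / m.nx) % m.ny),
          k0 = (int)(c / ((long)m.nx * m.ny));
      if (bmap[c] < 0) { ps.nfallback++; continue; }
      double psi0 = psiv[bmap[c]];
      double A[3][3] = {{0}}, rhs[3] = {0, 0, 0};
      int npts = 0;
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            int i = i0 + di, j = j0 + dj, k = k0 + dk;
            if (!m.per[0] && !m.in_range(i, 0)) continue;
            if (!m.per[1] && !m.in_range(j, 1)) continue;
            if (!m.per[2] && !m.in_range(k, 2)) continue;
            long q = m.cidx(m.wrap(i, 0), m.wrap(j, 1), m.wrap(k, 2));
            if (bmap[q] < 0) continue;
            double r[3] = {di * dx, dj * dx, dk * dx};
            double r2 = r[0] * r[0] + r[1] * r[1] + r[2] * r[2];
            double w = 1.0 / (r2 * r2); // closer samples dominate
            double dpsi = psiv[bmap[q]] - psi0;
            for (int a = 0; a < 3; ++a) {
              rhs[a] += w * dpsi * r[a];
              for (int b2 = 0; b2 < 3; ++b2) A[a][b2] += w * r[a] * r[b2];
            }
            npts++;
          }
      if (m.nz == 1) { A[2][2] = 1.0; rhs[2] = 0.0; }
      // solve the 3x3 normal equations by Cramer's rule
      double det =
        A[0][0] * (A[1][1] * A[2][2] - A[1][2] * A[2][1]) -
        A[0][1] * (A[1][0] * A[2][2] - A[1][2] * A[2][0]) +
        A[0][2] * (A[1][0] * A[2][1] - A[1][1] * A[2][0]);
      if (npts < 6 || std::fabs(det) < 1e-30) { ps.nfallback++; continue; }
      auto solve1 = [&](int col) {
        double M[3][3];
        for (int a = 0; a < 3; ++a)
          for (int b2 = 0; b2 < 3; ++b2)
            M[a][b2] = b2 == col ? rhs[a] : A[a][b2];
        return (M[0][0] * (M[1][1] * M[2][2] - M[1][2] * M[2][1]) -
                M[0][1] * (M[1][0] * M[2][2] - M[1][2] * M[2][0]) +
                M[0][2] * (M[1][0] * M[2][1] - M[1][1] * M[2][0])) / det;
      };
      double gx = solve1(0), gy = solve1(1), gz = m.nz > 1 ? solve1(2) : 0.0;
      double len = std::sqrt(gx * gx + gy * gy + gz * gz);
      if (len < 1e-14) { ps.nfallback++; continue; } // keep prior normal
      double n[3] = {gx / len, gy / len, gz / len};
      ps.nxv[c] = n[0]; ps.nyv[c] = n[1]; ps.nzv[c] = n[2];
      ps.cv[c] = plane_constant(n, alpha[c], dx);
    }
  }
}

// geometric flux through a face (volume per unit face area, signed)
static double face_flux(const std::vector<double>& alpha, const PlicState& ps,
                        const Mesh& m, int d, double uf, double dt,
                        int ic, int jc, int kc /* donor cell (wrapped) */) {
  if (uf == 0.0) return 0.0;
  double w = std::fabs(uf) * dt;          // swept slab thickness
  long c = m.cidx(ic, jc, kc);
  double a = alpha[c];
  double vol;
  if (a >= 1.0 - INT_EPS) vol = w;
  else if (a <= INT_EPS) vol = 0.0;
  else if (!ps.is_int[c]) vol = a * w;    // no plane (shouldn't happen)
  else {
    double lo[3] = {0.0, 0.0, 0.0}, hi[3] = {1.0, 1.0, 1.0};
    double wfrac = std::min(1.0, w / m.dx);
    if (uf > 0.0) lo[d] = 1.0 - wfrac; else hi[d] = wfrac;
    double n[3] = {ps.nxv[c], ps.nyv[c], ps.nzv[c]};
    double frac = plane_box_fraction(n, ps.cv[c], lo, hi, m.dx);
    vol = frac * w;
  }
  return uf > 0.0 ? vol : -vol;
}

void vof_advect(std::vector<double>& alpha,
                const std::vector<double>& ux, const std::vector<double>& uy,
                const std::vector<double>& uz, const Mesh& m, double dt,
                int step_parity, int rdf_iters, PlicState& ps, double* lost) {
  long N = m.N();
  double dx = m.dx;
  std::vector<unsigned char> cc(N);
  for (long c = 0; c < N; ++c) cc[c] = alpha[c] >= 0.5 ? 1 : 0;
  int ndim = m.nz > 1 ? 3 : 2;
  std::vector<int> order(ndim);
  for (int d = 0; d < ndim; ++d) order[d] = (d + step_parity) % ndim;
  const std::vector<double>* ucomp[3] = {&ux, &uy, &uz};

  for (int sweep = 0; sweep < ndim; ++sweep) {
    int d = order[sweep];
    plic_reconstruct(alpha, m, rdf_iters, ps, true);
    FaceDims fd(m, d);
    const std::vector<double>& u = *ucomp[d];
    std::vector<double> anew(alpha);
    // away from the interface the donor fluxes of a uniform region cancel
    // the dilation term exactly, so only cells near interface cells change
    std::vector<unsigned char> act(N, 0);
    for (long c = 0; c < N; ++c) act[c] = ps.is_int[c];
    {
      std::vector<unsigned char> tmp(N);
      for (int dd = 0; dd < ndim; ++dd) {
        tmp.assign(N, 0);
        for (int k = 0; k < m.nz; ++k)
          for (int j = 0; j < m.ny; ++j)
            for (int i = 0; i < m.nx; ++i) {
              if (!act[m.cidx(i, j, k)]) continue;
              for (int s = -2; s <= 2; ++s) {
                int q[3] = {i, j, k};
                q[dd] += s;
                q[dd] = m.wrap(q[dd], dd);
                tmp[m.cidx(q[0], q[1], q[2])] = 1;
              }
            }
        act.swap(tmp);
      }
    }
    for (int k = 0; k < m.nz; ++k)
      for (int j = 0; j < m.ny; ++j)
        for (int i = 0; i < m.nx; ++i) {
          long c = m.cidx(i, j, k);
          if (m.is_wall(i, j, k)) { anew[c] = 0.0; continue; }
          if (!act[c]) continue;
          int q = (d == 0 ? i : (d == 1 ? j : k));
          int flo[3] = {i, j, k};
          int fhi[3] = {i, j, k}; fhi[d] += 1;
          double ulo = u[fd.idx(flo[0], flo[1], flo[2])];
          double uhi = u[fd.idx(fhi[0], fhi[1], fhi[2])];
          // donors
          auto donor_flux = [&](double uf, int fq) -> double {
            if (uf == 0.0) return 0.0;
            int dc[3] = {i, j, k};
            dc[d] = uf > 0.0 ? fq - 1 : fq;
            dc[d] = m.wrap(dc[d], d);
            return face_flux(alpha, ps, m, d, uf, dt, dc[0], dc[1], dc[2]);
          };
          double Flo = donor_flux(ulo, q);
          double Fhi = donor_flux(uhi, q + 1);
          anew[c] = alpha[c] - (Fhi - Flo) / dx +
                    (cc[c] ? dt * (uhi - ulo) / dx : 0.0);
#ifdef EULFSI_VOF_DEBUG
          if (anew[c] < -1e-8 || anew[c] > 1.0 + 1e-8) {
            Rprintf("sweep d=%d cell (%d,%d,%d) a=%.6g anew=%.6g Flo=%.6g Fhi=%.6g ulo=%g uhi=%g cc=%d n=(%g,%g,%g) cpl=%g isint=%d\n",
                    d, i, j, k, alpha[c], anew[c], Flo, Fhi, ulo, uhi,
                    (int)cc[c], ps.nxv[c], ps.nyv[c], ps.nzv[c], ps.cv[c],
                    (int)ps.is_int[c]);
          }
#endif
        }
    alpha.swap(anew);
  }
  // boundedness check and local redistribution of clamped mass
  double lost_acc = 0.0;
  const double tol = 1e-8;
  for (long c = 0; c < N; ++c) {
    if (alpha[c] < -tol || alpha[c] > 1.0 + tol) {
      Rcpp::stop("volume-fraction advection out of bounds (alpha = %g at cell %ld)",
                 alpha[c], c);
    }
  }
  auto try_redistribute = [&](long c, double excess) -> double {
    int i0 = (int)(c % m.nx), j0 = (int)((c / m.nx) % m.ny),
        k0 = (int)(c / ((long)m.nx * m.ny));
    static const int off[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
    for (int s = 0; s < 6; ++s) {
      int i = i0 + off[s][0], j = j0 + off[s][1], k = k0 + off[s][2];
      if (!m.per[0] && !m.in_range(i, 0)) continue;
      if (!m.per[1] && !m.in_range(j, 1)) continue;
      if (!m.per[2] && !m.in_range(k, 2)) continue;
      long q = m.cidx(m.wrap(i, 0), m.wrap(j, 1), m.wrap(k, 2));
      if (m.has_wall() && m.wall[q]) continue;
      if (alpha[q] <= INT_EPS || alpha[q] >= 1.0 - INT_EPS) continue;
      double cap = excess > 0.0 ? 1.0 - alpha[q] : alpha[q];
      double take = excess > 0.0 ? std::min(excess, cap) : -std::min(-excess, cap);
      alpha[q] += take;
      excess -= take;
      if (std::fabs(excess) < 1e-300) break;
    }
    return excess;
  };
  for (long c = 0; c < N; ++c) {
    if (alpha[c] > 1.0) {
      double rem = try_redistribute(c, alpha[c] - 1.0);
      lost_acc += std::fabs(rem);
      alpha[c] = 1.0;
    } else if (alpha[c] < 0.0) {
      double rem = try_redistribute(c, alpha[c]);
      lost_acc += std::fabs(rem);
      alpha[c] = 0.0;
    }
  }
  if (lost) *lost = lost_acc;
}

// ---------------------------------------------------------------- R entry
static Mesh mesh_from_args(Rcpp::IntegerVector dim, double dx,
                           Rcpp::LogicalVector periodic,
                           Rcpp::Nullable<Rcpp::LogicalVector> wall) {
  Mesh m;
  m.nx = dim[0]; m.ny = dim.size() > 1 ? dim[1] : 1;
  m.nz = dim.size() > 2 ? dim[2] : 1;
  m.dx = dx;
  for (int d = 0; d < 3; ++d)
    m.per[d] = d < periodic.size() ? (bool)periodic[d] : true;
  if (dim.size() == 2) m.per[2] = true; // planar: z wraps onto itself
  if (wall.isNotNull()) {
    Rcpp::LogicalVector w(wall);
    m.wall.assign(w.size(), 0);
    for (long c = 0; c < (long)w.size(); ++c) m.wall[c] = w[c] ? 1 : 0;
  }
  return m;
}

// [[Rcpp::export]]
Rcpp::List cpp_plic_reconstruct(Rcpp::NumericVector alpha,
                                Rcpp::IntegerVector dim, double dx,
                                Rcpp::LogicalVector periodic,
                                Rcpp::Nullable<Rcpp::LogicalVector> wall,
                                int rdf_iters,
                                Rcpp::Nullable<Rcpp::NumericMatrix> prev_normals) {
  Mesh m = mesh_from_args(dim, dx, periodic, wall);
  std::vector<double> a(alpha.begin(), alpha.end());
  PlicState ps;
  if (prev_normals.isNotNull()) {
    Rcpp::NumericMatrix pn(prev_normals);
    ps.resize(m.N());
    for (long c = 0; c < m.N(); ++c) {
      ps.nxv[c] = pn(c, 0); ps.nyv[c] = pn(c, 1); ps.nzv[c] = pn(c, 2);
    }
  }
  plic_reconstruct(a, m, rdf_iters, ps, prev_normals.isNotNull());
  std::vector<int> cells;
  for (long c = 0; c < m.N(); ++c) if (ps.is_int[c]) cells.push_back((int)c + 1);
  long nc = cells.size();
  Rcpp::NumericMatrix normals(nc, 3);
  Rcpp::NumericVector cv(nc), resid(nc);
  for (long t = 0; t < nc; ++t) {
    long c = cells[t] - 1;
    normals(t, 0) = ps.nxv[c]; normals(t, 1) = ps.nyv[c]; normals(t, 2) = ps.nzv[c];
    cv[t] = ps.cv[c];
    double n[3] = {ps.nxv[c], ps.nyv[c], ps.nzv[c]};
    double lo[3] = {0, 0, 0}, hi[3] = {1, 1, 1};
    resid[t] = plane_box_fraction(n, ps.cv[c], lo, hi, m.dx) - a[c];
  }
  return Rcpp::List::create(
    Rcpp::Named("cells") = Rcpp::wrap(cells),
    Rcpp::Named("normals") = normals,
    Rcpp::Named("plane_constant") = cv,
    Rcpp::Named("volume_residual") = resid,
    Rcpp::Named("n_fallback") = (double)ps.nfallback);
}

// [[Rcpp::export]]
Rcpp::List cpp_advect_alpha(Rcpp::NumericVector alpha, Rcpp::List ufaces,
                            Rcpp::IntegerVector dim, double dx,
                            Rcpp::LogicalVector periodic,
                            Rcpp::Nullable<Rcpp::LogicalVector> wall,
                            double dt, int step_parity, int rdf_iters) {
  Mesh m = mesh_from_args(dim, dx, periodic, wall);
  std::vector<double> a(alpha.begin(), alpha.end());
  Rcpp::NumericVector uxr = ufaces[0];
  Rcpp::NumericVector uyr = ufaces[1];
  std::vector<double> ux(uxr.begin(), uxr.end());
  std::vector<double> uy(uyr.begin(), uyr.end());
  std::vector<double> uz;
  if (ufaces.size() > 2) {
    Rcpp::NumericVector uzr = ufaces[2];
    uz.assign(uzr.begin(), uzr.end());
  } else uz.assign((long)m.nx * m.ny * (m.nz + 1), 0.0);
  PlicState ps;
  double lost = 0.0;
  vof_advect(a, ux, uy, uz, m, dt, step_parity, rdf_iters, ps, &lost);
  Rcpp::NumericVector out(a.begin(), a.end());
  out.attr("dim") = dim;
  return Rcpp::List::create(Rcpp::Named("alpha") = out,
                            Rcpp::Named("lost") = lost);
}

// [[Rcpp::export]]
double cpp_plane_cell_fraction(Rcpp::NumericVector normal, double c, double dx) {
  double n[3] = {normal[0], normal[1], normal.size() > 2 ? normal[2] : 0.0};
  double lo[3] = {0, 0, 0}, hi[3] = {1, 1, 1};
  return plane_box_fraction(n, c, lo, hi, dx);
}
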