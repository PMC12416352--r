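// Shared mesh / field plumbing for the full Eulerian FSI core.
// All fields are flat column-major arrays over a uniform Cartesian grid;
// planar (2D) problems run with nz = 1 and a periodic z axis so that every
// z-difference cancels identically.
#ifndef EULFSI_CORE_H
#define EULFSI_CORE_H

#include <vector>
#include <cmath>
#include <cstring>
#include <stdexcept>
#include <algorithm>

struct Mesh {
  int nx, ny, nz;
  double dx;
  bool per[3];
  std::vector<unsigned char> wall; // 1 = wall/exterior cell; empty = none

  int n(int d) const { return d == 0 ? nx : (d == 1 ? ny : nz); }
  long N() const { return (long)nx * ny * nz; }
  long cidx(int i, int j, int k) const { return i + (long)nx * (j + (long)ny * k); }
  bool has_wall() const { return !wall.empty(); }
  bool is_wall(int i, int j, int k) const {
    return has_wall() && wall[cidx(i, j, k)] != 0;
  }
  // wrap (periodic) or clamp (zero-gradient ghost) a cell index on axis d
  int wrap(int i, int d) const {
    int m = n(d);
    if (per[d]) { i %= m; if (i < 0) i += m; return i; }
    if (i < 0) return 0;
    if (i >= m) return m - 1;
    return i;
  }
  bool in_range(int i, int d) const { return i >= 0 && i < n(d); }
};

// cell-centered fetch with periodic wrap / zero-gradient clamp; cells under
// the wall mask report a fixed wall value.
inline double cget(const std::vector<double>& f, const Mesh& m,
                   int i, int j, int k, double wall_value = 0.0,
                   bool use_wall_value = false) {
  i = m.wrap(i, 0); j = m.wrap(j, 1); k = m.wrap(k, 2);
  if (use_wall_value && m.is_wall(i, j, k)) return wall_value;
  return f[m.cidx(i, j, k)];
}

// staggered face-array helpers -------------------------------------------
// component d has (n_d + 1) planes along its own axis (periodic axes keep
// plane 0 and plane n_d synchronized).
struct FaceDims {
  int fn[3];
  FaceDims(const Mesh& m, int d) {
    fn[0] = m.nx + (d == 0 ? 1 : 0);
    fn[1] = m.ny + (d == 1 ? 1 : 0);
    fn[2] = m.nz + (d == 2 ? 1 : 0);
  }
  long size() const { return (long)fn[0] * fn[1] * fn[2]; }
  long idx(int i, int j, int k) const {
    return i + (long)fn[0] * (j + (long)fn[1] * k);
  }
};

// velocity boundary conditions per domain patch (used only on non-periodic,
// non-masked axes): 0 periodic, 1 no-slip wall (tangential value), 2 open
// (zero-gradient).
struct VelBCs {
  int kind[3][2];        // [axis][lo/hi]
  double tang[3][2][3];  // prescribed tangential velocity on wall patches
  VelBCs() {
    for (int a = 0; a < 3; ++a) for (int s = 0; s < 2; ++s) {
      kind[a][s] = 1;
      for (int c = 0; c < 3; ++c) tang[a][s][c] = 0.0;
    }
  }
};

// fetch staggered component d at logical face indices that may lie outside
// the array, applying the domain BCs.
inline double fget(const std::vector<double>& u, const FaceDims& fd,
                   const Mesh& m, const VelBCs& bc, int d,
                   int i, int j, int k) {
  int id3[3] = {i, j, k};
  for (int a = 0; a < 3; ++a) {
    int lim = fd.fn[a];
    int& q = id3[a];
    if (q >= 0 && q < lim) continue;
    if (m.per[a]) { // wrap with period n(a) (faces duplicate plane 0/n)
      int p = m.n(a);
      q %= p; if (q < 0) q += p;
      continue;
    }
    int side = q < 0 ? 0 : 1;
    int knd = bc.kind[a][side];
    if (a == d) {
      // beyond the boundary face along the component's own axis
      if (knd == 1) { // solid wall: odd reflection about the boundary face
        q = side == 0 ? -q : 2 * (lim - 1) - q;
        if (q < 0) q = 0; if (q >= lim) q = lim - 1;
        double v = fget(u, fd, m, bc, d, id3[0], id3[1], id3[2]);
        return -v;
      }
      q = side == 0 ? 0 : lim - 1; // open: clamp
    } else {
      if (knd == 1) { // wall: ghost = 2 * tangential value - interior
        int qi = side == 0 ? 0 : lim - 1;
        int tmp[3] = {id3[0], id3[1], id3[2]}; tmp[a] = qi;
        double vint = fget(u, fd, m, bc, d, tmp[0], tmp[1], tmp[2]);
        return 2.0 * bc.tang[a][side][d] - vint;
      }
      q = side == 0 ? 0 : lim - 1; // open: clamp
    }
  }
  return u[fd.idx(id3[0], id3[1], id3[2])];
}

// keep periodic duplicate planes in sync (copy plane 0 to plane n_d)
inline void sync_periodic_faces(std::vector<double>& u, const FaceDims& fd,
                                const Mesh& m, int d) {
  if (!m.per[d]) return;
  int last = fd.fn[d] - 1;
  for (int k = 0; k < fd.fn[2]; ++k)
    for (int j = 0; j < fd.fn[1]; ++j)
      for (int i = 0; i < fd.fn[0]; ++i) {
        int q = (d == 0 ? i : (d == 1 ? j : k));
        if (q != last) continue;
        int i0 = i, j0 = j, k0 = k;
        if (d == 0) i0 = 0; else if (d == 1) j0 = 0; else k0 = 0;
        u[fd.idx(i, j, k)] = u[fd.idx(i0, j0, k0)];
      }
}

// zero every face of component d that touches a wall-masked cell
inline void zero_wall_faces(std::vector<double>& u, const FaceDims& fd,
                            const Mesh& m, int d) {
  if (!m.has_wall()) return;
  for (int k = 0; k < fd.fn[2]; ++k)
    for (int j = 0; j < fd.fn[1]; ++j)
      for (int i = 0; i < fd.fn[0]; ++i) {
        int lo[3] = {i, j, k}; lo[d] -= 1;
        int hi[3] = {i, j, k};
        bool w = false;
        // cell on the low side
        if (m.in_range(lo[d], d) || m.per[d]) {
          int a = m.wrap(lo[0], 0), b = m.wrap(lo[1], 1), c = m.wrap(lo[2], 2);
          w = w || m.is_wall(a, b, c);
        }
        if ((hi[d] < m.n(d)) || m.per[d]) {
          int a = m.wrap(hi[0], 0), b = m.wrap(hi[1], 1), c = m.wrap(hi[2], 2);
          w = w || m.is_wall(a, b, c);
        }
        if (w) u[fd.idx(i, j, k)] = 0.0;
      }
}

inline double minmod(double a, double b) {
  if (a * b <= 0.0) return 0.0;
  return std::fabs(a) < std::fabs(b) ? a : b;
}

#endif
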