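#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Neighborhood cell index within the 3x3x3 cube: i = (dz+1)*9 + (dy+1)*3 + (dx+1).
// Center is 13. Offsets recovered as dx = i%3-1, dy = (i/3)%3-1, dz = i/9-1.

static inline int cell_dx(int i) { return i % 3 - 1; }
static inline int cell_dy(int i) { return (i / 3) % 3 - 1; }
static inline int cell_dz(int i) { return i / 9 - 1; }

// A foreground voxel p is "simple" (deletable without changing topology) iff
//  (a) the foreground voxels of N26(p) form exactly one 26-connected component, and
//  (b) the background voxels of N18(p) that are 6-adjacent to p form exactly one
//      6-connected component within N18.
// Standard local characterization for (26, 6) digital topology.
static bool is_simple(const bool nb[27]) {
  bool visited[27];

  // (a) 26-connected foreground components in N26 \ {center}
  for (int i = 0; i < 27; ++i) visited[i] = false;
  int n_fg_comp = 0;
  for (int s = 0; s < 27; ++s) {
    if (s == 13 || !nb[s] || visited[s]) continue;
    ++n_fg_comp;
    if (n_fg_comp > 1) return false;
    // BFS over 26-adjacent cells of the cube
    int stack[27], top = 0;
    stack[top++] = s;
    visited[s] = true;
    while (top > 0) {
      int c = stack[--top];
      int cx = cell_dx(c), cy = cell_dy(c), cz = cell_dz(c);
      for (int t = 0; t < 27; ++t) {
        if (t == 13 || visited[t] || !nb[t]) continue;
        int ddx = cell_dx(t) - cx, ddy = cell_dy(t) - cy, ddz = cell_dz(t) - cz;
        if (ddx >= -1 && ddx <= 1 && ddy >= -1 && ddy <= 1 && ddz >= -1 && ddz <= 1) {
          visited[t] = true;
          stack[top++] = t;
        }
      }
    }
  }
  if (n_fg_comp != 1) return false;

  // (b) 6-connected background components in N18 touching a face neighbor
  for (int i = 0; i < 27; ++i) visited[i] = false;
  int n_bg_comp = 0;
  for (int s = 0; s < 27; ++s) {
    if (s == 13 || nb[s] || visited[s]) continue;
    int manh = std::abs(cell_dx(s)) + std::abs(cell_dy(s)) + std::abs(cell_dz(s));
    if (manh != 1) continue;  // seed components only at face neighbors
    ++n_bg_comp;
    if (n_bg_comp > 1) return false;
    int stack[27], top = 0;
    stack[top++] = s;
    visited[s] = true;
    while (top > 0) {
      int c = stack[--top];
      int cx = cell_dx(c), cy = cell_dy(c), cz = cell_dz(c);
      for (int t = 0; t < 27; ++t) {
        if (t == 13 || visited[t] || nb[t]) continue;
        int tx = cell_dx(t), ty = cell_dy(t), tz = cell_dz(t);
        if (std::abs(tx) + std::abs(ty) + std::abs(tz) == 3) continue;  // corners not in N18
        if (std::abs(tx - cx) + std::abs(ty - cy) + std::abs(tz - cz) == 1) {
          visited[t] = true;
          stack[top++] = t;
        }
      }
    }
  }
  return n_bg_comp == 1;
}

struct Vol {
  const std::vector<char>& v;
  int ny, nx, nz;
  Vol(const std::vector<char>& v_, int ny_, int nx_, int nz_)
      : v(v_), ny(ny_), nx(nx_), nz(nz_) {}
  inline bool at(int y, int x, int z) const {
    if (y < 0 || y >= ny || x < 0 || x >= nx || z < 0 || z >= nz) return false;
    return v[(size_t)y + (size_t)ny * ((size_t)x + (size_t)nx * z)] != 0;
  }
};

static inline void fill_nb(const Vol& vol, int y, int x, int z, bool nb[27]) {
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx)
        nb[(dz + 1) * 9 + (dy + 1) * 3 + (dx + 1)] = vol.at(y + dy, x + dx, z + dz);
}

static inline int count_fg_neighbors(const bool nb[27]) {
  int n = 0;
  for (int i = 0; i < 27; ++i)
    if (i != 13 && nb[i]) ++n;
  return n;
}

//' @noRd
// [[Rcpp::export(name = ".thin3d_cpp")]]
LogicalVector thin3d_cpp(LogicalVector vol, IntegerVector dim) {
  int ny = dim[0], nx = dim[1], nz = dim[2];
  size_t n = (size_t)ny * nx * nz;
  std::vector<char> v(n);
  for (size_t i = 0; i < n; ++i) v[i] = vol[i] ? 1 : 0;
  Vol V(v, ny, nx, nz);

  // Six border directions (dy, dx, dz): U, D, N, S, E, W sub-iterations
  const int dirs[6][3] = {{0, 0, 1}, {0, 0, -1}, {-1, 0, 0},
                          {1, 0, 0}, {0, 1, 0},  {0, -1, 0}};
  bool nb[27];
  std::vector<size_t> cand;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      cand.clear();
      for (int z = 0; z < nz; ++z)
        for (int x = 0; x < nx; ++x)
          for (int y = 0; y < ny; ++y) {
            size_t i = (size_t)y + (size_t)ny * ((size_t)x + (size_t)nx * z);
            if (!v[i]) continue;
            if (V.at(y + dirs[d][0], x + dirs[d][1], z + dirs[d][2])) continue;
            fill_nb(V, y, x, z, nb);
            int nn = count_fg_neighbors(nb);
            if (nn < 2) continue;  // protect endpoints and isolated voxels
            if (is_simple(nb)) cand.push_back(i);
          }
      // Sequential deletion with re-check so connectivity is never broken.
      // Candidates are visited in the 8 parity subfields so that no two
      // adjacent voxels are deleted back to back: without this, a
      // two-voxel-wide ribbon can be munched away along its axis inside a
      // single pass (each receding end voxel stays simple).
      for (int sub = 0; sub < 8; ++sub) {
        for (size_t k = 0; k < cand.size(); ++k) {
          size_t i = cand[k];
          int z = (int)(i / ((size_t)ny * nx));
          int rem = (int)(i % ((size_t)ny * nx));
          int x = rem / ny, y = rem % ny;
          if (((y & 1) | ((x & 1) << 1) | ((z & 1) << 2)) != sub) continue;
          fill_nb(V, y, x, z, nb);
          if (count_fg_neighbors(nb) < 2) continue;
          if (!is_simple(nb)) continue;
          v[i] = 0;
          changed = true;
        }
      }
    }
  }

  LogicalVector out(vol.size());
  for (size_t i = 0; i < n; ++i) out[i] = v[i] != 0;
  out.attr("dim") = dim;
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".label3d_cpp")]]
IntegerVector label3d_cpp(LogicalVector vol, IntegerVector dim, int connectivity) {
  int ny = dim[0], nx = dim[1], nz = dim[2];
  size_t n = (size_t)ny * nx * nz;
  IntegerVector lab(vol.size(), 0);
  std::vector<size_t> stack;
  int next = 0;
  for (size_t s = 0; s < n; ++s) {
    if (!vol[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      size_t i = stack.back();
      stack.pop_back();
      int z = (int)(i / ((size_t)ny * nx));
      int rem = (int)(i % ((size_t)ny * nx));
      int x = rem / ny, y = rem % ny;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
            if (connectivity == 6 && manh != 1) continue;
            int yy = y + dy, xx = x + dx, zz = z + dz;
            if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0 || zz >= nz)
              continue;
            size_t j = (size_t)yy + (size_t)ny * ((size_t)xx + (size_t)nx * zz);
            if (vol[j] && lab[j] == 0) {
              lab[j] = next;
              stack.push_back(j);
            }
          }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}
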