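#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Voxel grids are stored as flat vectors in column-major order:
// index = ix + nx * (iy + ny * iz), 0-based.

static inline int vox(int ix, int iy, int iz, int nx, int ny) {
  return ix + nx * (iy + (long long)ny * iz);
}

// Mark voxels whose center lies within radii[a] of atom a.
// coords: n x 3 matrix (Angstrom); origin: center of voxel (0,0,0).
// [[Rcpp::export]]
LogicalVector grid_occupancy_cpp(NumericMatrix coords, NumericVector radii,
                                 NumericVector origin, double spacing,
                                 IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  LogicalVector occ((R_xlen_t)nx * ny * nz);
  const int n = coords.nrow();
  for (int a = 0; a < n; ++a) {
    const double r = radii[a];
    const double r2 = r * r;
    const double ax = coords(a, 0), ay = coords(a, 1), az = coords(a, 2);
    // local bounding box of the sphere in voxel indices
    int ix0 = (int)std::floor((ax - r - origin[0]) / spacing);
    int ix1 = (int)std::ceil((ax + r - origin[0]) / spacing);
    int iy0 = (int)std::floor((ay - r - origin[1]) / spacing);
    int iy1 = (int)std::ceil((ay + r - origin[1]) / spacing);
    int iz0 = (int)std::floor((az - r - origin[2]) / spacing);
    int iz1 = (int)std::ceil((az + r - origin[2]) / spacing);
    if (ix0 < 0) ix0 = 0; if (iy0 < 0) iy0 = 0; if (iz0 < 0) iz0 = 0;
    if (ix1 > nx - 1) ix1 = nx - 1;
    if (iy1 > ny - 1) iy1 = ny - 1;
    if (iz1 > nz - 1) iz1 = nz - 1;
    for (int iz = iz0; iz <= iz1; ++iz) {
      const double dz = origin[2] + iz * spacing - az;
      for (int iy = iy0; iy <= iy1; ++iy) {
        const double dy = origin[1] + iy * spacing - ay;
        const double dyz2 = dy * dy + dz * dz;
        if (dyz2 > r2) continue;
        for (int ix = ix0; ix <= ix1; ++ix) {
          const double dx = origin[0] + ix * spacing - ax;
          if (dx * dx + dyz2 <= r2)
            occ[vox(ix, iy, iz, nx, ny)] = true;
        }
      }
    }
  }
  return occ;
}

// Flood fill from all boundary voxels through unoccupied space,
// 6-connectivity (conservative: no diagonal leaks through walls).
// Returns TRUE for voxels connected to the grid boundary (= bulk solvent).
// [[Rcpp::export]]
LogicalVector grid_flood_bulk_cpp(LogicalVector occupied, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t ntot = (R_xlen_t)nx * ny * nz;
  LogicalVector bulk(ntot);
  std::queue<int> q;
  // seed: all unoccupied boundary voxels
  for (int iz = 0; iz < nz; ++iz)
    for (int iy = 0; iy < ny; ++iy)
      for (int ix = 0; ix < nx; ++ix) {
        if (ix > 0 && ix < nx - 1 && iy > 0 && iy < ny - 1 &&
            iz > 0 && iz < nz - 1) continue;
        const int v = vox(ix, iy, iz, nx, ny);
        if (!occupied[v] && !bulk[v]) { bulk[v] = true; q.push(v); }
      }
  const int dxs[6] = {1, -1, 0, 0, 0, 0};
  const int dys[6] = {0, 0, 1, -1, 0, 0};
  const int dzs[6] = {0, 0, 0, 0, 1, -1};
  while (!q.empty()) {
    const int v = q.front(); q.pop();
    const int ix = v % nx, iy = (v / nx) % ny, iz = v / (nx * ny);
    for (int d = 0; d < 6; ++d) {
      const int jx = ix + dxs[d], jy = iy + dys[d], jz = iz + dzs[d];
      if (jx < 0 || jx >= nx || jy < 0 || jy >= ny || jz < 0 || jz >= nz)
        continue;
      const int w = vox(jx, jy, jz, nx, ny);
      if (!occupied[w] && !bulk[w]) { bulk[w] = true; q.push(w); }
    }
  }
  return bulk;
}

// Label connected components of mask with 26-connectivity.
// Returns integer labels 1..k (0 outside mask), in scan order of the
// component's first voxel (deterministic).
// [[Rcpp::export]]
IntegerVector grid_label_components_cpp(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t ntot = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(ntot);
  int next = 0;
  std::queue<int> q;
  for (R_xlen_t s = 0; s < ntot; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    lab[s] = next;
    q.push((int)s);
    while (!q.empty()) {
      const int v = q.front(); q.pop();
      const int ix = v % nx, iy = (v / nx) % ny, iz = v / (nx * ny);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            const int jx = ix + dx, jy = iy + dy, jz = iz + dz;
            if (jx < 0 || jx >= nx || jy < 0 || jy >= ny || jz < 0 || jz >= nz)
              continue;
            const int w = vox(jx, jy, jz, nx, ny);
            if (mask[w] && !lab[w]) { lab[w] = next; q.push(w); }
          }
    }
  }
  return lab;
}

// Multi-source BFS over accessible voxels (26-connectivity), sources at
// depth 0. Returns step counts; -1 for unreachable or non-accessible voxels.
// [[Rcpp::export]]
IntegerVector grid_bfs_depth_cpp(LogicalVector accessible, LogicalVector sources,
                                 IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t ntot = (R_xlen_t)nx * ny * nz;
  IntegerVector depth(ntot, -1);
  std::queue<int> q;
  for (R_xlen_t v = 0; v < ntot; ++v)
    if (sources[v] && accessible[v]) { depth[v] = 0; q.push((int)v); }
  while (!q.empty()) {
    const int v = q.front(); q.pop();
    const int ix = v % nx, iy = (v / nx) % ny, iz = v / (nx * ny);
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dx && !dy && !dz) continue;
          const int jx = ix + dx, jy = iy + dy, jz = iz + dz;
          if (jx < 0 || jx >= nx || jy < 0 || jy >= ny || jz < 0 || jz >= nz)
            continue;
          const int w = vox(jx, jy, jz, nx, ny);
          if (accessible[w] && depth[w] < 0) { depth[w] = depth[v] + 1; q.push(w); }
        }
  }
  return depth;
}

// Antialiased occupancy fraction for boundary voxels. For each listed voxel
// (0-based linear index), 128 quasi-random sub-points (fixed Halton(2,3,5)
// pattern, Cranley-Patterson-rotated per voxel by a hash so patterns are
// decorrelated between voxels) are tested against the atom spheres; the
// returned value is the unoccupied fraction of the voxel.
// [[Rcpp::export]]
NumericVector grid_boundary_fractions_cpp(NumericMatrix coords, NumericVector radii,
                                          NumericVector origin, double spacing,
                                          IntegerVector dims,
                                          IntegerVector boundary) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nb = boundary.size();
  const int NS = 128;
  // Halton(2,3,5) base pattern in [0,1)^3
  static double hx[NS], hy[NS], hz[NS];
  static bool init = false;
  if (!init) {
    auto radical = [](int i, int b) {
      double f = 1.0, r = 0.0;
      while (i > 0) { f /= b; r += f * (i % b); i /= b; }
      return r;
    };
    for (int j = 0; j < NS; ++j) {
      hx[j] = radical(j + 1, 2);
      hy[j] = radical(j + 1, 3);
      hz[j] = radical(j + 1, 5);
    }
    init = true;
  }
  // map voxel -> slot in `boundary`
  std::vector<int> slot((size_t)nx * ny * nz, -1);
  for (int k = 0; k < nb; ++k) slot[boundary[k]] = k;
  std::vector<uint8_t> occsub((size_t)nb * NS, 0);
  std::vector<int> occount(nb, 0);

  const int n = coords.nrow();
  const double diag = spacing * 0.8660254037844386 * 2.0; // voxel diagonal
  for (int a = 0; a < n; ++a) {
    const double r = radii[a];
    const double reach = r + diag;
    const double r2 = r * r;
    const double ax = coords(a, 0), ay = coords(a, 1), az = coords(a, 2);
    int ix0 = (int)std::floor((ax - reach - origin[0]) / spacing);
    int ix1 = (int)std::ceil((ax + reach - origin[0]) / spacing);
    int iy0 = (int)std::floor((ay - reach - origin[1]) / spacing);
    int iy1 = (int)std::ceil((ay + reach - origin[1]) / spacing);
    int iz0 = (int)std::floor((az - reach - origin[2]) / spacing);
    int iz1 = (int)std::ceil((az + reach - origin[2]) / spacing);
    if (ix0 < 0) ix0 = 0; if (iy0 < 0) iy0 = 0; if (iz0 < 0) iz0 = 0;
    if (ix1 > nx - 1) ix1 = nx - 1;
    if (iy1 > ny - 1) iy1 = ny - 1;
    if (iz1 > nz - 1) iz1 = nz - 1;
    for (int iz = iz0; iz <= iz1; ++iz)
      for (int iy = iy0; iy <= iy1; ++iy)
        for (int ix = ix0; ix <= ix1; ++ix) {
          const int v = vox(ix, iy, iz, nx, ny);
          const int s = slot[v];
          if (s < 0 || occount[s] == NS) continue;
          // voxel cell spans center +/- spacing/2
          const double cx = origin[0] + ix * spacing - spacing / 2;
          const double cy = origin[1] + iy * spacing - spacing / 2;
          const double cz = origin[2] + iz * spacing - spacing / 2;
          // per-voxel rotation from a multiplicative hash
          uint32_t h = (uint32_t)v * 2654435761u;
          const double rx = (h & 0x3FF) / 1024.0;
          const double ry = ((h >> 10) & 0x3FF) / 1024.0;
          const double rz = ((h >> 20) & 0x3FF) / 1024.0;
          uint8_t *bits = &occsub[(size_t)s * NS];
          for (int j = 0; j < NS; ++j) {
            if (bits[j]) continue;
            double ux = hx[j] + rx; ux -= (ux >= 1.0);
            double uy = hy[j] + ry; uy -= (uy >= 1.0);
            double uz = hz[j] + rz; uz -= (uz >= 1.0);
            const double px = cx + ux * spacing - ax;
            const double py = cy + uy * spacing - ay;
            const double pz = cz + uz * spacing - az;
            if (px * px + py * py + pz * pz <= r2) {
              bits[j] = 1;
              ++occount[s];
            }
          }
        }
  }
  NumericVector frac(nb);
  for (int k = 0; k < nb; ++k) frac[k] = 1.0 - occount[k] / (double)NS;
  return frac;
}

// Per-atom minimum distance to voxel centers of each label, searched within
// `cutoff`; entries stay at cutoff + 1 when no voxel of that label is close.
// [[Rcpp::export]]
NumericMatrix grid_atom_label_mindist_cpp(NumericMatrix coords, IntegerVector labels,
                                          int nlab, NumericVector origin,
                                          double spacing, IntegerVector dims,
                                          double cutoff) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = coords.nrow();
  NumericMatrix mind(n, nlab);
  std::fill(mind.begin(), mind.end(), cutoff + 1.0);
  const double c2 = cutoff * cutoff;
  for (int a = 0; a < n; ++a) {
    const double ax = coords(a, 0), ay = coords(a, 1), az = coords(a, 2);
    int ix0 = (int)std::floor((ax - cutoff - origin[0]) / spacing);
    int ix1 = (int)std::ceil((ax + cutoff - origin[0]) / spacing);
    int iy0 = (int)std::floor((ay - cutoff - origin[1]) / spacing);
    int iy1 = (int)std::ceil((ay + cutoff - origin[1]) / spacing);
    int iz0 = (int)std::floor((az - cutoff - origin[2]) / spacing);
    int iz1 = (int)std::ceil((az + cutoff - origin[2]) / spacing);
    if (ix0 < 0) ix0 = 0; if (iy0 < 0) iy0 = 0; if (iz0 < 0) iz0 = 0;
    if (ix1 > nx - 1) ix1 = nx - 1;
    if (iy1 > ny - 1) iy1 = ny - 1;
    if (iz1 > nz - 1) iz1 = nz - 1;
    for (int iz = iz0; iz <= iz1; ++iz) {
      const double dz = origin[2] + iz * spacing - az;
      for (int iy = iy0; iy <= iy1; ++iy) {
        const double dy = origin[1] + iy * spacing - ay;
        const double dyz2 = dy * dy + dz * dz;
        if (dyz2 > c2) continue;
        for (int ix = ix0; ix <= ix1; ++ix) {
          const int l = labels[vox(ix, iy, iz, nx, ny)];
          if (l <= 0 || l > nlab) continue;
          const double dx = origin[0] + ix * spacing - ax;
          const double d2 = dx * dx + dyz2;
          if (d2 <= c2) {
            const double d = std::sqrt(d2);
            if (d < mind(a, l - 1)) mind(a, l - 1) = d;
          }
        }
      }
    }
  }
  return mind;
}

// Per-atom counts of labelled cavity voxel centers within `cutoff`.
// labels: voxel labels (0 = not cavity). Returns an n x nlab count matrix.
// [[Rcpp::export]]
IntegerMatrix grid_atom_label_counts_cpp(NumericMatrix coords, IntegerVector labels,
                                         int nlab, NumericVector origin,
                                         double spacing, IntegerVector dims,
                                         double cutoff) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = coords.nrow();
  IntegerMatrix counts(n, nlab);
  const double c2 = cutoff * cutoff;
  for (int a = 0; a < n; ++a) {
    const double ax = coords(a, 0), ay = coords(a, 1), az = coords(a, 2);
    int ix0 = (int)std::floor((ax - cutoff - origin[0]) / spacing);
    int ix1 = (int)std::ceil((ax + cutoff - origin[0]) / spacing);
    int iy0 = (int)std::floor((ay - cutoff - origin[1]) / spacing);
    int iy1 = (int)std::ceil((ay + cutoff - origin[1]) / spacing);
    int iz0 = (int)std::floor((az - cutoff - origin[2]) / spacing);
    int iz1 = (int)std::ceil((az + cutoff - origin[2]) / spacing);
    if (ix0 < 0) ix0 = 0; if (iy0 < 0) iy0 = 0; if (iz0 < 0) iz0 = 0;
    if (ix1 > nx - 1) ix1 = nx - 1;
    if (iy1 > ny - 1) iy1 = ny - 1;
    if (iz1 > nz - 1) iz1 = nz - 1;
    for (int iz = iz0; iz <= iz1; ++iz) {
      const double dz = origin[2] + iz * spacing - az;
      for (int iy = iy0; iy <= iy1; ++iy) {
        const double dy = origin[1] + iy * spacing - ay;
        const double dyz2 = dy * dy + dz * dz;
        if (dyz2 > c2) continue;
        for (int ix = ix0; ix <= ix1; ++ix) {
          const int l = labels[vox(ix, iy, iz, nx, ny)];
          if (l <= 0 || l > nlab) continue;
          const double dx = origin[0] + ix * spacing - ax;
          if (dx * dx + dyz2 <= c2) counts(a, l - 1) += 1;
        }
      }
    }
  }
  return counts;
}
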