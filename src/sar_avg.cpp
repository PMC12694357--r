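// Mass-averaged SAR over sphere / hemisphere / adaptive air-excluding
// kernels on a voxel grid. Offsets are visited in a deterministic order:
// increasing squared physical distance, ties broken by (dz, dy, dx)
// ascending. The adaptive mode accumulates whole voxels in that order until
// the tissue mass reaches the target, so the realized mass lies within one
// voxel mass above the target.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {
struct Off {
  double d2;
  int dz, dy, dx;
};
}

// [[Rcpp::export]]
List sar_mass_avg_cpp(NumericVector sar,      // [nx, ny, nz] array
                      NumericVector mass,     // voxel mass (kg), 0 for air
                      LogicalVector tissue,   // voxels counted in the kernel
                      IntegerVector dims,     // nx, ny, nz
                      NumericVector spacing,  // m, per axis
                      double target_mass,     // kg (adaptive mode)
                      int hemisphere,         // 0 sphere, 1 hemisphere
                      NumericVector axis,     // hemisphere dome direction
                      int adaptive,           // 1: grow to target mass
                      double radius,          // m (fixed mode)
                      double max_radius) {    // m (adaptive search bound)
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const double rmax = adaptive ? max_radius : radius;
  const int kx = (int)std::floor(rmax / sx), kyn = (int)std::floor(rmax / sy),
            kz = (int)std::floor(rmax / sz);

  double an = std::sqrt(axis[0] * axis[0] + axis[1] * axis[1] +
                        axis[2] * axis[2]);
  double ax = axis[0] / an, ay = axis[1] / an, az = axis[2] / an;

  std::vector<Off> offs;
  for (int dz = -kz; dz <= kz; ++dz)
    for (int dy = -kyn; dy <= kyn; ++dy)
      for (int dx = -kx; dx <= kx; ++dx) {
        double px = dx * sx, py = dy * sy, pz = dz * sz;
        double d2 = px * px + py * py + pz * pz;
        if (d2 > rmax * rmax + 1e-15) continue;
        if (hemisphere) {
          double dot = px * ax + py * ay + pz * az;
          if (dot < -1e-12) continue;
        }
        offs.push_back({d2, dz, dy, dx});
      }
  std::sort(offs.begin(), offs.end(), [](const Off& a, const Off& b) {
    if (a.d2 != b.d2) return a.d2 < b.d2;
    if (a.dz != b.dz) return a.dz < b.dz;
    if (a.dy != b.dy) return a.dy < b.dy;
    return a.dx < b.dx;
  });

  const int ntot = nx * ny * nz;
  NumericVector avg(ntot, NA_REAL), realized(ntot, NA_REAL);
  int short_count = 0;

  for (int iz = 0; iz < nz; ++iz)
    for (int iy = 0; iy < ny; ++iy)
      for (int ix = 0; ix < nx; ++ix) {
        int idx = ix + nx * (iy + ny * iz);
        if (!tissue[idx]) continue;
        double m = 0.0, num = 0.0;
        for (size_t k = 0; k < offs.size(); ++k) {
          int jx = ix + offs[k].dx, jy = iy + offs[k].dy,
              jz = iz + offs[k].dz;
          if (jx < 0 || jx >= nx || jy < 0 || jy >= ny || jz < 0 ||
              jz >= nz)
            continue;
          int j = jx + nx * (jy + ny * jz);
          if (!tissue[j]) continue;
          m += mass[j];
          num += sar[j] * mass[j];
          if (adaptive && m >= target_mass) break;
        }
        if (adaptive && m < target_mass) { ++short_count; continue; }
        if (m > 0.0) {
          avg[idx] = num / m;
          realized[idx] = m;
        }
      }

  return List::create(_["avg"] = avg, _["realized_mass"] = realized,
                      _["short_count"] = short_count,
                      _["n_offsets"] = (int)offs.size());
}
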