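#include <Rcpp.h>
using namespace Rcpp;

// Gray-level pair and run accumulation for 3D regions of interest.
// Levels are 0-based integers inside the mask and NA outside; both
// matrices are accumulated over a set of 3D displacement directions.

static inline bool in_bounds(int x, int y, int z, int nx, int ny, int nz) {
  return x >= 0 && x < nx && y >= 0 && y < ny && z >= 0 && z < nz;
}

// [[Rcpp::export]]
IntegerMatrix glcm_accumulate(IntegerVector levels, IntegerVector dims,
                              IntegerMatrix offsets, int n_levels,
                              bool symmetric) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerMatrix counts(n_levels, n_levels);
  for (int o = 0; o < offsets.nrow(); ++o) {
    const int dx = offsets(o, 0), dy = offsets(o, 1), dz = offsets(o, 2);
    for (int z = 0; z < nz; ++z) {
      for (int y = 0; y < ny; ++y) {
        for (int x = 0; x < nx; ++x) {
          const int a = levels[x + nx * (y + ny * z)];
          if (a == NA_INTEGER) continue;
          const int x2 = x + dx, y2 = y + dy, z2 = z + dz;
          if (!in_bounds(x2, y2, z2, nx, ny, nz)) continue;
          const int b = levels[x2 + nx * (y2 + ny * z2)];
          if (b == NA_INTEGER) continue;
          counts(a, b) += 1;
          if (symmetric) counts(b, a) += 1;
        }
      }
    }
  }
  return counts;
}

// [[Rcpp::export]]
IntegerMatrix glrlm_accumulate(IntegerVector levels, IntegerVector dims,
                               IntegerMatrix directions, int n_levels,
                               int max_run) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerMatrix counts(n_levels, max_run);
  for (int o = 0; o < directions.nrow(); ++o) {
    const int dx = directions(o, 0), dy = directions(o, 1), dz = directions(o, 2);
    for (int z = 0; z < nz; ++z) {
      for (int y = 0; y < ny; ++y) {
        for (int x = 0; x < nx; ++x) {
          const int a = levels[x + nx * (y + ny * z)];
          if (a == NA_INTEGER) continue;
          // run starts here iff the predecessor voxel is outside the
          // array, outside the mask, or a different level
          const int xp = x - dx, yp = y - dy, zp = z - dz;
          if (in_bounds(xp, yp, zp, nx, ny, nz)) {
            const int p = levels[xp + nx * (yp + ny * zp)];
            if (p != NA_INTEGER && p == a) continue;
          }
          int len = 1;
          int xc = x + dx, yc = y + dy, zc = z + dz;
          while (in_bounds(xc, yc, zc, nx, ny, nz)) {
            const int c = levels[xc + nx * (yc + ny * zc)];
            if (c == NA_INTEGER || c != a) break;
            ++len;
            xc += dx; yc += dy; zc += dz;
          }
          if (len > max_run) len = max_run;
          counts(a, len - 1) += 1;
        }
      }
    }
  }
  return counts;
}
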