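#include <Rcpp.h>
using namespace Rcpp;

// Rigid resampling of a 3D volume with trilinear interpolation, plus the
// exact transpose of the interpolation operator (needed so the adjoint dot
// test and CG theory hold exactly).
//
// Convention: the transform maps input coordinates p to output coordinates
// T(p) = R (p - c) + c + t, with c the grid centre (floor(n/2), 0-based) and
// t in voxel units. The resampled output therefore reads
//   out(v) = in(R^T (v - c - t) + c)
// with trilinear weights; samples outside the grid are zero.

static inline void source_coord(const double *Rm, const double *t,
                                const double *c, int i, int j, int k,
                                double &x, double &y, double &z) {
  double dx = i - c[0] - t[0];
  double dy = j - c[1] - t[1];
  double dz = k - c[2] - t[2];
  // R^T * d
  x = Rm[0] * dx + Rm[1] * dy + Rm[2] * dz + c[0];
  y = Rm[3] * dx + Rm[4] * dy + Rm[5] * dz + c[1];
  z = Rm[6] * dx + Rm[7] * dy + Rm[8] * dz + c[2];
}

// [[Rcpp::export(name = ".resampleRigidC")]]
NumericVector resample_rigid(NumericVector vol, IntegerVector dims,
                             NumericVector rot, NumericVector tvox,
                             NumericVector centre) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out(vol.size());
  const double *in = vol.begin();
  double *o = out.begin();
  // rot is column-major R; a straight copy reads as row-major R^T, which
  // is what source_coord needs (out(v) = in(R^T (v - c - t) + c))
  double Rm[9];
  for (int k = 0; k < 9; ++k) Rm[k] = rot[k];
  const double t[3] = {tvox[0], tvox[1], tvox[2]};
  const double c[3] = {centre[0], centre[1], centre[2]};
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        double x, y, z;
        source_coord(Rm, t, c, i, j, k, x, y, z);
        int x0 = (int)std::floor(x), y0 = (int)std::floor(y),
            z0 = (int)std::floor(z);
        double fx = x - x0, fy = y - y0, fz = z - z0;
        double acc = 0.0;
        for (int dz = 0; dz < 2; ++dz) {
          int zz = z0 + dz;
          if (zz < 0 || zz >= nz) continue;
          double wz = dz ? fz : 1.0 - fz;
          for (int dy = 0; dy < 2; ++dy) {
            int yy = y0 + dy;
            if (yy < 0 || yy >= ny) continue;
            double wy = dy ? fy : 1.0 - fy;
            for (int dx = 0; dx < 2; ++dx) {
              int xx = x0 + dx;
              if (xx < 0 || xx >= nx) continue;
              double wx = dx ? fx : 1.0 - fx;
              acc += wx * wy * wz * in[xx * sx + yy * sy + zz * sz];
            }
          }
        }
        o[i * sx + j * sy + k * sz] = acc;
      }
    }
  }
  return out;
}

// Exact transpose: scatters each output voxel's value back onto the eight
// input-grid neighbours it read from, with the same trilinear weights.
// [[Rcpp::export(name = ".resampleRigidAdjointC")]]
NumericVector resample_rigid_adjoint(NumericVector vol, IntegerVector dims,
                                     NumericVector rot, NumericVector tvox,
                                     NumericVector centre) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out(vol.size());
  const double *in = vol.begin();
  double *o = out.begin();
  double Rm[9];
  for (int k = 0; k < 9; ++k) Rm[k] = rot[k];
  const double t[3] = {tvox[0], tvox[1], tvox[2]};
  const double c[3] = {centre[0], centre[1], centre[2]};
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        double v = in[i * sx + j * sy + k * sz];
        if (v == 0.0) continue;
        double x, y, z;
        source_coord(Rm, t, c, i, j, k, x, y, z);
        int x0 = (int)std::floor(x), y0 = (int)std::floor(y),
            z0 = (int)std::floor(z);
        double fx = x - x0, fy = y - y0, fz = z - z0;
        for (int dz = 0; dz < 2; ++dz) {
          int zz = z0 + dz;
          if (zz < 0 || zz >= nz) continue;
          double wz = dz ? fz : 1.0 - fz;
          for (int dy = 0; dy < 2; ++dy) {
            int yy = y0 + dy;
            if (yy < 0 || yy >= ny) continue;
            double wy = dy ? fy : 1.0 - fy;
            for (int dx = 0; dx < 2; ++dx) {
              int xx = x0 + dx;
              if (xx < 0 || xx >= nx) continue;
              double wx = dx ? fx : 1.0 - fx;
              o[xx * sx + yy * sy + zz * sz] += wx * wy * wz * v;
            }
          }
        }
      }
    }
  }
  return out;
}
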