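// Trilinear pull-back warp and its exact transpose (scatter) for 3D volumes.
// Convention: out(r) = in(r + u(r)) with r in 1-based voxel indices and u in
// voxel units; sample coordinates are clamped to the volume bounds so the
// scatter kernel is the exact matrix transpose of the gather kernel.
#include <Rcpp.h>
using namespace Rcpp;

static inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// [[Rcpp::export]]
NumericVector warp3_gather(NumericVector img, IntegerVector dims,
                           NumericVector ux, NumericVector uy,
                           NumericVector uz) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  R_xlen_t idx = 0;
  for (int z = 1; z <= nz; ++z) {
    for (int y = 1; y <= ny; ++y) {
      for (int x = 1; x <= nx; ++x, ++idx) {
        double px = clampd(x + ux[idx], 1.0, (double)nx);
        double py = clampd(y + uy[idx], 1.0, (double)ny);
        double pz = clampd(z + uz[idx], 1.0, (double)nz);
        int x0 = (int)px; if (x0 > nx - 1) x0 = nx - 1; if (nx == 1) x0 = 1;
        int y0 = (int)py; if (y0 > ny - 1) y0 = ny - 1; if (ny == 1) y0 = 1;
        int z0 = (int)pz; if (z0 > nz - 1) z0 = nz - 1; if (nz == 1) z0 = 1;
        double fx = px - x0, fy = py - y0, fz = pz - z0;
        int x1 = nx == 1 ? x0 : x0 + 1;
        int y1 = ny == 1 ? y0 : y0 + 1;
        int z1 = nz == 1 ? z0 : z0 + 1;
        if (nx == 1) fx = 0.0; if (ny == 1) fy = 0.0; if (nz == 1) fz = 0.0;
        R_xlen_t b000 = (x0 - 1) + (R_xlen_t)nx * ((y0 - 1) + (R_xlen_t)ny * (z0 - 1));
        R_xlen_t b100 = (x1 - 1) + (R_xlen_t)nx * ((y0 - 1) + (R_xlen_t)ny * (z0 - 1));
        R_xlen_t b010 = (x0 - 1) + (R_xlen_t)nx * ((y1 - 1) + (R_xlen_t)ny * (z0 - 1));
        R_xlen_t b110 = (x1 - 1) + (R_xlen_t)nx * ((y1 - 1) + (R_xlen_t)ny * (z0 - 1));
        R_xlen_t b001 = (x0 - 1) + (R_xlen_t)nx * ((y0 - 1) + (R_xlen_t)ny * (z1 - 1));
        R_xlen_t b101 = (x1 - 1) + (R_xlen_t)nx * ((y0 - 1) + (R_xlen_t)ny * (z1 - 1));
        R_xlen_t b011 = (x0 - 1) + (R_xlen_t)nx * ((y1 - 1) + (R_xlen_t)ny * (z1 - 1));
        R_xlen_t b111 = (x1 - 1) + (R_xlen_t)nx * ((y1 - 1) + (R_xlen_t)ny * (z1 - 1));
        out[idx] =
          img[b000] * (1 - fx) * (1 - fy) * (1 - fz) +
          img[b100] * fx * (1 - fy) * (1 - fz) +
          img[b010] * (1 - fx) * fy * (1 - fz) +
          img[b110] * fx * fy * (1 - fz) +
          img[b001] * (1 - fx) * (1 - fy) * fz +
          img[b101] * fx * (1 - fy) * fz +
          img[b011] * (1 - fx) * fy * fz +
          img[b111] * fx * fy * fz;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector warp3_scatter(NumericVector img, IntegerVector dims,
                            NumericVector ux, NumericVector uy,
                            NumericVector uz) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  R_xlen_t idx = 0;
  for (int z = 1; z <= nz; ++z) {
    for (int y = 1; y <= ny; ++y) {
      for (int x = 1; x <= nx; ++x, ++idx) {
        double px = clampd(x + ux[idx], 1.0, (double)nx);
        double py = clampd(y + uy[idx], 1.0, (double)ny);
        double pz = clampd(z + uz[idx], 1.0, (double)nz);
        int x0 = (int)px; if (x0 > nx - 1) x0 = nx - 1; if (nx == 1) x0 = 1;
        int y0 = (int)py; if (y0 > ny - 1) y0 = ny - 1; if (ny == 1) y0 = 1;
        int z0 = (int)pz; if (z0 > nz - 1) z0 = nz - 1; if (nz == 1) z0 = 1;
        double fx = px - x0, fy = py - y0, fz = pz - z0;
        int x1 = nx == 1 ? x0 : x0 + 1;
        int y1 = ny == 1 ? y0 : y0 + 1;
        int z1 = nz == 1 ? z0 : z0 + 1;
        if (nx == 1) fx = 0.0; if (ny == 1) fy = 0.0; if (nz == 1) fz = 0.0;
        double v = img[idx];
        R_xlen_t b000 = (x0 - 1) + (R_xlen_t)nx * ((y0 - 1) + (R_xlen_t)ny * (z0 - 1));
        R_xlen_t b100 = (x1 - 1) + (R_xlen_t)nx * ((y0 - 1) + (R_xlen_t)ny * (z0 - 1));
        R_xlen_t b010 = (x0 - 1) + (R_xlen_t)nx * ((y1 - 1) + (R_xlen_t)ny * (z0 - 1));
        R_xlen_t b110 = (x1 - 1) + (R_xlen_t)nx * ((y1 - 1) + (R_xlen_t)ny * (z0 - 1));
        R_xlen_t b001 = (x0 - 1) + (R_xlen_t)nx * ((y0 - 1) + (R_xlen_t)ny * (z1 - 1));
        R_xlen_t b101 = (x1 - 1) + (R_xlen_t)nx * ((y0 - 1) + (R_xlen_t)ny * (z1 - 1));
        R_xlen_t b011 = (x0 - 1) + (R_xlen_t)nx * ((y1 - 1) + (R_xlen_t)ny * (z1 - 1));
        R_xlen_t b111 = (x1 - 1) + (R_xlen_t)nx * ((y1 - 1) + (R_xlen_t)ny * (z1 - 1));
        out[b000] += v * (1 - fx) * (1 - fy) * (1 - fz);
        out[b100] += v * fx * (1 - fy) * (1 - fz);
        out[b010] += v * (1 - fx) * fy * (1 - fz);
        out[b110] += v * fx * fy * (1 - fz);
        out[b001] += v * (1 - fx) * (1 - fy) * fz;
        out[b101] += v * fx * (1 - fy) * fz;
        out[b011] += v * (1 - fx) * fy * fz;
        out[b111] += v * fx * fy * fz;
      }
    }
  }
  return out;
}
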