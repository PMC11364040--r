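// Minimal 3D neural-network kernels for the volumetric U-Net denoiser:
// same-padded 3D cross-correlation ("conv") with full backward pass,
// 2x max-pooling, and 2x nearest-neighbour upsampling. Arrays are R
// numeric arrays in column-major layout with dims (nx, ny, nz, channels);
// kernels have dims (k, k, k, c_in, c_out). Single-threaded and exactly
// deterministic.
#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

static inline size_t vol3(const IntegerVector& d) {
  return (size_t)d[0] * d[1] * d[2];
}

// [[Rcpp::export]]
NumericVector conv3d_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int nx = xd[0], ny = xd[1], nz = xd[2], cin = xd[3];
  const int k = wd[0], cout = wd[4];
  if (wd[3] != cin) stop("kernel c_in does not match input channels");
  if (k % 2 == 0) stop("kernel edge must be odd");
  const int p = (k - 1) / 2;
  const size_t nvol = (size_t)nx * ny * nz;
  NumericVector y(nvol * cout);
  y.attr("dim") = IntegerVector::create(nx, ny, nz, cout);
  const double* xp = REAL(x);
  const double* wp = REAL(w);
  double* yp = REAL(y);
  for (int co = 0; co < cout; ++co) {
    double* yco = yp + nvol * co;
    std::fill(yco, yco + nvol, b[co]);
    for (int ci = 0; ci < cin; ++ci) {
      const double* xci = xp + nvol * ci;
      for (int dz = -p; dz <= p; ++dz)
        for (int dy = -p; dy <= p; ++dy)
          for (int dx = -p; dx <= p; ++dx) {
            const double wv =
              wp[(size_t)(dx + p) +
                 (size_t)k * ((dy + p) + (size_t)k * ((dz + p) +
                 (size_t)k * (ci + (size_t)cin * co)))];
            if (wv == 0.0) continue;
            const int z0 = std::max(0, -dz), z1 = nz - std::max(0, dz);
            const int y0 = std::max(0, -dy), y1 = ny - std::max(0, dy);
            const int x0 = std::max(0, -dx), x1 = nx - std::max(0, dx);
            for (int z = z0; z < z1; ++z)
              for (int yy = y0; yy < y1; ++yy) {
                double* yrow = yco + (size_t)nx * (yy + (size_t)ny * z);
                const double* xrow = xci +
                  (size_t)nx * ((yy + dy) + (size_t)ny * (z + dz)) + dx;
                for (int xx = x0; xx < x1; ++xx) yrow[xx] += wv * xrow[xx];
              }
          }
    }
  }
  return y;
}

// [[Rcpp::export]]
List conv3d_bwd(NumericVector x, NumericVector w, NumericVector gy) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int nx = xd[0], ny = xd[1], nz = xd[2], cin = xd[3];
  const int k = wd[0], cout = wd[4];
  const int p = (k - 1) / 2;
  const size_t nvol = (size_t)nx * ny * nz;
  NumericVector gx(x.size());
  gx.attr("dim") = xd;
  NumericVector gw(w.size());
  gw.attr("dim") = wd;
  NumericVector gb(cout);
  const double* xp = REAL(x);
  const double* wp = REAL(w);
  const double* gyp = REAL(gy);
  double* gxp = REAL(gx);
  double* gwp = REAL(gw);
  for (int co = 0; co < cout; ++co) {
    const double* gyco = gyp + nvol * co;
    double s = 0.0;
    for (size_t i = 0; i < nvol; ++i) s += gyco[i];
    gb[co] = s;
    for (int ci = 0; ci < cin; ++ci) {
      const double* xci = xp + nvol * ci;
      double* gxci = gxp + nvol * ci;
      for (int dz = -p; dz <= p; ++dz)
        for (int dy = -p; dy <= p; ++dy)
          for (int dx = -p; dx <= p; ++dx) {
            const size_t wi = (size_t)(dx + p) +
              (size_t)k * ((dy + p) + (size_t)k * ((dz + p) +
              (size_t)k * (ci + (size_t)cin * co)));
            const double wv = wp[wi];
            double acc = 0.0;
            const int z0 = std::max(0, -dz), z1 = nz - std::max(0, dz);
            const int y0 = std::max(0, -dy), y1 = ny - std::max(0, dy);
            const int x0 = std::max(0, -dx), x1 = nx - std::max(0, dx);
            for (int z = z0; z < z1; ++z)
              for (int yy = y0; yy < y1; ++yy) {
                const double* gyrow = gyco + (size_t)nx * (yy + (size_t)ny * z);
                const size_t off =
                  (size_t)nx * ((yy + dy) + (size_t)ny * (z + dz)) + dx;
                const double* xrow = xci + off;
                double* gxrow = gxci + off;
                for (int xx = x0; xx < x1; ++xx) {
                  const double g = gyrow[xx];
                  acc += g * xrow[xx];
                  gxrow[xx] += wv * g;
                }
              }
            gwp[wi] += acc;
          }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
List maxpool3d_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int nx = xd[0], ny = xd[1], nz = xd[2], nc = xd[3];
  if (nx % 2 || ny % 2 || nz % 2)
    stop("max-pooling requires even spatial dimensions; got %dx%dx%d",
         nx, ny, nz);
  const int ox = nx / 2, oy = ny / 2, oz = nz / 2;
  const size_t nvol = (size_t)nx * ny * nz, ovol = (size_t)ox * oy * oz;
  NumericVector y(ovol * nc);
  y.attr("dim") = IntegerVector::create(ox, oy, oz, nc);
  IntegerVector arg(ovol * nc);  // 0-based linear index into x
  const double* xp = REAL(x);
  double* yp = REAL(y);
  int* ap = INTEGER(arg);
  for (int c = 0; c < nc; ++c) {
    const double* xc = xp + nvol * c;
    double* yc = yp + ovol * c;
    int* ac = ap + ovol * c;
    for (int z = 0; z < oz; ++z)
      for (int yy = 0; yy < oy; ++yy)
        for (int xx = 0; xx < ox; ++xx) {
          double best = R_NegInf;
          size_t besti = 0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                const size_t i = (size_t)(2 * xx + dx) +
                  (size_t)nx * ((2 * yy + dy) + (size_t)ny * (2 * z + dz));
                if (xc[i] > best) { best = xc[i]; besti = i; }
              }
          const size_t o = (size_t)xx + (size_t)ox * (yy + (size_t)oy * z);
          yc[o] = best;
          ac[o] = (int)(besti + nvol * c);
        }
  }
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool3d_bwd(IntegerVector argmax, NumericVector gy,
                            IntegerVector xdim) {
  NumericVector gx((size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  gx.attr("dim") = xdim;
  double* gxp = REAL(gx);
  const double* gyp = REAL(gy);
  const int* ap = INTEGER(argmax);
  const R_xlen_t n = gy.size();
  for (R_xlen_t i = 0; i < n; ++i) gxp[ap[i]] += gyp[i];
  return gx;
}

// [[Rcpp::export]]
NumericVector upsample3d_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int nx = xd[0], ny = xd[1], nz = xd[2], nc = xd[3];
  const int ox = nx * 2, oy = ny * 2, oz = nz * 2;
  const size_t nvol = (size_t)nx * ny * nz, ovol = (size_t)ox * oy * oz;
  NumericVector y(ovol * nc);
  y.attr("dim") = IntegerVector::create(ox, oy, oz, nc);
  const double* xp = REAL(x);
  double* yp = REAL(y);
  for (int c = 0; c < nc; ++c) {
    const double* xc = xp + nvol * c;
    double* yc = yp + ovol * c;
    for (int z = 0; z < oz; ++z)
      for (int yy = 0; yy < oy; ++yy) {
        const double* xrow = xc + (size_t)nx * ((yy / 2) + (size_t)ny * (z / 2));
        double* yrow = yc + (size_t)ox * (yy + (size_t)oy * z);
        for (int xx = 0; xx < ox; ++xx) yrow[xx] = xrow[xx / 2];
      }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector upsample3d_bwd(NumericVector gy, IntegerVector xdim) {
  const int nx = xdim[0], ny = xdim[1], nz = xdim[2], nc = xdim[3];
  const int ox = nx * 2, oy = ny * 2, oz = nz * 2;
  const size_t nvol = (size_t)nx * ny * nz, ovol = (size_t)ox * oy * oz;
  NumericVector gx(nvol * nc);
  gx.attr("dim") = xdim;
  const double* gyp = REAL(gy);
  double* gxp = REAL(gx);
  for (int c = 0; c < nc; ++c) {
    const double* gyc = gyp + ovol * c;
    double* gxc = gxp + nvol * c;
    for (int z = 0; z < oz; ++z)
      for (int yy = 0; yy < oy; ++yy) {
        double* gxrow = gxc + (size_t)nx * ((yy / 2) + (size_t)ny * (z / 2));
        const double* gyrow = gyc + (size_t)ox * (yy + (size_t)oy * z);
        for (int xx = 0; xx < ox; ++xx) gxrow[xx / 2] += gyrow[xx];
      }
  }
  return gx;
}
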