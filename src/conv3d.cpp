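// 3D convolution, pooling and upsampling kernels for the compact U-Net.
// Layout: column-major R arrays (nx, ny, nz, channels); kernels are 3x3x3
// cross-correlations with zero padding 1 ("same" output size).
#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

static inline R_xlen_t vidx(int i, int j, int k, int c, int nx, int ny, int nz) {
  return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * ((R_xlen_t)k + (R_xlen_t)nz * c));
}

// Gather the 27-neighbourhood of voxel (i,j,k) for all channels into
// buf[ci*27 + o], zero-padded at the borders.
static inline void gather27(const double *p, int nx, int ny, int nz, int nc,
                            R_xlen_t nvox, int i, int j, int k, double *buf) {
  const bool interior = i > 0 && j > 0 && k > 0 &&
    i < nx - 1 && j < ny - 1 && k < nz - 1;
  for (int c = 0; c < nc; ++c) {
    const double *pc = p + nvox * c;
    double *bc = buf + 27 * c;
    int o = 0;
    if (interior) {
      for (int oz = -1; oz <= 1; ++oz)
        for (int oy = -1; oy <= 1; ++oy) {
          const double *row = pc + (R_xlen_t)(i - 1) +
            (R_xlen_t)nx * ((j + oy) + (R_xlen_t)ny * (k + oz));
          bc[o++] = row[0]; bc[o++] = row[1]; bc[o++] = row[2];
        }
    } else {
      for (int oz = -1; oz <= 1; ++oz)
        for (int oy = -1; oy <= 1; ++oy)
          for (int ox = -1; ox <= 1; ++ox) {
            const int ii = i + ox, jj = j + oy, kk = k + oz;
            bc[o++] = (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny ||
                       kk >= nz)
              ? 0.0
              : pc[(R_xlen_t)ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk)];
          }
    }
  }
}

// x: (nx,ny,nz,cin), w: (27, cin, cout) with offset order
// o = (ox+1) + 3*(oy+1) + 9*(oz+1), ox/oy/oz in {-1,0,1}; b: cout
// [[Rcpp::export(name = ".cpp_conv3d_fwd")]]
NumericVector cpp_conv3d_fwd(NumericVector x, NumericVector w, NumericVector b,
                             IntegerVector dims, int cin, int cout) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  NumericVector y(nvox * cout);
  const double *px = x.begin(), *pw = w.begin(), *pb = b.begin();
  double *py = y.begin();
  std::vector<double> buf(27 * cin);
  const int nk = 27 * cin;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        gather27(px, nx, ny, nz, cin, nvox, i, j, k, buf.data());
        const R_xlen_t p = (R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        for (int co = 0; co < cout; ++co) {
          const double *wc = pw + (R_xlen_t)nk * co;
          double acc = pb[co];
          for (int t = 0; t < nk; ++t) acc += wc[t] * buf[t];
          py[p + nvox * co] = acc;
        }
      }
  return y;
}

// Gradients w.r.t. input, weights and bias of cpp_conv3d_fwd.
// [[Rcpp::export(name = ".cpp_conv3d_bwd")]]
List cpp_conv3d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                    IntegerVector dims, int cin, int cout) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  NumericVector gx(nvox * cin), gw(27 * (R_xlen_t)cin * cout), gb(cout);
  const double *px = x.begin(), *pw = w.begin(), *pgy = gy.begin();
  double *pgx = gx.begin(), *pgw = gw.begin(), *pgb = gb.begin();
  const int nk = 27 * cin;
  std::vector<double> xbuf(27 * cin), gybuf(27 * cout);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const R_xlen_t p = (R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        gather27(px, nx, ny, nz, cin, nvox, i, j, k, xbuf.data());
        gather27(pgy, nx, ny, nz, cout, nvox, i, j, k, gybuf.data());
        for (int co = 0; co < cout; ++co) {
          const double g = pgy[p + nvox * co];
          pgb[co] += g;
          double *gwc = pgw + (R_xlen_t)nk * co;
          for (int t = 0; t < nk; ++t) gwc[t] += g * xbuf[t];
        }
        // gx[p,ci] = sum_{o,co} w[o,ci,co] * gy[p-o,co]; gy[p-o] sits at the
        // flipped offset 26-o' within gybuf's own 27-neighbourhood layout,
        // which for channel co is gybuf[co*27 + (26-o)].
        for (int ci = 0; ci < cin; ++ci) {
          double acc = 0.0;
          for (int co = 0; co < cout; ++co) {
            const double *wc = pw + 27 * ((R_xlen_t)ci + (R_xlen_t)cin * co);
            const double *gb27 = gybuf.data() + 27 * co;
            for (int o = 0; o < 27; ++o) acc += wc[o] * gb27[26 - o];
          }
          pgx[p + nvox * ci] = acc;
        }
      }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2x2 max pooling; dims must be even. Returns pooled values and the
// 1-based flat index of each max for the backward pass.
// [[Rcpp::export(name = ".cpp_maxpool3d")]]
List cpp_maxpool3d(NumericVector x, IntegerVector dims, int nc) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int mx = nx / 2, my = ny / 2, mz = nz / 2;
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz, mvox = (R_xlen_t)mx * my * mz;
  NumericVector y(mvox * nc);
  IntegerVector amax(mvox * nc);
  const double *px = x.begin();
  for (int c = 0; c < nc; ++c) {
    const double *xc = px + nvox * c;
    for (int k = 0; k < mz; ++k)
      for (int j = 0; j < my; ++j)
        for (int i = 0; i < mx; ++i) {
          double best = -1e300; R_xlen_t bi = 0;
          for (int dk = 0; dk < 2; ++dk)
            for (int dj = 0; dj < 2; ++dj)
              for (int di = 0; di < 2; ++di) {
                R_xlen_t id = vidx(2 * i + di, 2 * j + dj, 2 * k + dk, 0, nx, ny, nz);
                if (xc[id] > best) { best = xc[id]; bi = id; }
              }
          R_xlen_t o = (R_xlen_t)i + (R_xlen_t)mx * (j + (R_xlen_t)my * (k + (R_xlen_t)mz * c));
          y[o] = best;
          amax[o] = (int)(bi + nvox * c) + 1;
        }
  }
  return List::create(_["y"] = y, _["amax"] = amax,
                      _["dims"] = IntegerVector::create(mx, my, mz));
}

// [[Rcpp::export(name = ".cpp_maxpool3d_bwd")]]
NumericVector cpp_maxpool3d_bwd(NumericVector gy, IntegerVector amax,
                                R_xlen_t n_in) {
  NumericVector gx(n_in);
  for (R_xlen_t t = 0; t < gy.size(); ++t) gx[amax[t] - 1] += gy[t];
  return gx;
}

// Nearest-neighbour 2x upsampling.
// [[Rcpp::export(name = ".cpp_upsample3d")]]
NumericVector cpp_upsample3d(NumericVector x, IntegerVector dims, int nc) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int ux = nx * 2, uy = ny * 2, uz = nz * 2;
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz, uvox = (R_xlen_t)ux * uy * uz;
  NumericVector y(uvox * nc);
  for (int c = 0; c < nc; ++c) {
    const double *xc = x.begin() + nvox * c;
    double *yc = y.begin() + uvox * c;
    for (int k = 0; k < uz; ++k)
      for (int j = 0; j < uy; ++j) {
        const double *xr = xc + (R_xlen_t)nx * ((j / 2) + (R_xlen_t)ny * (k / 2));
        double *yr = yc + (R_xlen_t)ux * (j + (R_xlen_t)uy * k);
        for (int i = 0; i < ux; ++i) yr[i] = xr[i / 2];
      }
  }
  return y;
}

// Adjoint of nearest upsampling: sum each 2x2x2 block.
// [[Rcpp::export(name = ".cpp_upsample3d_bwd")]]
NumericVector cpp_upsample3d_bwd(NumericVector gy, IntegerVector dims_in, int nc) {
  const int nx = dims_in[0], ny = dims_in[1], nz = dims_in[2];
  const int ux = nx * 2, uy = ny * 2, uz = nz * 2;
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz, uvox = (R_xlen_t)ux * uy * uz;
  NumericVector gx(nvox * nc);
  for (int c = 0; c < nc; ++c) {
    double *gc = gx.begin() + nvox * c;
    const double *yc = gy.begin() + uvox * c;
    for (int k = 0; k < uz; ++k)
      for (int j = 0; j < uy; ++j) {
        double *gr = gc + (R_xlen_t)nx * ((j / 2) + (R_xlen_t)ny * (k / 2));
        const double *yr = yc + (R_xlen_t)ux * (j + (R_xlen_t)uy * k);
        for (int i = 0; i < ux; ++i) gr[i / 2] += yr[i];
      }
  }
  return gx;
}
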