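// Raster utilities: interpolation at arbitrary points, exact Euclidean
// distance transform, connected-component labelling and box morphology.
#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Trilinear interpolation at continuous 0-based voxel coordinates.
// pts: n x 3 matrix; outside the grid -> fill.
// [[Rcpp::export(name = ".cpp_trilinear")]]
NumericVector cpp_trilinear(NumericVector vox, IntegerVector dims,
                            NumericMatrix pts, double fill) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = pts.nrow();
  NumericVector out(n);
  const double *pv = vox.begin();
  for (R_xlen_t t = 0; t < n; ++t) {
    const double x = pts(t, 0), y = pts(t, 1), z = pts(t, 2);
    if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1) {
      out[t] = fill; continue;
    }
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
    if (i0 == nx - 1) --i0;
    if (j0 == ny - 1) --j0;
    if (k0 == nz - 1) --k0;
    if (nx == 1) i0 = 0;
    if (ny == 1) j0 = 0;
    if (nz == 1) k0 = 0;
    const double fx = x - i0, fy = y - j0, fz = z - k0;
    const int i1 = std::min(i0 + 1, nx - 1), j1 = std::min(j0 + 1, ny - 1),
              k1 = std::min(k0 + 1, nz - 1);
    auto at = [&](int i, int j, int k) {
      return pv[(R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
    };
    const double c00 = at(i0, j0, k0) * (1 - fx) + at(i1, j0, k0) * fx;
    const double c10 = at(i0, j1, k0) * (1 - fx) + at(i1, j1, k0) * fx;
    const double c01 = at(i0, j0, k1) * (1 - fx) + at(i1, j0, k1) * fx;
    const double c11 = at(i0, j1, k1) * (1 - fx) + at(i1, j1, k1) * fx;
    out[t] = (c00 * (1 - fy) + c10 * fy) * (1 - fz) + (c01 * (1 - fy) + c11 * fy) * fz;
  }
  return out;
}

// Nearest-neighbour sampling at continuous 0-based voxel coordinates.
// [[Rcpp::export(name = ".cpp_nearest")]]
NumericVector cpp_nearest(NumericVector vox, IntegerVector dims,
                          NumericMatrix pts, double fill) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = pts.nrow();
  NumericVector out(n);
  for (R_xlen_t t = 0; t < n; ++t) {
    const int i = (int)std::lround(pts(t, 0)), j = (int)std::lround(pts(t, 1)),
              k = (int)std::lround(pts(t, 2));
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) out[t] = fill;
    else out[t] = vox[(R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
  }
  return out;
}

// Felzenszwalb & Huttenlocher 1D squared distance transform.
static void dt1d(const double *f, double *d, int n, double step2) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0; z[0] = -1e300; z[1] = 1e300;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      const int p = v[k];
      s = ((f[q] + step2 * q * q) - (f[p] + step2 * p * p)) / (2.0 * step2 * (q - p));
      if (s > z[k]) break;
      --k;
    }
    ++k; v[k] = q; z[k] = s; z[k + 1] = 1e300;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    const double dq = (double)(q - v[k]);
    d[q] = step2 * dq * dq + f[v[k]];
  }
}

// Exact Euclidean distance (mm) from each foreground voxel to the nearest
// background voxel; 0 on background. Anisotropic spacing supported.
// [[Rcpp::export(name = ".cpp_edt3d")]]
NumericVector cpp_edt3d(LogicalVector mask, IntegerVector dims,
                        NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  NumericVector d(nvox);
  for (R_xlen_t t = 0; t < nvox; ++t) d[t] = mask[t] ? 1e300 : 0.0;
  std::vector<double> buf(std::max(nx, std::max(ny, nz)));
  std::vector<double> res(buf.size());
  double *pd = d.begin();
  // pass along x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      double *row = pd + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      dt1d(row, res.data(), nx, spacing[0] * spacing[0]);
      std::copy(res.begin(), res.begin() + nx, row);
    }
  // pass along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) buf[j] = pd[(R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
      dt1d(buf.data(), res.data(), ny, spacing[1] * spacing[1]);
      for (int j = 0; j < ny; ++j) pd[(R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = res[j];
    }
  // pass along z
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k) buf[k] = pd[(R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
      dt1d(buf.data(), res.data(), nz, spacing[2] * spacing[2]);
      for (int k = 0; k < nz; ++k) pd[(R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = res[k];
    }
  for (R_xlen_t t = 0; t < nvox; ++t) pd[t] = std::sqrt(pd[t]);
  return d;
}

// Connected-component labels (1..ncomp, 0 background), 6- or 26-connectivity.
// [[Rcpp::export(name = ".cpp_label3d")]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dims, int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(nvox);
  std::vector<std::array<int, 3>> nb;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        if (connectivity == 6 && std::abs(dx) + std::abs(dy) + std::abs(dz) > 1) continue;
        nb.push_back({dx, dy, dz});
      }
  int cur = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < nvox; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++cur;
    stack.push_back(s);
    lab[s] = cur;
    while (!stack.empty()) {
      const R_xlen_t p = stack.back(); stack.pop_back();
      const int i = (int)(p % nx), j = (int)((p / nx) % ny), k = (int)(p / ((R_xlen_t)nx * ny));
      for (auto &o : nb) {
        const int ii = i + o[0], jj = j + o[1], kk = k + o[2];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
        const R_xlen_t q = (R_xlen_t)ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
        if (mask[q] && !lab[q]) { lab[q] = cur; stack.push_back(q); }
      }
    }
  }
  return lab;
}

// Separable box dilation (maximum filter) with radius r voxels per axis.
static void box_pass(std::vector<double> &v, std::vector<double> &tmp, int n, int r, bool maxop) {
  for (int q = 0; q < n; ++q) {
    double best = v[q];
    for (int d = -r; d <= r; ++d) {
      const int p = q + d;
      if (p < 0 || p >= n) continue;
      if (maxop ? v[p] > best : v[p] < best) best = v[p];
    }
    tmp[q] = best;
  }
  std::copy(tmp.begin(), tmp.begin() + n, v.begin());
}

// [[Rcpp::export(name = ".cpp_box_morph")]]
LogicalVector cpp_box_morph(LogicalVector mask, IntegerVector dims, int r, bool dilate) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  std::vector<double> d(nvox);
  for (R_xlen_t t = 0; t < nvox; ++t) d[t] = mask[t] ? 1.0 : 0.0;
  const int mdim = std::max(nx, std::max(ny, nz));
  std::vector<double> line(mdim), tmp(mdim);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      double *row = d.data() + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      std::copy(row, row + nx, line.begin());
      box_pass(line, tmp, nx, r, dilate);
      std::copy(line.begin(), line.begin() + nx, row);
    }
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) line[j] = d[(R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
      box_pass(line, tmp, ny, r, dilate);
      for (int j = 0; j < ny; ++j) d[(R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = line[j];
    }
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k) line[k] = d[(R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
      box_pass(line, tmp, nz, r, dilate);
      for (int k = 0; k < nz; ++k) d[(R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = line[k];
    }
  LogicalVector out(nvox);
  for (R_xlen_t t = 0; t < nvox; ++t) out[t] = d[t] > 0.5;
  return out;
}

// 26-connectivity neighbour edge list over foreground voxels, weighted by
// physical step length divided by a medialness factor supplied per voxel.
// Returns 1-based voxel indices (restricted to mask) and weights.
// [[Rcpp::export(name = ".cpp_mask_graph")]]
List cpp_mask_graph(LogicalVector mask, IntegerVector dims, NumericVector spacing,
                    NumericVector medial) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  // map voxel -> node id (1-based over mask voxels)
  std::vector<int> node(nvox, 0);
  int nn = 0;
  for (R_xlen_t t = 0; t < nvox; ++t) if (mask[t]) node[t] = ++nn;
  std::vector<int> from, to;
  std::vector<double> wt;
  from.reserve(nn * 13); to.reserve(nn * 13); wt.reserve(nn * 13);
  // half of the 26 neighbourhood to avoid duplicate edges
  std::vector<std::array<int, 3>> nb;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dz > 0 || (dz == 0 && (dy > 0 || (dy == 0 && dx > 0)))) nb.push_back({dx, dy, dz});
      }
  for (R_xlen_t t = 0; t < nvox; ++t) {
    if (!mask[t]) continue;
    const int i = (int)(t % nx), j = (int)((t / nx) % ny), k = (int)(t / ((R_xlen_t)nx * ny));
    for (auto &o : nb) {
      const int ii = i + o[0], jj = j + o[1], kk = k + o[2];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
      const R_xlen_t q = (R_xlen_t)ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
      if (!mask[q]) continue;
      const double step = std::sqrt(
        o[0] * o[0] * spacing[0] * spacing[0] +
        o[1] * o[1] * spacing[1] * spacing[1] +
        o[2] * o[2] * spacing[2] * spacing[2]);
      const double m = 0.5 * (medial[t] + medial[q]);
      from.push_back(node[t]);
      to.push_back(node[q]);
      wt.push_back(step / m);
    }
  }
  IntegerVector vox_of_node(nn);
  for (R_xlen_t t = 0; t < nvox; ++t) if (node[t]) vox_of_node[node[t] - 1] = (int)(t + 1);
  return List::create(_["from"] = wrap(from), _["to"] = wrap(to),
                      _["weight"] = wrap(wt), _["voxel"] = vox_of_node);
}
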