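// Low-level 3-D image kernels. Arrays arrive as R arrays with dim (nz, ny, nx),
// column-major, so linear index = z + nz*(y + ny*x), 0-based here.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <limits>
using namespace Rcpp;

static inline int reflect_idx(int i, int n) {
  // scipy-style "reflect": (c b a | a b c | c b a)
  if (n == 1) return 0;
  const int period = 2 * n;
  i %= period;
  if (i < 0) i += period;
  return (i < n) ? i : (period - 1 - i);
}

// [[Rcpp::export]]
NumericVector cpp_conv1d_axis(NumericVector arr, IntegerVector dims, int axis,
                              NumericVector kernel) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int nk = kernel.size(), half = nk / 2;
  NumericVector out(arr.size());
  const int n_axis = (axis == 1) ? nz : (axis == 2) ? ny : nx;
  // strides for walking along the chosen axis
  const int stride = (axis == 1) ? 1 : (axis == 2) ? nz : nz * ny;
  std::vector<double> line(n_axis);
  const int n1 = (axis == 1) ? ny : nz;
  const int n2 = (axis == 3) ? ny : nx;
  for (int b = 0; b < n2; ++b) {
    for (int a = 0; a < n1; ++a) {
      int base;
      if (axis == 1)      base = nz * (a + ny * b);       // a=y, b=x
      else if (axis == 2) base = a + nz * ny * b;          // a=z, b=x
      else                base = a + nz * b;               // a=z, b=y
      for (int i = 0; i < n_axis; ++i) line[i] = arr[base + i * stride];
      for (int i = 0; i < n_axis; ++i) {
        double acc = 0.0;
        for (int k = 0; k < nk; ++k)
          acc += kernel[k] * line[reflect_idx(i + k - half, n_axis)];
        out[base + i * stride] = acc;
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_median3(NumericVector arr, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  NumericVector out(arr.size());
  std::vector<double> buf(27);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        int n = 0;
        for (int dx = -1; dx <= 1; ++dx) {
          const int xx = reflect_idx(x + dx, nx);
          for (int dy = -1; dy <= 1; ++dy) {
            const int yy = reflect_idx(y + dy, ny);
            for (int dz = -1; dz <= 1; ++dz)
              buf[n++] = arr[reflect_idx(z + dz, nz) + nz * (yy + ny * xx)];
          }
        }
        std::nth_element(buf.begin(), buf.begin() + 13, buf.begin() + 27);
        out[z + nz * (y + ny * x)] = buf[13];
      }
  out.attr("dim") = dims;
  return out;
}

// 26-connected component labeling; labels assigned in ascending order of the
// first (lowest linear index) voxel of each component.
// [[Rcpp::export]]
IntegerVector cpp_label26(LogicalVector mask, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int n = mask.size();
  IntegerVector lab(n, 0);
  std::vector<int> stack;
  int next = 0;
  for (int idx = 0; idx < n; ++idx) {
    if (!mask[idx] || lab[idx]) continue;
    ++next;
    lab[idx] = next;
    stack.push_back(idx);
    while (!stack.empty()) {
      const int cur = stack.back(); stack.pop_back();
      const int z = cur % nz, y = (cur / nz) % ny, x = cur / (nz * ny);
      for (int dx = -1; dx <= 1; ++dx) {
        const int xx = x + dx; if (xx < 0 || xx >= nx) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          const int yy = y + dy; if (yy < 0 || yy >= ny) continue;
          for (int dz = -1; dz <= 1; ++dz) {
            const int zz = z + dz; if (zz < 0 || zz >= nz) continue;
            const int nb = zz + nz * (yy + ny * xx);
            if (mask[nb] && !lab[nb]) { lab[nb] = next; stack.push_back(nb); }
          }
        }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// 1-D squared distance transform of a sampled function (lower envelope of
// parabolas), with physical sample spacing w.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 double w, std::vector<int>& v, std::vector<double>& zz) {
  const int n = (int)f.size();
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0; zz[0] = -INF; zz[1] = INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;
    if (f[v[0]] == INF && k == 0) { v[0] = q; continue; }
    double s;
    while (true) {
      const int p = v[k];
      s = ((f[q] + w * w * q * q) - (f[p] + w * w * p * p)) / (2.0 * w * w * (q - p));
      if (s <= zz[k]) { --k; } else break;
    }
    ++k; v[k] = q; zz[k] = s; zz[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    if (f[v[0]] == INF) { d[q] = INF; continue; }
    while (zz[k + 1] < (double)q) ++k;  // zz holds intersection *indices*
    const double dq = w * (q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
}

// Anisotropy-aware Euclidean distance transform: distance (um) from every
// voxel to the nearest TRUE voxel of `mask`. Empty mask -> all Inf.
// [[Rcpp::export]]
NumericVector cpp_edt3d(LogicalVector mask, IntegerVector dims,
                        double sz, double sy, double sx) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const double INF = std::numeric_limits<double>::infinity();
  NumericVector out(mask.size());
  for (int i = 0; i < mask.size(); ++i) out[i] = mask[i] ? 0.0 : INF;
  const int nmax = std::max(nz, std::max(ny, nx));
  std::vector<double> f(nmax), d(nmax), zbuf(nmax + 1);
  std::vector<int> v(nmax);
  // pass along z
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      const int base = nz * (y + ny * x);
      f.assign(nz, 0.0);
      for (int z = 0; z < nz; ++z) f[z] = out[base + z];
      d.assign(nz, 0.0);
      dt1d(f, d, sz, v, zbuf);
      for (int z = 0; z < nz; ++z) out[base + z] = d[z];
    }
  // pass along y
  for (int x = 0; x < nx; ++x)
    for (int z = 0; z < nz; ++z) {
      f.assign(ny, 0.0);
      for (int y = 0; y < ny; ++y) f[y] = out[z + nz * (y + ny * x)];
      d.assign(ny, 0.0);
      dt1d(f, d, sy, v, zbuf);
      for (int y = 0; y < ny; ++y) out[z + nz * (y + ny * x)] = d[y];
    }
  // pass along x
  for (int y = 0; y < ny; ++y)
    for (int z = 0; z < nz; ++z) {
      f.assign(nx, 0.0);
      for (int x = 0; x < nx; ++x) f[x] = out[z + nz * (y + ny * x)];
      d.assign(nx, 0.0);
      dt1d(f, d, sx, v, zbuf);
      for (int x = 0; x < nx; ++x) out[z + nz * (y + ny * x)] = std::sqrt(d[x]);
    }
  out.attr("dim") = dims;
  return out;
}

// Minimum Euclidean distance between two point sets (rows = points, um).
// [[Rcpp::export]]
double cpp_min_pair_dist(NumericMatrix a, NumericMatrix b) {
  double best = std::numeric_limits<double>::infinity();
  const int na = a.nrow(), nb = b.nrow(), d = a.ncol();
  for (int i = 0; i < na; ++i) {
    for (int j = 0; j < nb; ++j) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        const double diff = a(i, k) - b(j, k);
        s += diff * diff;
      }
      if (s < best) {
        best = s;
        if (best == 0.0) return 0.0;
      }
    }
  }
  return std::sqrt(best);
}
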