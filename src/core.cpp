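// Computational kernels for radrobust.
//
// Volumes are R arrays in column-major order, dim = (nx, ny, nz); voxel
// (i, j, k) lives at index i + nx * (j + ny * k).  Texture level grids use
// 0 for voxels outside the ROI and 1..n_bins inside.

#include <Rcpp.h>
#include <array>
#include <cmath>
#include <cstring>
#include <vector>
#include <limits>
#include <queue>
#include <map>
#include <algorithm>

using namespace Rcpp;

static inline int idx3(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// 13 unique 3D direction vectors (lexicographically positive half of the
// 26-neighbourhood); shared by GLCM and GLRLM.
static const int DIRS13[13][3] = {
  {1, 0, 0}, {0, 1, 0}, {0, 0, 1},
  {1, 1, 0}, {1, -1, 0}, {1, 0, 1}, {1, 0, -1},
  {0, 1, 1}, {0, 1, -1},
  {1, 1, 1}, {1, 1, -1}, {1, -1, 1}, {1, -1, -1}
};

// ---------------------------------------------------------------------------
// separable Gaussian smoothing, reflect boundary
// ---------------------------------------------------------------------------

static std::vector<double> gauss_kernel(double sigma) {
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * (double)(i * i) / (sigma * sigma));
    s += k[i + r];
  }
  for (double& v : k) v /= s;
  return k;
}

static inline int reflect_idx(int i, int n) {
  // reflect-101 style boundary (abcb|a); degenerates safely for n == 1
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i;
    if (i >= n) i = 2 * (n - 1) - i;
  }
  return i;
}

static void smooth_axis(std::vector<double>& v, int nx, int ny, int nz,
                        int axis, const std::vector<double>& ker) {
  int r = ((int)ker.size() - 1) / 2;
  std::vector<double> out(v.size());
  int n[3] = {nx, ny, nz};
  int na = n[axis];
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int c[3] = {i, j, k};
        double acc = 0.0;
        for (int t = -r; t <= r; ++t) {
          int cc[3] = {c[0], c[1], c[2]};
          cc[axis] = reflect_idx(c[axis] + t, na);
          acc += ker[t + r] * v[idx3(cc[0], cc[1], cc[2], nx, ny)];
        }
        out[idx3(i, j, k, nx, ny)] = acc;
      }
  v.swap(out);
}

// [[Rcpp::export(name = ".cpp_gaussian_smooth3")]]
NumericVector cpp_gaussian_smooth3(NumericVector vol, IntegerVector dim,
                                   double sigma) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> v(vol.begin(), vol.end());
  if (sigma > 0) {
    std::vector<double> ker = gauss_kernel(sigma);
    smooth_axis(v, nx, ny, nz, 0, ker);
    smooth_axis(v, nx, ny, nz, 1, ker);
    if (nz > 1) smooth_axis(v, nx, ny, nz, 2, ker);
  }
  NumericVector out(v.begin(), v.end());
  out.attr("dim") = dim;
  return out;
}

// ---------------------------------------------------------------------------
// stationary (undecimated) single-level 3D wavelet transform, periodic
// ---------------------------------------------------------------------------

static void conv_axis_periodic(const std::vector<double>& in,
                               std::vector<double>& out,
                               int nx, int ny, int nz, int axis,
                               const std::vector<double>& filt, int offset) {
  int n[3] = {nx, ny, nz};
  int na = n[axis];
  int m = (int)filt.size();
  int stride = axis == 0 ? 1 : (axis == 1 ? nx : nx * ny);
  // precompute wrapped positions per axis coordinate
  std::vector<int> pos((size_t)na * m);
  for (int c = 0; c < na; ++c)
    for (int t = 0; t < m; ++t) {
      int p = c + t + offset;
      p %= na; if (p < 0) p += na;
      pos[c * m + t] = p - c;   // relative offset in axis units
    }
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int c[3] = {i, j, k};
        int ca = c[axis];
        int base = idx3(i, j, k, nx, ny);
        const int* pp = &pos[ca * m];
        double acc = 0.0;
        for (int t = 0; t < m; ++t)
          acc += filt[t] * in[base + pp[t] * stride];
        out[base] = acc;
      }
}

// [[Rcpp::export(name = ".cpp_swt3")]]
List cpp_swt3(NumericVector vol, IntegerVector dim,
              NumericVector lo, NumericVector hi) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> filt_lo(lo.begin(), lo.end());
  std::vector<double> filt_hi(hi.begin(), hi.end());
  int off = -((int)filt_lo.size() / 2);  // roughly centre the filter support
  std::vector<double> base(vol.begin(), vol.end());

  // apply along x, then y, then z; band name letter order is (x, y, z)
  std::vector<std::vector<double> > stage1(2), stage2(4), stage3(8);
  std::vector<double> tmp(base.size());
  conv_axis_periodic(base, tmp, nx, ny, nz, 0, filt_lo, off); stage1[0] = tmp;
  conv_axis_periodic(base, tmp, nx, ny, nz, 0, filt_hi, off); stage1[1] = tmp;
  for (int b = 0; b < 2; ++b) {
    conv_axis_periodic(stage1[b], tmp, nx, ny, nz, 1, filt_lo, off);
    stage2[2 * b] = tmp;
    conv_axis_periodic(stage1[b], tmp, nx, ny, nz, 1, filt_hi, off);
    stage2[2 * b + 1] = tmp;
  }
  for (int b = 0; b < 4; ++b) {
    conv_axis_periodic(stage2[b], tmp, nx, ny, nz, 2, filt_lo, off);
    stage3[2 * b] = tmp;
    conv_axis_periodic(stage2[b], tmp, nx, ny, nz, 2, filt_hi, off);
    stage3[2 * b + 1] = tmp;
  }
  // stage3 order: index bits (x,y,z) with 0 = L, 1 = H, x most significant
  const char* names[8] = {"LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH"};
  List out(8);
  CharacterVector nm(8);
  for (int b = 0; b < 8; ++b) {
    int xbit = (b >> 2) & 1, ybit = (b >> 1) & 1, zbit = b & 1;
    int src = 4 * xbit + 2 * ybit + zbit;  // same ordering, kept explicit
    NumericVector v(stage3[src].begin(), stage3[src].end());
    v.attr("dim") = dim;
    out[b] = v;
    nm[b] = names[b];
  }
  out.attr("names") = nm;
  return out;
}

// ---------------------------------------------------------------------------
// squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
// anisotropic spacing, distance to nearest foreground voxel centre
// ---------------------------------------------------------------------------

static void dt1d(std::vector<double>& f, double step) {
  int n = (int)f.size();
  std::vector<double> d(n);
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double xq = q * step;
    double s;
    while (true) {
      double xv = v[k] * step;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * step;
    while (z[k + 1] < xq) ++k;
    double dx = xq - v[k] * step;
    d[q] = dx * dx + f[v[k]];
  }
  f.swap(d);
}

// [[Rcpp::export(name = ".cpp_edt_sq")]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dim,
                         NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  const double INF = 1e30;
  std::vector<double> d(n);
  for (size_t i = 0; i < n; ++i) d[i] = mask[i] ? 0.0 : INF;
  std::vector<double> line;
  // x
  line.resize(nx);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) line[i] = d[idx3(i, j, k, nx, ny)];
      dt1d(line, spacing[0]);
      for (int i = 0; i < nx; ++i) d[idx3(i, j, k, nx, ny)] = line[i];
    }
  // y
  line.resize(ny);
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) line[j] = d[idx3(i, j, k, nx, ny)];
      dt1d(line, spacing[1]);
      for (int j = 0; j < ny; ++j) d[idx3(i, j, k, nx, ny)] = line[j];
    }
  // z
  if (nz > 1) {
    line.resize(nz);
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        for (int k = 0; k < nz; ++k) line[k] = d[idx3(i, j, k, nx, ny)];
        dt1d(line, spacing[2]);
        for (int k = 0; k < nz; ++k) d[idx3(i, j, k, nx, ny)] = line[k];
      }
  }
  NumericVector out(d.begin(), d.end());
  out.attr("dim") = dim;
  return out;
}

// ---------------------------------------------------------------------------
// connected components (6 or 26 connectivity; in-plane this is 4 or 8)
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_label_components")]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  lab.attr("dim") = dim;
  int* L = lab.begin();
  const int* M = mask.begin();   // LogicalVector stores ints
  std::vector<std::array<int, 3> > offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        offs.push_back({dx, dy, dz});
      }
  int cur = 0;
  std::vector<int> stack;
  for (size_t s = 0; s < n; ++s) {
    if (!M[s] || L[s] != 0) continue;
    ++cur;
    stack.clear();
    stack.push_back((int)s);
    L[s] = cur;
    while (!stack.empty()) {
      int p = stack.back();
      stack.pop_back();
      int k = p / (nx * ny), rem = p % (nx * ny);
      int j = rem / nx, i = rem % nx;
      for (const auto& o : offs) {
        int ii = i + o[0], jj = j + o[1], kk = k + o[2];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
          continue;
        int q = idx3(ii, jj, kk, nx, ny);
        if (M[q] && L[q] == 0) {
          L[q] = cur;
          stack.push_back(q);
        }
      }
    }
  }
  return lab;
}

// [[Rcpp::export(name = ".cpp_boundary_mask")]]
LogicalVector cpp_boundary_mask(LogicalVector mask, IntegerVector dim) {
  // boundary = foreground voxel with a 6-neighbour that is background or
  // outside the grid
  int nx = dim[0], ny = dim[1], nz = dim[2];
  LogicalVector out((size_t)nx * ny * nz, false);
  out.attr("dim") = dim;
  const int* M = mask.begin();
  int* O = out.begin();
  const int off[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int p = idx3(i, j, k, nx, ny);
        if (!M[p]) continue;
        for (int t = 0; t < 6; ++t) {
          int ii = i + off[t][0], jj = j + off[t][1], kk = k + off[t][2];
          if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz ||
              !M[idx3(ii, jj, kk, nx, ny)]) {
            O[p] = 1;
            break;
          }
        }
      }
  return out;
}

// [[Rcpp::export(name = ".cpp_max_pair_dist")]]
double cpp_max_pair_dist(NumericMatrix pts) {
  int n = pts.nrow(), m = pts.ncol();
  std::vector<double> p((size_t)n * m);
  for (int c = 0; c < m; ++c)
    for (int a = 0; a < n; ++a) p[a * m + c] = pts(a, c);
  double best = 0.0;
  for (int a = 0; a < n; ++a)
    for (int b = a + 1; b < n; ++b) {
      double d = 0.0;
      for (int c = 0; c < m; ++c) {
        double t = p[a * m + c] - p[b * m + c];
        d += t * t;
      }
      if (d > best) best = d;
    }
  return std::sqrt(best);
}

// [[Rcpp::export(name = ".cpp_max_diameters")]]
List cpp_max_diameters(IntegerMatrix vox, NumericVector spacing) {
  // one O(n^2) pass over voxel coordinates (1-based, columns i,j,k)
  // returning the 3D diameter and the per-plane in-slice diameters
  int n = vox.nrow();
  std::vector<double> xs(n), ys(n), zs(n);
  // voxel indices fit exactly in single precision, so the O(n^2) diameter
  // scan runs in float (4-wide SIMD) and only the final value is promoted
  std::vector<float> fx(n), fy(n), fz(n);
  for (int a = 0; a < n; ++a) {
    xs[a] = vox(a, 0) * spacing[0];
    ys[a] = vox(a, 1) * spacing[1];
    zs[a] = vox(a, 2) * spacing[2];
    fx[a] = (float)vox(a, 0);
    fy[a] = (float)vox(a, 1);
    fz[a] = (float)vox(a, 2);
  }
  float sx = (float)spacing[0], sy = (float)spacing[1],
        sz = (float)spacing[2];
  float f3 = 0;
  int best_a = 0, best_b = 0;
  for (int a = 0; a < n; ++a) {
    float xa = fx[a], ya = fy[a], za = fz[a];
    float local = f3;
    int lb = -1;
    for (int b = a + 1; b < n; ++b) {
      float dx = (xa - fx[b]) * sx, dy = (ya - fy[b]) * sy,
            dz = (za - fz[b]) * sz;
      float q = dx * dx + dy * dy + dz * dz;
      if (q > local) { local = q; lb = b; }
    }
    if (lb >= 0) { f3 = local; best_a = a; best_b = lb; }
  }
  // recompute the winning pair in double precision
  double d3 = 0;
  {
    double dx = xs[best_a] - xs[best_b], dy = ys[best_a] - ys[best_b],
           dz = zs[best_a] - zs[best_b];
    d3 = dx * dx + dy * dy + dz * dz;
  }
  // in-plane diameters: group points by the shared coordinate, pairwise
  // within each (small) group
  auto plane_max = [&](int axis) {
    std::map<int, std::vector<int> > groups;
    for (int a = 0; a < n; ++a) groups[vox(a, axis)].push_back(a);
    double best = 0;
    for (auto& g : groups) {
      const std::vector<int>& id = g.second;
      for (size_t a = 0; a < id.size(); ++a)
        for (size_t b = a + 1; b < id.size(); ++b) {
          double dx = xs[id[a]] - xs[id[b]], dy = ys[id[a]] - ys[id[b]],
                 dz = zs[id[a]] - zs[id[b]];
          double q = dx * dx + dy * dy + dz * dz;
          best = q > best ? q : best;
        }
    }
    return best;
  };
  double ds = plane_max(2), dc = plane_max(1), dr = plane_max(0);
  return List::create(_["max3d"] = std::sqrt(d3),
                      _["slice"] = std::sqrt(ds),
                      _["column"] = std::sqrt(dc),
                      _["row"] = std::sqrt(dr));
}

// ---------------------------------------------------------------------------
// texture matrices
// ---------------------------------------------------------------------------

// collect linear indices and coordinates of in-ROI voxels once per call
template <typename T>
static void roi_voxels(const T* lev, int nx, int ny, int nz,
                       std::vector<int>& vi, std::vector<int>& vj,
                       std::vector<int>& vk) {
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i)
        if (lev[idx3(i, j, k, nx, ny)] != 0) {
          vi.push_back(i); vj.push_back(j); vk.push_back(k);
        }
}

// [[Rcpp::export(name = ".cpp_glcm")]]
NumericVector cpp_glcm(IntegerVector levels, IntegerVector dim, int nbins) {
  // symmetric co-occurrence counts at distance 1, per direction:
  // array nbins x nbins x 13
  int nx = dim[0], ny = dim[1], nz = dim[2];
  const int* lev = levels.begin();
  NumericVector out((size_t)nbins * nbins * 13, 0.0);
  out.attr("dim") = IntegerVector::create(nbins, nbins, 13);
  std::vector<int> vi, vj, vk;
  roi_voxels(lev, nx, ny, nz, vi, vj, vk);
  for (int d = 0; d < 13; ++d) {
    int dx = DIRS13[d][0], dy = DIRS13[d][1], dz = DIRS13[d][2];
    double* M = out.begin() + (size_t)d * nbins * nbins;
    for (size_t t = 0; t < vi.size(); ++t) {
      int i = vi[t], j = vj[t], k = vk[t];
      int a = lev[idx3(i, j, k, nx, ny)];
      int ii = i + dx, jj = j + dy, kk = k + dz;
      if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
        continue;
      int b = lev[idx3(ii, jj, kk, nx, ny)];
      if (b == 0) continue;
      M[(a - 1) + nbins * (b - 1)] += 1.0;
      M[(b - 1) + nbins * (a - 1)] += 1.0;
    }
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_glrlm")]]
NumericVector cpp_glrlm(IntegerVector levels, IntegerVector dim, int nbins) {
  // run-length counts per direction: array nbins x maxrun x 13
  int nx = dim[0], ny = dim[1], nz = dim[2];
  const int* lev = levels.begin();
  int maxrun = std::max(nx, std::max(ny, nz));
  NumericVector out((size_t)nbins * maxrun * 13, 0.0);
  out.attr("dim") = IntegerVector::create(nbins, maxrun, 13);
  std::vector<int> vi, vj, vk;
  roi_voxels(lev, nx, ny, nz, vi, vj, vk);
  for (int d = 0; d < 13; ++d) {
    int dx = DIRS13[d][0], dy = DIRS13[d][1], dz = DIRS13[d][2];
    double* M = out.begin() + (size_t)d * nbins * maxrun;
    for (size_t t = 0; t < vi.size(); ++t) {
      // start of a maximal run: previous voxel along -d is outside the
      // grid, outside the ROI, or a different gray level
      int i = vi[t], j = vj[t], k = vk[t];
      int a = lev[idx3(i, j, k, nx, ny)];
      int pi = i - dx, pj = j - dy, pk = k - dz;
      if (pi >= 0 && pi < nx && pj >= 0 && pj < ny && pk >= 0 && pk < nz &&
          lev[idx3(pi, pj, pk, nx, ny)] == a)
        continue;
      int len = 1;
      int ci = i + dx, cj = j + dy, ck = k + dz;
      while (ci >= 0 && ci < nx && cj >= 0 && cj < ny && ck >= 0 &&
             ck < nz && lev[idx3(ci, cj, ck, nx, ny)] == a) {
        ++len;
        ci += dx; cj += dy; ck += dz;
      }
      M[(a - 1) + nbins * (len - 1)] += 1.0;
    }
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_glszm")]]
IntegerMatrix cpp_glszm(IntegerVector levels, IntegerVector dim, int nbins) {
  // zones: 26-connected components of equal gray level; returns (level, size)
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  std::vector<char> seen(n, 0);
  std::vector<int> zl, zs, stack;
  for (size_t s = 0; s < n; ++s) {
    int a = levels[s];
    if (a == 0 || seen[s]) continue;
    int size = 0;
    stack.clear();
    stack.push_back((int)s);
    seen[s] = 1;
    while (!stack.empty()) {
      int p = stack.back();
      stack.pop_back();
      ++size;
      int k = p / (nx * ny), rem = p % (nx * ny);
      int j = rem / nx, i = rem % nx;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int ii = i + dx, jj = j + dy, kk = k + dz;
            if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
              continue;
            int q = idx3(ii, jj, kk, nx, ny);
            if (!seen[q] && levels[q] == a) {
              seen[q] = 1;
              stack.push_back(q);
            }
          }
    }
    zl.push_back(a);
    zs.push_back(size);
  }
  IntegerMatrix out((int)zl.size(), 2);
  for (int r = 0; r < (int)zl.size(); ++r) {
    out(r, 0) = zl[r];
    out(r, 1) = zs[r];
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_ngtdm")]]
NumericMatrix cpp_ngtdm(IntegerVector levels, IntegerVector dim, int nbins) {
  // per gray level: n_i (count of ROI voxels with >=1 valid neighbour) and
  // s_i (sum of |level - mean 26-neighbourhood level|)
  int nx = dim[0], ny = dim[1], nz = dim[2];
  const int* lev = levels.begin();
  NumericMatrix out(nbins, 2);
  std::vector<int> vi, vj, vk;
  roi_voxels(lev, nx, ny, nz, vi, vj, vk);
  for (size_t t = 0; t < vi.size(); ++t) {
    int i = vi[t], j = vj[t], k = vk[t];
    int a = lev[idx3(i, j, k, nx, ny)];
    double sum = 0.0;
    int cnt = 0;
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dx && !dy && !dz) continue;
          int ii = i + dx, jj = j + dy, kk = k + dz;
          if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 ||
              kk >= nz)
            continue;
          int b = lev[idx3(ii, jj, kk, nx, ny)];
          if (b == 0) continue;
          sum += b;
          ++cnt;
        }
    if (cnt > 0) {
      out(a - 1, 0) += 1.0;
      out(a - 1, 1) += std::fabs((double)a - sum / cnt);
    }
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_gldm")]]
NumericVector cpp_gldm(IntegerVector levels, IntegerVector dim, int nbins,
                       int alpha) {
  // dependence matrix: D[level, d + 1] with d = number of 26-neighbours in
  // the ROI whose |level difference| <= alpha; columns 1..27 (d = 0..26)
  int nx = dim[0], ny = dim[1], nz = dim[2];
  const int* lev = levels.begin();
  NumericVector out((size_t)nbins * 27, 0.0);
  out.attr("dim") = IntegerVector::create(nbins, 27);
  std::vector<int> vi, vj, vk;
  roi_voxels(lev, nx, ny, nz, vi, vj, vk);
  for (size_t t = 0; t < vi.size(); ++t) {
    int i = vi[t], j = vj[t], k = vk[t];
    int a = lev[idx3(i, j, k, nx, ny)];
    int dcount = 0;
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dx && !dy && !dz) continue;
          int ii = i + dx, jj = j + dy, kk = k + dz;
          if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 ||
              kk >= nz)
            continue;
          int b = lev[idx3(ii, jj, kk, nx, ny)];
          if (b == 0) continue;
          if (std::abs(a - b) <= alpha) ++dcount;
        }
    out[(a - 1) + (size_t)nbins * dcount] += 1.0;
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_moments")]]
NumericVector cpp_moments(NumericVector x) {
  // one pass: n, mean, central moments 2-4, min, max, sum of squares,
  // then a second pass for mean absolute deviation
  size_t n = x.size();
  double s = 0, mn = x[0], mx = x[0], ss = 0;
  for (size_t t = 0; t < n; ++t) {
    double v = x[t];
    s += v; ss += v * v;
    if (v < mn) mn = v;
    if (v > mx) mx = v;
  }
  double m = s / n;
  double m2 = 0, m3 = 0, m4 = 0, mad = 0;
  for (size_t t = 0; t < n; ++t) {
    double d = x[t] - m, d2 = d * d;
    m2 += d2; m3 += d2 * d; m4 += d2 * d2;
    mad += std::fabs(d);
  }
  return NumericVector::create(
    _["n"] = (double)n, _["mean"] = m, _["m2"] = m2 / n, _["m3"] = m3 / n,
    _["m4"] = m4 / n, _["min"] = mn, _["max"] = mx, _["energy"] = ss,
    _["mad"] = mad / n);
}

// [[Rcpp::export(name = ".cpp_texture_neighbors")]]
List cpp_texture_neighbors(IntegerVector levels, IntegerVector dim,
                           int nbins, int alpha) {
  // one shared 26-neighbourhood pass producing the GLCM co-occurrence
  // counts (per 13 directions), the NGTDM (n_i, s_i) table, the GLDM
  // dependence matrix, the GLRLM run counts and the GLSZM zone table;
  // equivalent to the standalone builders
  int nx = dim[0], ny = dim[1], nz = dim[2];
  const int* lev0 = levels.begin();
  // gray levels fit in a byte: a compact copy keeps the scattered
  // neighbour loads inside the cache
  std::vector<unsigned char> levb((size_t)nx * ny * nz);
  for (size_t t = 0; t < levb.size(); ++t)
    levb[t] = (unsigned char)lev0[t];
  const unsigned char* lev = levb.data();
  NumericVector glcm((size_t)nbins * nbins * 13, 0.0);
  glcm.attr("dim") = IntegerVector::create(nbins, nbins, 13);
  NumericMatrix ngtdm(nbins, 2);
  NumericVector gldm((size_t)nbins * 27, 0.0);
  gldm.attr("dim") = IntegerVector::create(nbins, 27);
  int maxrun = std::max(nx, std::max(ny, nz));
  NumericVector glrlm((size_t)nbins * maxrun * 13, 0.0);
  glrlm.attr("dim") = IntegerVector::create(nbins, maxrun, 13);

  std::vector<int> vi, vj, vk;
  roi_voxels(lev, nx, ny, nz, vi, vj, vk);
  size_t nvox = vi.size();
  // 26 linear offsets: canonical 13 then their negatives
  int offs[26], stepdir[13];
  for (int d = 0; d < 13; ++d) {
    stepdir[d] = DIRS13[d][0] + nx * (DIRS13[d][1] + ny * DIRS13[d][2]);
    offs[d] = stepdir[d];
    offs[d + 13] = -stepdir[d];
  }
  double* G = glcm.begin();
  double* D = gldm.begin();
  double* R = glrlm.begin();
  size_t nb2 = (size_t)nbins * nbins;

  for (size_t t = 0; t < nvox; ++t) {
    int i = vi[t], j = vj[t], k = vk[t];
    int p = idx3(i, j, k, nx, ny);
    int a = lev[p];
    bool interior = i > 0 && i < nx - 1 && j > 0 && j < ny - 1 &&
                    k > 0 && k < nz - 1;
    double nsum = 0.0;
    int ncnt = 0, dcount = 0;
    for (int d = 0; d < 26; ++d) {
      int b;
      if (interior) {
        b = lev[p + offs[d]];
      } else {
        int s = d < 13 ? 1 : -1;
        int dd = d < 13 ? d : d - 13;
        int ii = i + s * DIRS13[dd][0], jj = j + s * DIRS13[dd][1],
            kk = k + s * DIRS13[dd][2];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
          continue;
        b = lev[idx3(ii, jj, kk, nx, ny)];
      }
      if (b == 0) continue;
      nsum += b;
      ++ncnt;
      dcount += std::abs(a - b) <= alpha;
      if (d < 13) {
        double* M = G + (size_t)d * nb2;
        M[(a - 1) + nbins * (b - 1)] += 1.0;
        M[(b - 1) + nbins * (a - 1)] += 1.0;
      }
    }
    if (ncnt > 0) {
      ngtdm(a - 1, 0) += 1.0;
      ngtdm(a - 1, 1) += std::fabs((double)a - nsum / ncnt);
    }
    D[(a - 1) + (size_t)nbins * dcount] += 1.0;

    // GLRLM: treat this voxel as a run start per direction when the
    // previous voxel along -d is not the same level
    for (int d = 0; d < 13; ++d) {
      int dx = DIRS13[d][0], dy = DIRS13[d][1], dz = DIRS13[d][2];
      if (interior) {
        if (lev[p - stepdir[d]] == a) continue;
      } else {
        int pi = i - dx, pj = j - dy, pk = k - dz;
        if (pi >= 0 && pi < nx && pj >= 0 && pj < ny && pk >= 0 &&
            pk < nz && lev[p - stepdir[d]] == a)
          continue;
      }
      int len = 1;
      int ci = i + dx, cj = j + dy, ck = k + dz, cp = p + stepdir[d];
      while (ci >= 0 && ci < nx && cj >= 0 && cj < ny && ck >= 0 &&
             ck < nz && lev[cp] == a) {
        ++len;
        ci += dx; cj += dy; ck += dz; cp += stepdir[d];
      }
      double* M = R + (size_t)d * nbins * maxrun;
      M[(a - 1) + nbins * (len - 1)] += 1.0;
    }
  }

  // GLSZM zones by DFS over equal-level 26-neighbours
  std::vector<char> seen((size_t)nx * ny * nz, 0);
  std::vector<int> zl, zs, stack;
  for (size_t t = 0; t < nvox; ++t) {
    int p0 = idx3(vi[t], vj[t], vk[t], nx, ny);
    if (seen[p0]) continue;
    int a = lev[p0];
    int size = 0;
    stack.clear();
    stack.push_back(p0);
    seen[p0] = 1;
    while (!stack.empty()) {
      int p = stack.back();
      stack.pop_back();
      ++size;
      int k = p / (nx * ny), rem = p % (nx * ny);
      int j = rem / nx, i = rem % nx;
      bool interior = i > 0 && i < nx - 1 && j > 0 && j < ny - 1 &&
                      k > 0 && k < nz - 1;
      for (int d = 0; d < 26; ++d) {
        int q;
        if (interior) {
          q = p + offs[d];
        } else {
          int s = d < 13 ? 1 : -1;
          int dd = d < 13 ? d : d - 13;
          int ii = i + s * DIRS13[dd][0], jj = j + s * DIRS13[dd][1],
              kk = k + s * DIRS13[dd][2];
          if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 ||
              kk >= nz)
            continue;
          q = idx3(ii, jj, kk, nx, ny);
        }
        if (!seen[q] && lev[q] == a) {
          seen[q] = 1;
          stack.push_back(q);
        }
      }
    }
    zl.push_back(a);
    zs.push_back(size);
  }
  IntegerMatrix zones((int)zl.size(), 2);
  for (int r = 0; r < (int)zl.size(); ++r) {
    zones(r, 0) = zl[r];
    zones(r, 1) = zs[r];
  }
  return List::create(_["glcm"] = glcm, _["ngtdm"] = ngtdm,
                      _["gldm"] = gldm, _["glrlm"] = glrlm,
                      _["glszm"] = zones);
}

// ---------------------------------------------------------------------------
// iso-surface by marching tetrahedra: surface area + enclosed volume
// ---------------------------------------------------------------------------

struct V3 { double x, y, z; };

static inline V3 vlerp(const V3& a, const V3& b, double va, double vb,
                       double iso) {
  double t = (iso - va) / (vb - va);
  if (t < 0) t = 0;
  if (t > 1) t = 1;
  return {a.x + t * (b.x - a.x), a.y + t * (b.y - a.y), a.z + t * (b.z - a.z)};
}

static void emit_tri(const V3& p1, const V3& p2, const V3& p3,
                     const V3& inside, double& area, double& vol6) {
  // orient the triangle so its normal points away from `inside`
  V3 u = {p2.x - p1.x, p2.y - p1.y, p2.z - p1.z};
  V3 w = {p3.x - p1.x, p3.y - p1.y, p3.z - p1.z};
  V3 nrm = {u.y * w.z - u.z * w.y, u.z * w.x - u.x * w.z,
            u.x * w.y - u.y * w.x};
  V3 c = {(p1.x + p2.x + p3.x) / 3 - inside.x,
          (p1.y + p2.y + p3.y) / 3 - inside.y,
          (p1.z + p2.z + p3.z) / 3 - inside.z};
  const V3* a = &p2;
  const V3* b = &p3;
  if (nrm.x * c.x + nrm.y * c.y + nrm.z * c.z < 0) { a = &p3; b = &p2; }
  V3 uu = {a->x - p1.x, a->y - p1.y, a->z - p1.z};
  V3 ww = {b->x - p1.x, b->y - p1.y, b->z - p1.z};
  V3 n2 = {uu.y * ww.z - uu.z * ww.y, uu.z * ww.x - uu.x * ww.z,
           uu.x * ww.y - uu.y * ww.x};
  area += 0.5 * std::sqrt(n2.x * n2.x + n2.y * n2.y + n2.z * n2.z);
  // signed volume of tetra (origin, p1, a, b); outward normals sum to +V*6
  vol6 += p1.x * (a->y * b->z - a->z * b->y) -
          p1.y * (a->x * b->z - a->z * b->x) +
          p1.z * (a->x * b->y - a->y * b->x);
}

static void march_tet(const V3 p[4], const double v[4], double iso,
                      double& area, double& vol6) {
  int code = 0;
  for (int i = 0; i < 4; ++i)
    if (v[i] >= iso) code |= (1 << i);
  if (code == 0 || code == 15) return;
  // centroid of the "inside" vertices as the orientation anchor
  V3 ins = {0, 0, 0};
  int ni = 0;
  for (int i = 0; i < 4; ++i)
    if (v[i] >= iso) { ins.x += p[i].x; ins.y += p[i].y; ins.z += p[i].z; ++ni; }
  ins.x /= ni; ins.y /= ni; ins.z /= ni;
  int in[4], out[4], a = 0, b = 0;
  for (int i = 0; i < 4; ++i) {
    if (v[i] >= iso) in[a++] = i; else out[b++] = i;
  }
  if (a == 1) {
    V3 q1 = vlerp(p[in[0]], p[out[0]], v[in[0]], v[out[0]], iso);
    V3 q2 = vlerp(p[in[0]], p[out[1]], v[in[0]], v[out[1]], iso);
    V3 q3 = vlerp(p[in[0]], p[out[2]], v[in[0]], v[out[2]], iso);
    emit_tri(q1, q2, q3, ins, area, vol6);
  } else if (a == 3) {
    V3 q1 = vlerp(p[out[0]], p[in[0]], v[out[0]], v[in[0]], iso);
    V3 q2 = vlerp(p[out[0]], p[in[1]], v[out[0]], v[in[1]], iso);
    V3 q3 = vlerp(p[out[0]], p[in[2]], v[out[0]], v[in[2]], iso);
    emit_tri(q1, q2, q3, ins, area, vol6);
  } else {  // a == 2: quad split into two triangles
    V3 q11 = vlerp(p[in[0]], p[out[0]], v[in[0]], v[out[0]], iso);
    V3 q12 = vlerp(p[in[0]], p[out[1]], v[in[0]], v[out[1]], iso);
    V3 q21 = vlerp(p[in[1]], p[out[0]], v[in[1]], v[out[0]], iso);
    V3 q22 = vlerp(p[in[1]], p[out[1]], v[in[1]], v[out[1]], iso);
    emit_tri(q11, q12, q21, ins, area, vol6);
    emit_tri(q21, q12, q22, ins, area, vol6);
  }
}

// [[Rcpp::export(name = ".cpp_mesh_area_volume")]]
List cpp_mesh_area_volume(NumericVector field, IntegerVector dim,
                          NumericVector spacing, double iso) {
  // marching tetrahedra over the cell lattice; vertices at voxel centres
  // i * spacing; field values outside the grid are treated as 0 by padding
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int px = nx + 2, py = ny + 2, pz = nz + 2;
  std::vector<double> f((size_t)px * py * pz, 0.0);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i)
        f[idx3(i + 1, j + 1, k + 1, px, py)] =
          field[idx3(i, j, k, nx, ny)];
  // 6-tetra decomposition of each cube (shared main diagonal 0-7)
  static const int TETS[6][4] = {
    {0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7},
    {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}
  };
  static const int CORN[8][3] = {
    {0, 0, 0}, {1, 0, 0}, {0, 1, 0}, {1, 1, 0},
    {0, 0, 1}, {1, 0, 1}, {0, 1, 1}, {1, 1, 1}
  };
  double area = 0.0, vol6 = 0.0;
  for (int k = 0; k < pz - 1; ++k)
    for (int j = 0; j < py - 1; ++j)
      for (int i = 0; i < px - 1; ++i) {
        double cv[8];
        bool any = false, all = true;
        for (int c = 0; c < 8; ++c) {
          cv[c] = f[idx3(i + CORN[c][0], j + CORN[c][1], k + CORN[c][2],
                         px, py)];
          if (cv[c] >= iso) any = true; else all = false;
        }
        if (!any || all) continue;
        for (int t = 0; t < 6; ++t) {
          V3 p[4];
          double v[4];
          for (int c = 0; c < 4; ++c) {
            int corner = TETS[t][c];
            p[c] = {(i + CORN[corner][0] - 1) * spacing[0],
                    (j + CORN[corner][1] - 1) * spacing[1],
                    (k + CORN[corner][2] - 1) * spacing[2]};
            v[c] = cv[corner];
          }
          march_tet(p, v, iso, area, vol6);
        }
      }
  return List::create(_["area"] = area, _["volume"] = std::fabs(vol6) / 6.0);
}

// ---------------------------------------------------------------------------
// marching squares on a 2D field: perimeter + enclosed area
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_contour_perimeter_area")]]
List cpp_contour_perimeter_area(NumericVector field, IntegerVector dim,
                                NumericVector spacing, double iso) {
  int nx = dim[0], ny = dim[1];
  int px = nx + 2, py = ny + 2;
  std::vector<double> f((size_t)px * py, 0.0);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i)
      f[(i + 1) + px * (j + 1)] = field[i + nx * j];
  double per = 0.0, area2 = 0.0;
  auto interp = [&](double xa, double ya, double va, double xb, double yb,
                    double vb, double& x, double& y) {
    double t = (iso - va) / (vb - va);
    if (t < 0) t = 0;
    if (t > 1) t = 1;
    x = xa + t * (xb - xa);
    y = ya + t * (yb - ya);
  };
  for (int j = 0; j < py - 1; ++j)
    for (int i = 0; i < px - 1; ++i) {
      double v00 = f[i + px * j], v10 = f[(i + 1) + px * j];
      double v01 = f[i + px * (j + 1)], v11 = f[(i + 1) + px * (j + 1)];
      int code = (v00 >= iso) | ((v10 >= iso) << 1) | ((v01 >= iso) << 2) |
                 ((v11 >= iso) << 3);
      if (code == 0 || code == 15) continue;
      double x0 = (i - 1) * spacing[0], y0 = (j - 1) * spacing[1];
      double x1 = x0 + spacing[0], y1 = y0 + spacing[1];
      // candidate edge crossings
      double ex[4], ey[4];
      bool has[4] = {false, false, false, false};
      if ((v00 >= iso) != (v10 >= iso)) {  // bottom
        interp(x0, y0, v00, x1, y0, v10, ex[0], ey[0]); has[0] = true;
      }
      if ((v10 >= iso) != (v11 >= iso)) {  // right
        interp(x1, y0, v10, x1, y1, v11, ex[1], ey[1]); has[1] = true;
      }
      if ((v01 >= iso) != (v11 >= iso)) {  // top
        interp(x0, y1, v01, x1, y1, v11, ex[2], ey[2]); has[2] = true;
      }
      if ((v00 >= iso) != (v01 >= iso)) {  // left
        interp(x0, y0, v00, x0, y1, v01, ex[3], ey[3]); has[3] = true;
      }
      std::vector<std::pair<int,int> > segs;
      int nc = has[0] + has[1] + has[2] + has[3];
      if (nc == 2) {
        int e[2], c = 0;
        for (int t = 0; t < 4; ++t) if (has[t]) e[c++] = t;
        segs.push_back({e[0], e[1]});
      } else {  // saddle: pair by the centre value
        double vc = 0.25 * (v00 + v10 + v01 + v11);
        // corners v00 & v11 inside (code 9) or v10 & v01 inside (code 6)
        if ((vc >= iso) == (v00 >= iso)) {
          segs.push_back({0, 1});
          segs.push_back({2, 3});
        } else {
          segs.push_back({0, 3});
          segs.push_back({1, 2});
        }
      }
      for (auto& sg : segs) {
        double ax = ex[sg.first], ay = ey[sg.first];
        double bx = ex[sg.second], by = ey[sg.second];
        double dx = bx - ax, dy = by - ay;
        per += std::sqrt(dx * dx + dy * dy);
        // orient so the inside lies to the left of a->b, then accumulate
        // the shoelace term
        double mx = 0.5 * (ax + bx), my = 0.5 * (ay + by);
        // left normal of a->b is (-dy, dx)
        double lx = mx - 0.1 * dy, ly = my + 0.1 * dx;
        double rx = mx + 0.1 * dy, ry = my - 0.1 * dx;
        auto bilin = [&](double X, double Y) {
          double u = (X - x0) / spacing[0], w = (Y - y0) / spacing[1];
          if (u < 0) u = 0; if (u > 1) u = 1;
          if (w < 0) w = 0; if (w > 1) w = 1;
          return v00 * (1 - u) * (1 - w) + v10 * u * (1 - w) +
                 v01 * (1 - u) * w + v11 * u * w;
        };
        if (bilin(lx, ly) < bilin(rx, ry)) {
          std::swap(ax, bx);
          std::swap(ay, by);
        }
        area2 += ax * by - bx * ay;
      }
    }
  return List::create(_["perimeter"] = per,
                      _["area"] = std::fabs(area2) / 2.0);
}

// ---------------------------------------------------------------------------
// trilinear / nearest-neighbour resampling onto an isotropic grid
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_resample")]]
NumericVector cpp_resample(NumericVector vol, IntegerVector dim,
                           NumericVector in_spacing,
                           NumericVector out_spacing,
                           IntegerVector out_dim, bool nearest) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int ox = out_dim[0], oy = out_dim[1], oz = out_dim[2];
  NumericVector out((size_t)ox * oy * oz);
  out.attr("dim") = out_dim;
  for (int k = 0; k < oz; ++k)
    for (int j = 0; j < oy; ++j)
      for (int i = 0; i < ox; ++i) {
        double tx = i * out_spacing[0] / in_spacing[0];
        double ty = j * out_spacing[1] / in_spacing[1];
        double tz = k * out_spacing[2] / in_spacing[2];
        if (tx > nx - 1) tx = nx - 1;
        if (ty > ny - 1) ty = ny - 1;
        if (tz > nz - 1) tz = nz - 1;
        double val;
        if (nearest) {
          int ii = (int)std::floor(tx + 0.5);
          int jj = (int)std::floor(ty + 0.5);
          int kk = (int)std::floor(tz + 0.5);
          val = vol[idx3(ii, jj, kk, nx, ny)];
        } else {
          int i0 = (int)std::floor(tx), j0 = (int)std::floor(ty),
              k0 = (int)std::floor(tz);
          int i1 = std::min(i0 + 1, nx - 1), j1 = std::min(j0 + 1, ny - 1),
              k1 = std::min(k0 + 1, nz - 1);
          double fx = tx - i0, fy = ty - j0, fz = tz - k0;
          double c00 = vol[idx3(i0, j0, k0, nx, ny)] * (1 - fx) +
                       vol[idx3(i1, j0, k0, nx, ny)] * fx;
          double c10 = vol[idx3(i0, j1, k0, nx, ny)] * (1 - fx) +
                       vol[idx3(i1, j1, k0, nx, ny)] * fx;
          double c01 = vol[idx3(i0, j0, k1, nx, ny)] * (1 - fx) +
                       vol[idx3(i1, j0, k1, nx, ny)] * fx;
          double c11 = vol[idx3(i0, j1, k1, nx, ny)] * (1 - fx) +
                       vol[idx3(i1, j1, k1, nx, ny)] * fx;
          double c0 = c00 * (1 - fy) + c10 * fy;
          double c1 = c01 * (1 - fy) + c11 * fy;
          val = c0 * (1 - fz) + c1 * fz;
        }
        out[idx3(i, j, k, ox, oy)] = val;
      }
  return out;
}
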