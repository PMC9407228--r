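// Low-level 3D image primitives: separable Gaussian smoothing, discrete
// Laplacian, scale-space local maxima, and trilinear sampling.  All grids are
// R arrays in column-major (x fastest) order; boundaries use reflect-101
// mirroring unless noted.

#include <Rcpp.h>
#include <cmath>
#include <random>
#include <vector>

using namespace Rcpp;

static inline int reflect_idx(int i, int n) {
  // reflect-101: ... 2 1 | 0 1 2 ... n-1 | n-2 n-3 ...
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i;
    if (i >= n) i = 2 * n - 2 - i;
  }
  return i;
}

static std::vector<double> gauss_kernel(double sigma) {
  int r = (int)std::ceil(3.5 * sigma);
  if (r < 1) r = 1;
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (double& v : k) v /= s;
  return k;
}

// Smooth along one axis (0,1,2) with kernel k.
static void smooth_axis(const double* in, double* out, int nx, int ny, int nz,
                        int axis, const std::vector<double>& k) {
  int r = ((int)k.size() - 1) / 2;
  int n[3] = {nx, ny, nz};
  int len = n[axis];
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int idx[3] = {x, y, z};
        double acc = 0.0;
        for (int t = -r; t <= r; ++t) {
          int j[3] = {x, y, z};
          j[axis] = reflect_idx(idx[axis] + t, len);
          acc += k[t + r] * in[j[0] + (size_t)nx * (j[1] + (size_t)ny * j[2])];
        }
        out[x + (size_t)nx * (y + (size_t)ny * z)] = acc;
      }
}

// [[Rcpp::export(name = ".gaussian_smooth3d_cpp")]]
NumericVector gaussian_smooth3d_cpp(NumericVector vol, double sigma) {
  IntegerVector dim = vol.attr("dim");
  int nx = dim[0], ny = dim[1], nz = dim[2];
  if (sigma <= 0) return clone(vol);
  std::vector<double> k = gauss_kernel(sigma);
  NumericVector a = clone(vol), b(vol.size());
  smooth_axis(a.begin(), b.begin(), nx, ny, nz, 0, k);
  smooth_axis(b.begin(), a.begin(), nx, ny, nz, 1, k);
  smooth_axis(a.begin(), b.begin(), nx, ny, nz, 2, k);
  b.attr("dim") = dim;
  return b;
}

// 6-neighbour discrete Laplacian, reflect-101 boundary.
// [[Rcpp::export(name = ".laplacian3d_cpp")]]
NumericVector laplacian3d_cpp(NumericVector vol) {
  IntegerVector dim = vol.attr("dim");
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out(vol.size());
  const double* v = vol.begin();
  double* o = out.begin();
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        size_t c = x + (size_t)nx * (y + (size_t)ny * z);
        double acc = -6.0 * v[c];
        acc += v[reflect_idx(x - 1, nx) + (size_t)nx * (y + (size_t)ny * z)];
        acc += v[reflect_idx(x + 1, nx) + (size_t)nx * (y + (size_t)ny * z)];
        acc += v[x + (size_t)nx * (reflect_idx(y - 1, ny) + (size_t)ny * z)];
        acc += v[x + (size_t)nx * (reflect_idx(y + 1, ny) + (size_t)ny * z)];
        acc += v[x + (size_t)nx * (y + (size_t)ny * reflect_idx(z - 1, nz))];
        acc += v[x + (size_t)nx * (y + (size_t)ny * reflect_idx(z + 1, nz))];
        o[c] = acc;
      }
  out.attr("dim") = dim;
  return out;
}

// Local maxima of a scale-space stack: voxel (x,y,z,s) is a maximum when its
// value >= every value in the 3x3x3 spatial neighbourhood at its own scale
// (and, when across_scale is true, at scales s-1 and s+1 as well), is inside
// the mask, and exceeds min_response.  Border voxels are skipped.  Returns a
// matrix (x,y,z,scale,value) with 0-based integer voxel indices and 1-based
// scale index.
// [[Rcpp::export(name = ".scale_space_maxima_cpp")]]
NumericMatrix scale_space_maxima_cpp(List responses, LogicalVector mask,
                                     double min_response,
                                     bool across_scale = false) {
  int ns = responses.size();
  NumericVector first = responses[0];
  IntegerVector dim = first.attr("dim");
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<const double*> r(ns);
  for (int s = 0; s < ns; ++s) {
    NumericVector v = responses[s];
    r[s] = v.begin();
  }
  const int* mk = mask.begin();
  std::vector<double> out;
  for (int s = 0; s < ns; ++s) {
    int s0 = across_scale ? std::max(0, s - 1) : s;
    int s1 = across_scale ? std::min(ns - 1, s + 1) : s;
    for (int z = 1; z < nz - 1; ++z)
      for (int y = 1; y < ny - 1; ++y)
        for (int x = 1; x < nx - 1; ++x) {
          size_t c = x + (size_t)nx * (y + (size_t)ny * z);
          if (!mk[c]) continue;
          double val = r[s][c];
          if (!(val >= min_response)) continue;
          bool ismax = true;
          for (int ss = s0; ss <= s1 && ismax; ++ss)
            for (int dz = -1; dz <= 1 && ismax; ++dz)
              for (int dy = -1; dy <= 1 && ismax; ++dy)
                for (int dx = -1; dx <= 1; ++dx) {
                  if (ss == s && dx == 0 && dy == 0 && dz == 0) continue;
                  size_t q = (x + dx) +
                             (size_t)nx * ((y + dy) + (size_t)ny * (z + dz));
                  if (r[ss][q] > val) { ismax = false; break; }
                }
          if (ismax) {
            out.push_back(x); out.push_back(y); out.push_back(z);
            out.push_back(s + 1); out.push_back(val);
          }
        }
  }
  int nrow = out.size() / 5;
  NumericMatrix res(nrow, 5);
  for (int i = 0; i < nrow; ++i)
    for (int j = 0; j < 5; ++j) res(i, j) = out[5 * i + j];
  colnames(res) = CharacterVector::create("x", "y", "z", "scale", "value");
  return res;
}

// Simard-style elastic deformation in one call: a per-voxel displacement
// field ~ uniform(-1,1)^3 (mt19937 seeded), Gaussian-smoothed with `sigma`,
// scaled by `alpha` voxels, applied by trilinear resampling with mirror
// boundary.  Field draw order: axis-major (all x-displacements, then y,
// then z), voxel index column-major.
// [[Rcpp::export(name = ".elastic_deform_cpp")]]
NumericVector elastic_deform_cpp(NumericVector vol, double alpha,
                                 double sigma, int seed) {
  IntegerVector dim = vol.attr("dim");
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t V = (size_t)nx * ny * nz;
  if (alpha == 0.0) return clone(vol);
  std::mt19937 rng((unsigned)seed);
  std::uniform_real_distribution<double> unif(-1.0, 1.0);
  std::vector<double> k = gauss_kernel(sigma);
  std::vector<std::vector<double>> disp(3, std::vector<double>(V));
  std::vector<double> tmp(V), tmp2(V);
  for (int a = 0; a < 3; ++a) {
    for (size_t i = 0; i < V; ++i) tmp[i] = unif(rng);
    smooth_axis(tmp.data(), tmp2.data(), nx, ny, nz, 0, k);
    smooth_axis(tmp2.data(), tmp.data(), nx, ny, nz, 1, k);
    smooth_axis(tmp.data(), disp[a].data(), nx, ny, nz, 2, k);
  }
  NumericVector out(vol.size());
  const double* v = vol.begin();
  double* o = out.begin();
  size_t idx = 0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x, ++idx) {
        double px = x + alpha * disp[0][idx];
        double py = y + alpha * disp[1][idx];
        double pz = z + alpha * disp[2][idx];
        int x0 = (int)std::floor(px), y0 = (int)std::floor(py),
            z0 = (int)std::floor(pz);
        double fx = px - x0, fy = py - y0, fz = pz - z0;
        double acc = 0.0;
        for (int dz = 0; dz <= 1; ++dz)
          for (int dy = 0; dy <= 1; ++dy)
            for (int dx = 0; dx <= 1; ++dx) {
              double w = (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy) *
                         (dz ? fz : 1 - fz);
              if (w == 0.0) continue;
              int xi = reflect_idx(x0 + dx, nx);
              int yi = reflect_idx(y0 + dy, ny);
              int zi = reflect_idx(z0 + dz, nz);
              acc += w * v[xi + (size_t)nx * (yi + (size_t)ny * zi)];
            }
        o[idx] = acc;
      }
  out.attr("dim") = dim;
  return out;
}

// Trilinear sampling of vol at continuous 0-based voxel coordinates
// (rows of pts), reflect-101 mirror boundary.
// [[Rcpp::export(name = ".trilinear_sample_cpp")]]
NumericVector trilinear_sample_cpp(NumericVector vol, NumericMatrix pts) {
  IntegerVector dim = vol.attr("dim");
  int nx = dim[0], ny = dim[1], nz = dim[2];
  const double* v = vol.begin();
  int n = pts.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double px = pts(i, 0), py = pts(i, 1), pz = pts(i, 2);
    int x0 = (int)std::floor(px), y0 = (int)std::floor(py),
        z0 = (int)std::floor(pz);
    double fx = px - x0, fy = py - y0, fz = pz - z0;
    double acc = 0.0;
    for (int dz = 0; dz <= 1; ++dz)
      for (int dy = 0; dy <= 1; ++dy)
        for (int dx = 0; dx <= 1; ++dx) {
          double w = (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy) *
                     (dz ? fz : 1 - fz);
          if (w == 0.0) continue;
          int xi = reflect_idx(x0 + dx, nx);
          int yi = reflect_idx(y0 + dy, ny);
          int zi = reflect_idx(z0 + dz, nz);
          acc += w * v[xi + (size_t)nx * (yi + (size_t)ny * zi)];
        }
    out[i] = acc;
  }
  return out;
}
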