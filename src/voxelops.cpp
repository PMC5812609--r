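// Low-level 3D voxel operations backing segmentation and meshing.
// Volumes are passed as flat vectors in R array order: x fastest, then y, then z.

#include <Rcpp.h>
#include <array>
#include <cmath>
#include <cstdint>
#include <limits>
#include <queue>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

static inline R_xlen_t idx3(int x, int y, int z, int nx, int ny) {
  return (R_xlen_t)x + (R_xlen_t)nx * ((R_xlen_t)y + (R_xlen_t)ny * (R_xlen_t)z);
}

// ---------------------------------------------------------------------------
// Separable Gaussian smoothing, zero boundary condition (outside counts as 0,
// i.e. air for a binary body mask).
// ---------------------------------------------------------------------------

static std::vector<double> gauss_kernel(double sigma) {
  if (sigma <= 0) return std::vector<double>(1, 1.0);
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

static void convolve_axis(std::vector<double>& vol, int nx, int ny, int nz,
                          int axis, const std::vector<double>& ker) {
  if (ker.size() == 1) return;
  int r = ((int)ker.size() - 1) / 2;
  int n = axis == 0 ? nx : (axis == 1 ? ny : nz);
  std::vector<double> line(n), out(n);
  int n1 = axis == 0 ? ny : nx;
  int n2 = axis == 2 ? ny : nz;
  for (int b = 0; b < n2; ++b) {
    for (int a = 0; a < n1; ++a) {
      for (int i = 0; i < n; ++i) {
        int x = axis == 0 ? i : a;
        int y = axis == 1 ? i : (axis == 0 ? a : a);
        int z = axis == 2 ? i : b;
        if (axis == 1) { x = a; y = i; z = b; }
        if (axis == 2) { x = a; y = b; z = i; }
        line[i] = vol[idx3(x, y, z, nx, ny)];
      }
      for (int i = 0; i < n; ++i) {
        double s = 0.0;
        for (int j = -r; j <= r; ++j) {
          int p = i + j;
          if (p >= 0 && p < n) s += ker[j + r] * line[p];
        }
        out[i] = s;
      }
      for (int i = 0; i < n; ++i) {
        int x = axis == 0 ? i : a, y = a, z = b;
        if (axis == 0) { y = a; z = b; }
        if (axis == 1) { x = a; y = i; z = b; }
        if (axis == 2) { x = a; y = b; z = i; }
        vol[idx3(x, y, z, nx, ny)] = out[i];
      }
    }
  }
}

// [[Rcpp::export(name = ".cpp_gaussian_smooth")]]
NumericVector cpp_gaussian_smooth(NumericVector vol, IntegerVector dims,
                                  NumericVector sigma_vox) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<double> v(vol.begin(), vol.end());
  for (int axis = 0; axis < 3; ++axis)
    convolve_axis(v, nx, ny, nz, axis, gauss_kernel(sigma_vox[axis]));
  NumericVector out(v.begin(), v.end());
  out.attr("dim") = dims;
  return out;
}

// ---------------------------------------------------------------------------
// Exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
// separable, anisotropic spacing in mm. Returns squared distance (mm^2) from
// every voxel to the nearest foreground voxel centre (Inf if none).
// ---------------------------------------------------------------------------

static void edt_1d(const std::vector<double>& f, std::vector<double>& d, int n, double s) {
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<int> sites;
  sites.reserve(n);
  for (int q = 0; q < n; ++q)
    if (f[q] < INF) sites.push_back(q);
  if (sites.empty()) {
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  std::vector<int> v(sites.size());
  std::vector<double> z(sites.size() + 1);
  int k = 0;
  v[0] = sites[0];
  z[0] = -INF; z[1] = INF;
  auto intersect = [&](int p, int q) {
    double sp = p * s, sq = q * s;
    return ((f[q] + sq * sq) - (f[p] + sp * sp)) / (2.0 * sq - 2.0 * sp);
  };
  for (size_t qi = 1; qi < sites.size(); ++qi) {
    int q = sites[qi];
    double x = intersect(v[k], q);
    while (k > 0 && x <= z[k]) { --k; x = intersect(v[k], q); }
    ++k;
    v[k] = q; z[k] = x; z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double sq = (double)q * s;
    while (z[k + 1] < sq) ++k;
    double sv = (double)v[k] * s;
    d[q] = (sq - sv) * (sq - sv) + f[v[k]];
  }
}

// [[Rcpp::export(name = ".cpp_edt_sq")]]
NumericVector cpp_edt_sq(LogicalVector fg, IntegerVector dims, NumericVector spacing) {
  const double INF = std::numeric_limits<double>::infinity();
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> d((size_t)n);
  for (R_xlen_t i = 0; i < n; ++i) d[(size_t)i] = fg[i] ? 0.0 : INF;

  // pass along x
  {
    std::vector<double> f(nx), o(nx);
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y) {
        bool any = false;
        for (int x = 0; x < nx; ++x) { f[x] = d[idx3(x, y, z, nx, ny)]; if (f[x] < INF) any = true; }
        if (!any) continue;
        edt_1d(f, o, nx, spacing[0]);
        for (int x = 0; x < nx; ++x) d[idx3(x, y, z, nx, ny)] = o[x];
      }
  }
  // pass along y
  {
    std::vector<double> f(ny), o(ny);
    for (int z = 0; z < nz; ++z)
      for (int x = 0; x < nx; ++x) {
        bool any = false;
        for (int y = 0; y < ny; ++y) { f[y] = d[idx3(x, y, z, nx, ny)]; if (f[y] < INF) any = true; }
        if (!any) continue;
        edt_1d(f, o, ny, spacing[1]);
        for (int y = 0; y < ny; ++y) d[idx3(x, y, z, nx, ny)] = o[y];
      }
  }
  // pass along z
  {
    std::vector<double> f(nz), o(nz);
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        bool any = false;
        for (int z = 0; z < nz; ++z) { f[z] = d[idx3(x, y, z, nx, ny)]; if (f[z] < INF) any = true; }
        if (!any) continue;
        edt_1d(f, o, nz, spacing[2]);
        for (int z = 0; z < nz; ++z) d[idx3(x, y, z, nx, ny)] = o[z];
      }
  }
  NumericVector out(d.begin(), d.end());
  out.attr("dim") = dims;
  return out;
}

// ---------------------------------------------------------------------------
// Connected-component labelling, 26- or 6-connectivity, BFS.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_label")]]
IntegerVector cpp_label(LogicalVector fg, IntegerVector dims, int connectivity) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<std::array<int, 3>> nbr;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && m != 1) continue;
        nbr.push_back({dx, dy, dz});
      }
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (int z0 = 0; z0 < nz; ++z0)
    for (int y0 = 0; y0 < ny; ++y0)
      for (int x0 = 0; x0 < nx; ++x0) {
        R_xlen_t i0 = idx3(x0, y0, z0, nx, ny);
        if (!fg[i0] || lab[i0]) continue;
        ++next;
        lab[i0] = next;
        stack.clear();
        stack.push_back(i0);
        while (!stack.empty()) {
          R_xlen_t i = stack.back(); stack.pop_back();
          int z = (int)(i / ((R_xlen_t)nx * ny));
          int rem = (int)(i % ((R_xlen_t)nx * ny));
          int y = rem / nx, x = rem % nx;
          for (const auto& d : nbr) {
            int X = x + d[0], Y = y + d[1], Z = z + d[2];
            if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz) continue;
            R_xlen_t j = idx3(X, Y, Z, nx, ny);
            if (fg[j] && !lab[j]) { lab[j] = next; stack.push_back(j); }
          }
        }
      }
  lab.attr("dim") = dims;
  lab.attr("n_components") = next;
  return lab;
}

// ---------------------------------------------------------------------------
// Marching tetrahedra: iso-surface of a scalar field sampled at voxel centres.
// Each cube cell is split into 6 tetrahedra sharing the main diagonal; crossing
// vertices are interpolated on tet edges (all of which join two grid points) and
// de-duplicated so the output is an indexed, watertight triangle mesh.
// ---------------------------------------------------------------------------

struct MeshAcc {
  std::unordered_map<uint64_t, int> edge_vertex;
  std::vector<double> vx, vy, vz;
  std::vector<int> f0, f1, f2;
  const double* field;
  double iso;
  int nx, ny, nz;
  double sx, sy, sz, ox, oy, oz;

  int vertex_on(R_xlen_t a, R_xlen_t b) {
    if (a > b) std::swap(a, b);
    uint64_t key = (uint64_t)a * (uint64_t)((R_xlen_t)nx * ny * nz) + (uint64_t)b;
    auto it = edge_vertex.find(key);
    if (it != edge_vertex.end()) return it->second;
    double fa = field[a], fb = field[b];
    double t = (iso - fa) / (fb - fa);
    if (t < 0) t = 0; if (t > 1) t = 1;
    int za = (int)(a / ((R_xlen_t)nx * ny)), ra = (int)(a % ((R_xlen_t)nx * ny));
    int ya = ra / nx, xa = ra % nx;
    int zb = (int)(b / ((R_xlen_t)nx * ny)), rb = (int)(b % ((R_xlen_t)nx * ny));
    int yb = rb / nx, xb = rb % nx;
    double px = ox + sx * (xa + t * (xb - xa));
    double py = oy + sy * (ya + t * (yb - ya));
    double pz = oz + sz * (za + t * (zb - za));
    int id = (int)vx.size();
    vx.push_back(px); vy.push_back(py); vz.push_back(pz);
    edge_vertex[key] = id;
    return id;
  }

  void tri(int a, int b, int c) { f0.push_back(a); f1.push_back(b); f2.push_back(c); }

  void do_tet(R_xlen_t p[4]) {
    bool in[4];
    int nin = 0;
    for (int i = 0; i < 4; ++i) { in[i] = field[p[i]] >= iso; nin += in[i]; }
    if (nin == 0 || nin == 4) return;
    if (nin == 1 || nin == 3) {
      int apex = -1;
      for (int i = 0; i < 4; ++i) if (in[i] == (nin == 1)) apex = i;
      int o[3], k = 0;
      for (int i = 0; i < 4; ++i) if (i != apex) o[k++] = i;
      tri(vertex_on(p[apex], p[o[0]]), vertex_on(p[apex], p[o[1]]),
          vertex_on(p[apex], p[o[2]]));
    } else {
      int a[2], b[2], ka = 0, kb = 0;
      for (int i = 0; i < 4; ++i) (in[i] ? a[ka++] : b[kb++]) = i;
      int v_ac = vertex_on(p[a[0]], p[b[0]]);
      int v_ad = vertex_on(p[a[0]], p[b[1]]);
      int v_bc = vertex_on(p[a[1]], p[b[0]]);
      int v_bd = vertex_on(p[a[1]], p[b[1]]);
      tri(v_ac, v_ad, v_bd);
      tri(v_ac, v_bd, v_bc);
    }
  }
};

// [[Rcpp::export(name = ".cpp_marching_tets")]]
List cpp_marching_tets(NumericVector field, IntegerVector dims,
                       NumericVector spacing, NumericVector origin, double iso) {
  MeshAcc m;
  m.field = field.begin();
  m.iso = iso;
  m.nx = dims[0]; m.ny = dims[1]; m.nz = dims[2];
  m.sx = spacing[0]; m.sy = spacing[1]; m.sz = spacing[2];
  m.ox = origin[0]; m.oy = origin[1]; m.oz = origin[2];
  int nx = m.nx, ny = m.ny, nz = m.nz;
  // 6-tet decomposition of the unit cube around the 0->6 main diagonal
  static const int tets[6][4] = {
    {0, 1, 2, 6}, {0, 2, 3, 6}, {0, 3, 7, 6},
    {0, 7, 4, 6}, {0, 4, 5, 6}, {0, 5, 1, 6}};
  static const int cdx[8] = {0, 1, 1, 0, 0, 1, 1, 0};
  static const int cdy[8] = {0, 0, 1, 1, 0, 0, 1, 1};
  static const int cdz[8] = {0, 0, 0, 0, 1, 1, 1, 1};
  const double* f = field.begin();
  for (int z = 0; z < nz - 1; ++z)
    for (int y = 0; y < ny - 1; ++y)
      for (int x = 0; x < nx - 1; ++x) {
        R_xlen_t c[8];
        int above = 0;
        for (int i = 0; i < 8; ++i) {
          c[i] = idx3(x + cdx[i], y + cdy[i], z + cdz[i], nx, ny);
          above += f[c[i]] >= iso;
        }
        if (above == 0 || above == 8) continue;
        for (int t = 0; t < 6; ++t) {
          R_xlen_t p[4] = {c[tets[t][0]], c[tets[t][1]], c[tets[t][2]], c[tets[t][3]]};
          m.do_tet(p);
        }
      }
  int nv = (int)m.vx.size(), nf = (int)m.f0.size();
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; ++i) { V(i, 0) = m.vx[i]; V(i, 1) = m.vy[i]; V(i, 2) = m.vz[i]; }
  IntegerMatrix F(nf, 3);
  for (int i = 0; i < nf; ++i) { F(i, 0) = m.f0[i] + 1; F(i, 1) = m.f1[i] + 1; F(i, 2) = m.f2[i] + 1; }
  return List::create(Named("vertices") = V, Named("faces") = F);
}

// ---------------------------------------------------------------------------
// Rigid resampling (rotation about the z axis through the volume centre plus a
// translation in voxel units), trilinear interpolation, constant fill outside.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_resample_rigid")]]
NumericVector cpp_resample_rigid(NumericVector vol, IntegerVector dims,
                                 double theta_deg, NumericVector shift_vox,
                                 double fill) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  double th = theta_deg * M_PI / 180.0;
  double ct = std::cos(th), st = std::sin(th);
  double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0;
  NumericVector out((R_xlen_t)nx * ny * nz);
  const double* v = vol.begin();
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        // inverse transform: undo shift, then undo rotation
        double xs = x - shift_vox[0], ys = y - shift_vox[1], zs = z - shift_vox[2];
        double xr = cx + ct * (xs - cx) + st * (ys - cy);
        double yr = cy - st * (xs - cx) + ct * (ys - cy);
        double val = fill;
        int x0 = (int)std::floor(xr), y0 = (int)std::floor(yr), z0 = (int)std::floor(zs);
        if (x0 >= 0 && x0 < nx - 1 && y0 >= 0 && y0 < ny - 1 && z0 >= 0 && z0 < nz - 1) {
          double fx = xr - x0, fy = yr - y0, fz = zs - z0;
          double acc = 0.0;
          for (int dz = 0; dz <= 1; ++dz)
            for (int dy = 0; dy <= 1; ++dy)
              for (int dx = 0; dx <= 1; ++dx) {
                double w = (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy) * (dz ? fz : 1 - fz);
                acc += w * v[idx3(x0 + dx, y0 + dy, z0 + dz, nx, ny)];
              }
          val = acc;
        }
        out[idx3(x, y, z, nx, ny)] = val;
      }
  out.attr("dim") = dims;
  return out;
}
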