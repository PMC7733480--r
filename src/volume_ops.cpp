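#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <array>
#include <algorithm>
using namespace Rcpp;

// Index helper: column-major (x fastest), 0-based.
static inline R_xlen_t vidx(int x, int y, int z, int nx, int ny) {
  return (R_xlen_t)x + (R_xlen_t)nx * ((R_xlen_t)y + (R_xlen_t)ny * (R_xlen_t)z);
}

// Separable Gaussian blur along one axis with reflect boundary.
static void blur_axis(std::vector<double> &v, int nx, int ny, int nz,
                      double sigma, int axis) {
  if (sigma <= 0) return;
  int radius = (int)std::ceil(3.0 * sigma);
  if (radius < 1) radius = 1;
  std::vector<double> k(2 * radius + 1);
  double s = 0.0;
  for (int i = -radius; i <= radius; ++i) {
    k[i + radius] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + radius];
  }
  for (double &w : k) w /= s;

  int n[3] = {nx, ny, nz};
  int len = n[axis];
  std::vector<double> out(v.size());
  // iterate over all lines along `axis`
  for (int z = 0; z < (axis == 2 ? 1 : nz); ++z) {
    for (int y = 0; y < (axis == 1 ? 1 : ny); ++y) {
      for (int x = 0; x < (axis == 0 ? 1 : nx); ++x) {
        for (int t = 0; t < len; ++t) {
          double acc = 0.0;
          for (int i = -radius; i <= radius; ++i) {
            int ti = t + i;
            // reflect
            while (ti < 0 || ti >= len) {
              if (ti < 0) ti = -ti - 1;
              if (ti >= len) ti = 2 * len - ti - 1;
            }
            int xi = x, yi = y, zi = z;
            if (axis == 0) xi = ti; else if (axis == 1) yi = ti; else zi = ti;
            acc += k[i + radius] * v[vidx(xi, yi, zi, nx, ny)];
          }
          int xo = x, yo = y, zo = z;
          if (axis == 0) xo = t; else if (axis == 1) yo = t; else zo = t;
          out[vidx(xo, yo, zo, nx, ny)] = acc;
        }
      }
    }
  }
  v.swap(out);
}

// [[Rcpp::export]]
NumericVector cpp_gaussian_blur(NumericVector vol, IntegerVector dims,
                                NumericVector sigma) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<double> v(vol.begin(), vol.end());
  blur_axis(v, nx, ny, nz, sigma[0], 0);
  blur_axis(v, nx, ny, nz, sigma[1], 1);
  blur_axis(v, nx, ny, nz, sigma[2], 2);
  NumericVector out(v.begin(), v.end());
  out.attr("dim") = dims;
  return out;
}

// Eigenvalues of a symmetric 3x3 matrix, analytic (Smith's trigonometric
// method). Returns eigenvalues sorted by increasing absolute value.
static void sym3_eigs(double a11, double a22, double a33,
                      double a12, double a13, double a23, double ev[3]) {
  double p1 = a12 * a12 + a13 * a13 + a23 * a23;
  if (p1 < 1e-300) {
    ev[0] = a11; ev[1] = a22; ev[2] = a33;
  } else {
    double q = (a11 + a22 + a33) / 3.0;
    double p2 = (a11 - q) * (a11 - q) + (a22 - q) * (a22 - q) +
                (a33 - q) * (a33 - q) + 2.0 * p1;
    double p = std::sqrt(p2 / 6.0);
    double b11 = (a11 - q) / p, b22 = (a22 - q) / p, b33 = (a33 - q) / p;
    double b12 = a12 / p, b13 = a13 / p, b23 = a23 / p;
    double detB = b11 * (b22 * b33 - b23 * b23) -
                  b12 * (b12 * b33 - b23 * b13) +
                  b13 * (b12 * b23 - b22 * b13);
    double r = detB / 2.0;
    if (r < -1.0) r = -1.0;
    if (r > 1.0) r = 1.0;
    double phi = std::acos(r) / 3.0;
    double e1 = q + 2.0 * p * std::cos(phi);
    double e3 = q + 2.0 * p * std::cos(phi + 2.0 * M_PI / 3.0);
    double e2 = 3.0 * q - e1 - e3;
    ev[0] = e1; ev[1] = e2; ev[2] = e3;
  }
  std::sort(ev, ev + 3, [](double a, double b) {
    return std::fabs(a) < std::fabs(b);
  });
}

// Single-scale Frangi-type vesselness for bright tubular structures.
// sigma in voxel units (isotropic in index space); response is
// scale-normalized (second derivatives multiplied by sigma^2).
// c_value <= 0 requests a per-call "auto" rule (c = max Frobenius norm of
// this scale / 2); the caller normally fixes c across the scale sweep.
// Returns list(response, smax).
// [[Rcpp::export]]
List cpp_vesselness_scale(NumericVector vol, IntegerVector dims,
                          double sigma, double alpha, double beta,
                          double c_value) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> v(vol.begin(), vol.end());
  blur_axis(v, nx, ny, nz, sigma, 0);
  blur_axis(v, nx, ny, nz, sigma, 1);
  blur_axis(v, nx, ny, nz, sigma, 2);

  double s2 = sigma * sigma;
  std::vector<double> l1(n), l2(n), l3(n), S(n);
  double smax = 0.0;
  for (int z = 0; z < nz; ++z) {
    int zm = std::max(z - 1, 0), zp = std::min(z + 1, nz - 1);
    for (int y = 0; y < ny; ++y) {
      int ym = std::max(y - 1, 0), yp = std::min(y + 1, ny - 1);
      for (int x = 0; x < nx; ++x) {
        int xm = std::max(x - 1, 0), xp = std::min(x + 1, nx - 1);
        double c0 = v[vidx(x, y, z, nx, ny)];
        double hxx = v[vidx(xp, y, z, nx, ny)] - 2 * c0 + v[vidx(xm, y, z, nx, ny)];
        double hyy = v[vidx(x, yp, z, nx, ny)] - 2 * c0 + v[vidx(x, ym, z, nx, ny)];
        double hzz = v[vidx(x, y, zp, nx, ny)] - 2 * c0 + v[vidx(x, y, zm, nx, ny)];
        double hxy = (v[vidx(xp, yp, z, nx, ny)] - v[vidx(xm, yp, z, nx, ny)] -
                      v[vidx(xp, ym, z, nx, ny)] + v[vidx(xm, ym, z, nx, ny)]) / 4.0;
        double hxz = (v[vidx(xp, y, zp, nx, ny)] - v[vidx(xm, y, zp, nx, ny)] -
                      v[vidx(xp, y, zm, nx, ny)] + v[vidx(xm, y, zm, nx, ny)]) / 4.0;
        double hyz = (v[vidx(x, yp, zp, nx, ny)] - v[vidx(x, ym, zp, nx, ny)] -
                      v[vidx(x, yp, zm, nx, ny)] + v[vidx(x, ym, zm, nx, ny)]) / 4.0;
        double ev[3];
        sym3_eigs(s2 * hxx, s2 * hyy, s2 * hzz, s2 * hxy, s2 * hxz, s2 * hyz, ev);
        R_xlen_t i = vidx(x, y, z, nx, ny);
        l1[i] = ev[0]; l2[i] = ev[1]; l3[i] = ev[2];
        S[i] = std::sqrt(ev[0] * ev[0] + ev[1] * ev[1] + ev[2] * ev[2]);
        if (S[i] > smax) smax = S[i];
      }
    }
  }
  double c = c_value > 0 ? c_value : smax / 2.0;
  NumericVector out(n);
  if (c <= 0) {  // flat volume
    out.attr("dim") = dims;
    return List::create(Named("response") = out, Named("smax") = smax);
  }
  double a2 = 2.0 * alpha * alpha, b2 = 2.0 * beta * beta, c2 = 2.0 * c * c;
  for (R_xlen_t i = 0; i < n; ++i) {
    // bright-on-dark: the two largest-magnitude eigenvalues must be negative
    if (l2[i] >= 0 || l3[i] >= 0) { out[i] = 0.0; continue; }
    double Ra = std::fabs(l2[i]) / std::fabs(l3[i]);
    double Rb = std::fabs(l1[i]) / std::sqrt(std::fabs(l2[i] * l3[i]));
    out[i] = (1.0 - std::exp(-Ra * Ra / a2)) * std::exp(-Rb * Rb / b2) *
             (1.0 - std::exp(-S[i] * S[i] / c2));
  }
  out.attr("dim") = dims;
  return List::create(Named("response") = out, Named("smax") = smax);
}

// Trilinear / nearest-neighbour resampling between axis-aligned grids.
// Voxel i center sits at origin + i * spacing (world mm).
// [[Rcpp::export]]
NumericVector cpp_resample(NumericVector vol, IntegerVector dims,
                           NumericVector spacing, NumericVector origin,
                           IntegerVector out_dims, NumericVector out_spacing,
                           NumericVector out_origin, bool nearest) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int ox = out_dims[0], oy = out_dims[1], oz = out_dims[2];
  NumericVector out((R_xlen_t)ox * oy * oz);
  for (int z = 0; z < oz; ++z) {
    double wz = out_origin[2] + z * out_spacing[2];
    double fz = (wz - origin[2]) / spacing[2];
    for (int y = 0; y < oy; ++y) {
      double wy = out_origin[1] + y * out_spacing[1];
      double fy = (wy - origin[1]) / spacing[1];
      for (int x = 0; x < ox; ++x) {
        double wx = out_origin[0] + x * out_spacing[0];
        double fx = (wx - origin[0]) / spacing[0];
        double val;
        if (nearest) {
          int ix = (int)std::lround(fx), iy = (int)std::lround(fy),
              iz = (int)std::lround(fz);
          ix = std::min(std::max(ix, 0), nx - 1);
          iy = std::min(std::max(iy, 0), ny - 1);
          iz = std::min(std::max(iz, 0), nz - 1);
          val = vol[vidx(ix, iy, iz, nx, ny)];
        } else {
          double cx = std::min(std::max(fx, 0.0), (double)(nx - 1));
          double cy = std::min(std::max(fy, 0.0), (double)(ny - 1));
          double cz = std::min(std::max(fz, 0.0), (double)(nz - 1));
          int x0 = (int)std::floor(cx), y0 = (int)std::floor(cy),
              z0 = (int)std::floor(cz);
          int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1),
              z1 = std::min(z0 + 1, nz - 1);
          double dx = cx - x0, dy = cy - y0, dz = cz - z0;
          double c000 = vol[vidx(x0, y0, z0, nx, ny)];
          double c100 = vol[vidx(x1, y0, z0, nx, ny)];
          double c010 = vol[vidx(x0, y1, z0, nx, ny)];
          double c110 = vol[vidx(x1, y1, z0, nx, ny)];
          double c001 = vol[vidx(x0, y0, z1, nx, ny)];
          double c101 = vol[vidx(x1, y0, z1, nx, ny)];
          double c011 = vol[vidx(x0, y1, z1, nx, ny)];
          double c111 = vol[vidx(x1, y1, z1, nx, ny)];
          val = c000 * (1 - dx) * (1 - dy) * (1 - dz) +
                c100 * dx * (1 - dy) * (1 - dz) +
                c010 * (1 - dx) * dy * (1 - dz) +
                c110 * dx * dy * (1 - dz) +
                c001 * (1 - dx) * (1 - dy) * dz +
                c101 * dx * (1 - dy) * dz +
                c011 * (1 - dx) * dy * dz +
                c111 * dx * dy * dz;
        }
        out[vidx(x, y, z, ox, oy)] = val;
      }
    }
  }
  out.attr("dim") = out_dims;
  return out;
}

// Connected-component labeling (6- or 26-connectivity), flood fill.
// Labels 1..K in scan order of component discovery.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<std::array<int, 3>> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        offs.push_back({dx, dy, dz});
      }
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t i = vidx(x, y, z, nx, ny);
        if (!mask[i] || lab[i] != 0) continue;
        ++next;
        lab[i] = next;
        stack.clear();
        stack.push_back(i);
        while (!stack.empty()) {
          R_xlen_t cur = stack.back();
          stack.pop_back();
          int cz = (int)(cur / ((R_xlen_t)nx * ny));
          int rem = (int)(cur % ((R_xlen_t)nx * ny));
          int cy = rem / nx, cx = rem % nx;
          for (auto &o : offs) {
            int ax = cx + o[0], ay = cy + o[1], az = cz + o[2];
            if (ax < 0 || ay < 0 || az < 0 || ax >= nx || ay >= ny || az >= nz)
              continue;
            R_xlen_t j = vidx(ax, ay, az, nx, ny);
            if (mask[j] && lab[j] == 0) {
              lab[j] = next;
              stack.push_back(j);
            }
          }
        }
      }
  lab.attr("dim") = dims;
  return lab;
}

// Binary dilation (or erosion via complement) with a Euclidean ball of
// radius r voxels.
// [[Rcpp::export]]
LogicalVector cpp_binary_dilate(LogicalVector mask, IntegerVector dims,
                                double radius) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int r = (int)std::floor(radius);
  std::vector<std::array<int, 3>> offs;
  for (int dz = -r; dz <= r; ++dz)
    for (int dy = -r; dy <= r; ++dy)
      for (int dx = -r; dx <= r; ++dx)
        if (dx * dx + dy * dy + dz * dz <= radius * radius)
          offs.push_back({dx, dy, dz});
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector out(n, FALSE);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        if (!mask[vidx(x, y, z, nx, ny)]) continue;
        for (auto &o : offs) {
          int ax = x + o[0], ay = y + o[1], az = z + o[2];
          if (ax < 0 || ay < 0 || az < 0 || ax >= nx || ay >= ny || az >= nz)
            continue;
          out[vidx(ax, ay, az, nx, ny)] = TRUE;
        }
      }
  out.attr("dim") = dims;
  return out;
}

// Minimum distance (mm) from each voxel center to a polyline given as an
// n x 3 matrix of world coordinates.
// [[Rcpp::export]]
NumericVector cpp_min_dist_polyline(IntegerVector dims, NumericVector spacing,
                                    NumericVector origin, NumericMatrix pts) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int np = pts.nrow();
  NumericVector out((R_xlen_t)nx * ny * nz);
  for (int z = 0; z < nz; ++z) {
    double wz = origin[2] + z * spacing[2];
    for (int y = 0; y < ny; ++y) {
      double wy = origin[1] + y * spacing[1];
      for (int x = 0; x < nx; ++x) {
        double wx = origin[0] + x * spacing[0];
        double best = R_PosInf;
        for (int s = 0; s + 1 < np; ++s) {
          double ax = pts(s, 0), ay = pts(s, 1), az = pts(s, 2);
          double bx = pts(s + 1, 0), by = pts(s + 1, 1), bz = pts(s + 1, 2);
          double ux = bx - ax, uy = by - ay, uz = bz - az;
          double L2 = ux * ux + uy * uy + uz * uz;
          double t = 0.0;
          if (L2 > 0) {
            t = ((wx - ax) * ux + (wy - ay) * uy + (wz - az) * uz) / L2;
            t = std::min(std::max(t, 0.0), 1.0);
          }
          double dx = wx - (ax + t * ux), dy = wy - (ay + t * uy),
                 dz = wz - (az + t * uz);
          double d2 = dx * dx + dy * dy + dz * dz;
          if (d2 < best) best = d2;
        }
        if (np == 1) {
          double dx = wx - pts(0, 0), dy = wy - pts(0, 1), dz = wz - pts(0, 2);
          best = dx * dx + dy * dy + dz * dz;
        }
        out[vidx(x, y, z, nx, ny)] = std::sqrt(best);
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}
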