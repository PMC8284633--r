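#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

// Volumes are dense 3-D arrays with R dim c(Z, Y, X), column-major, so the
// linear index of voxel (z, y, x) (0-based) is z + Z*(y + Y*x).

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

static inline double sample_trilinear(const double* vol, int Z, int Y, int X,
                                      double z, double y, double x) {
  // clamp-to-edge sampling in 0-based voxel coordinates
  if (z < 0) z = 0; if (z > Z - 1) z = Z - 1;
  if (y < 0) y = 0; if (y > Y - 1) y = Y - 1;
  if (x < 0) x = 0; if (x > X - 1) x = X - 1;
  int z0 = (int)std::floor(z), y0 = (int)std::floor(y), x0 = (int)std::floor(x);
  int z1 = clampi(z0 + 1, 0, Z - 1), y1 = clampi(y0 + 1, 0, Y - 1), x1 = clampi(x0 + 1, 0, X - 1);
  double fz = z - z0, fy = y - y0, fx = x - x0;
  const int ZY = Z * Y;
  #define V(zz, yy, xx) vol[(zz) + Z * ((yy) + Y * (xx))]
  double c00 = V(z0, y0, x0) * (1 - fz) + V(z1, y0, x0) * fz;
  double c10 = V(z0, y1, x0) * (1 - fz) + V(z1, y1, x0) * fz;
  double c01 = V(z0, y0, x1) * (1 - fz) + V(z1, y0, x1) * fz;
  double c11 = V(z0, y1, x1) * (1 - fz) + V(z1, y1, x1) * fz;
  #undef V
  (void)ZY;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fx) + c1 * fx;
}

// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector vol, IntegerVector dim,
                            NumericVector z, NumericVector y, NumericVector x) {
  int Z = dim[0], Y = dim[1], X = dim[2];
  if ((R_xlen_t)Z * Y * X != vol.size()) stop("dim does not match volume length");
  R_xlen_t n = z.size();
  if (y.size() != n || x.size() != n) stop("coordinate vectors differ in length");
  NumericVector out(n);
  const double* v = REAL(vol);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = sample_trilinear(v, Z, Y, X, z[i], y[i], x[i]);
  return out;
}

static void blur_line(const double* src, double* dst, int len, long st,
                      const std::vector<double>& k, int r) {
  for (int i = 0; i < len; ++i) {
    int j0 = std::max(-r, -i), j1 = std::min(r, len - 1 - i);
    double acc = 0.0;
    // clamped border: fold the out-of-range taps onto the edge samples
    if (j0 > -r) {
      double w = 0.0;
      for (int j = -r; j < j0; ++j) w += k[j + r];
      acc += w * src[0];
    }
    if (j1 < r) {
      double w = 0.0;
      for (int j = j1 + 1; j <= r; ++j) w += k[j + r];
      acc += w * src[(long)(len - 1) * st];
    }
    for (int j = j0; j <= j1; ++j) acc += k[j + r] * src[(long)(i + j) * st];
    dst[(long)i * st] = acc;
  }
}

static void blur_axis(std::vector<double>& a, std::vector<double>& tmp,
                      int Z, int Y, int X, int axis, const std::vector<double>& k) {
  int r = (int)(k.size() - 1) / 2;
  if (axis == 0) {
    for (long x = 0; x < X; ++x)
      for (long y = 0; y < Y; ++y) {
        long base = Z * (y + (long)Y * x);
        blur_line(a.data() + base, tmp.data() + base, Z, 1, k, r);
      }
  } else if (axis == 1) {
    for (long x = 0; x < X; ++x)
      for (long z = 0; z < Z; ++z) {
        long base = z + (long)Z * Y * x;
        blur_line(a.data() + base, tmp.data() + base, Y, Z, k, r);
      }
  } else {
    for (long y = 0; y < Y; ++y)
      for (long z = 0; z < Z; ++z) {
        long base = z + (long)Z * y;
        blur_line(a.data() + base, tmp.data() + base, X, (long)Z * Y, k, r);
      }
  }
  a.swap(tmp);
}

static std::vector<double> gauss_kernel(double sigma) {
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0;
  for (int j = -r; j <= r; ++j) { k[j + r] = std::exp(-0.5 * j * j / (sigma * sigma)); s += k[j + r]; }
  for (double& v : k) v /= s;
  return k;
}

static void blur3_inplace(std::vector<double>& a, int Z, int Y, int X, double sigma) {
  if (sigma <= 0) return;
  std::vector<double> k = gauss_kernel(sigma);
  std::vector<double> tmp(a.size());
  if (Z > 1) blur_axis(a, tmp, Z, Y, X, 0, k);
  if (Y > 1) blur_axis(a, tmp, Z, Y, X, 1, k);
  if (X > 1) blur_axis(a, tmp, Z, Y, X, 2, k);
}

// [[Rcpp::export]]
NumericVector cpp_gaussian_blur3(NumericVector vol, IntegerVector dim, double sigma) {
  int Z = dim[0], Y = dim[1], X = dim[2];
  if ((R_xlen_t)Z * Y * X != vol.size()) stop("dim does not match volume length");
  std::vector<double> a(vol.begin(), vol.end());
  blur3_inplace(a, Z, Y, X, sigma);
  return NumericVector(a.begin(), a.end());
}

// One pyramid level of classic (Thirion) demons. `field` holds the voxel-unit
// displacement as three stacked blocks (dz, dy, dx) of length Z*Y*X; the
// fixed-image gradient drives the update and the accumulated field is
// Gaussian-regularized after every iteration.
// [[Rcpp::export]]
NumericVector cpp_demons_level(NumericVector fixed, NumericVector moving,
                               IntegerVector dim, NumericVector field,
                               int niter, double sigma, int level,
                               double max_step = 2.0) {
  int Z = dim[0], Y = dim[1], X = dim[2];
  long n = (long)Z * Y * X;
  if ((R_xlen_t)n != fixed.size() || (R_xlen_t)n != moving.size())
    stop("dim does not match image length");
  if (field.size() != (R_xlen_t)(3 * n)) stop("field must have 3*Z*Y*X elements");

  const double* F = REAL(fixed);
  const double* M = REAL(moving);
  std::vector<double> fz(field.begin(), field.begin() + n);
  std::vector<double> fy(field.begin() + n, field.begin() + 2 * n);
  std::vector<double> fx(field.begin() + 2 * n, field.begin() + 3 * n);

  // fixed-image gradient, central differences with one-sided borders
  std::vector<double> gz(n), gy(n), gx(n);
  for (int x = 0; x < X; ++x)
    for (int y = 0; y < Y; ++y)
      for (int z = 0; z < Z; ++z) {
        long i = z + (long)Z * (y + (long)Y * x);
        int zp = clampi(z + 1, 0, Z - 1), zm = clampi(z - 1, 0, Z - 1);
        int yp = clampi(y + 1, 0, Y - 1), ym = clampi(y - 1, 0, Y - 1);
        int xp = clampi(x + 1, 0, X - 1), xm = clampi(x - 1, 0, X - 1);
        gz[i] = (F[zp + (long)Z * (y + (long)Y * x)] - F[zm + (long)Z * (y + (long)Y * x)]) / (double)(zp - zm);
        gy[i] = (F[z + (long)Z * (yp + (long)Y * x)] - F[z + (long)Z * (ym + (long)Y * x)]) / (double)(yp - ym);
        gx[i] = (F[z + (long)Z * (y + (long)Y * xp)] - F[z + (long)Z * (y + (long)Y * xm)]) / (double)(xp - xm);
      }

  for (int it = 0; it < niter; ++it) {
    bool bad = false;
    for (int x = 0; x < X && !bad; ++x)
      for (int y = 0; y < Y; ++y)
        for (int z = 0; z < Z; ++z) {
          long i = z + (long)Z * (y + (long)Y * x);
          double m = sample_trilinear(M, Z, Y, X, z + fz[i], y + fy[i], x + fx[i]);
          double diff = F[i] - m;
          double g2 = gz[i] * gz[i] + gy[i] * gy[i] + gx[i] * gx[i];
          double denom = g2 + diff * diff;
          if (denom > 1e-12) {
            double s = diff / denom;
            double uz = s * gz[i], uy = s * gy[i], ux = s * gx[i];
            double nrm = std::sqrt(uz * uz + uy * uy + ux * ux);
            if (nrm > max_step) { uz *= max_step / nrm; uy *= max_step / nrm; ux *= max_step / nrm; }
            fz[i] += uz; fy[i] += uy; fx[i] += ux;
            if (!std::isfinite(fz[i]) || !std::isfinite(fy[i]) || !std::isfinite(fx[i])) { bad = true; break; }
          }
        }
    if (bad)
      stop("demons update became non-finite at pyramid level %d, iteration %d", level, it + 1);
    blur3_inplace(fz, Z, Y, X, sigma);
    blur3_inplace(fy, Z, Y, X, sigma);
    blur3_inplace(fx, Z, Y, X, sigma);
  }

  NumericVector out(3 * n);
  std::copy(fz.begin(), fz.end(), out.begin());
  std::copy(fy.begin(), fy.end(), out.begin() + n);
  std::copy(fx.begin(), fx.end(), out.begin() + 2 * n);
  return out;
}

// 26-connected local maxima above a threshold; returns 0-based (z, y, x) rows.
// Plateau ties are kept only at the first voxel in scan order.
// [[Rcpp::export]]
IntegerMatrix cpp_local_maxima(NumericVector vol, IntegerVector dim, double threshold) {
  int Z = dim[0], Y = dim[1], X = dim[2];
  if ((R_xlen_t)((long)Z * Y * X) != vol.size()) stop("dim does not match volume length");
  const double* v = REAL(vol);
  std::vector<int> zz, yy, xx;
  for (int x = 0; x < X; ++x)
    for (int y = 0; y < Y; ++y)
      for (int z = 0; z < Z; ++z) {
        long i = z + (long)Z * (y + (long)Y * x);
        double c = v[i];
        if (!(c > threshold)) continue;
        bool ismax = true, tie_before = false;
        for (int dx = -1; dx <= 1 && ismax; ++dx)
          for (int dy = -1; dy <= 1 && ismax; ++dy)
            for (int dz = -1; dz <= 1; ++dz) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              int z2 = z + dz, y2 = y + dy, x2 = x + dx;
              if (z2 < 0 || z2 >= Z || y2 < 0 || y2 >= Y || x2 < 0 || x2 >= X) continue;
              double nb = v[z2 + (long)Z * (y2 + (long)Y * x2)];
              if (nb > c) { ismax = false; break; }
              if (nb == c) {
                long j = z2 + (long)Z * (y2 + (long)Y * x2);
                if (j < i) { tie_before = true; }
              }
            }
        if (ismax && !tie_before) { zz.push_back(z); yy.push_back(y); xx.push_back(x); }
      }
  IntegerMatrix out(zz.size(), 3);
  for (size_t r = 0; r < zz.size(); ++r) { out(r, 0) = zz[r]; out(r, 1) = yy[r]; out(r, 2) = xx[r]; }
  return out;
}

// Minimum-cost assignment on a square cost matrix (Hungarian algorithm,
// shortest-augmenting-path formulation with dual potentials).
// Returns the 1-based column assigned to each row.
// [[Rcpp::export]]
IntegerVector cpp_hungarian(NumericMatrix cost) {
  int n = cost.nrow();
  if (cost.ncol() != n) stop("cost matrix must be square");
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> u(n + 1, 0.0), v(n + 1, 0.0);
  std::vector<int> p(n + 1, 0), way(n + 1, 0);
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(n + 1, INF);
    std::vector<char> used(n + 1, 0);
    do {
      used[j0] = 1;
      int i0 = p[j0], j1 = -1;
      double delta = INF;
      for (int j = 1; j <= n; ++j)
        if (!used[j]) {
          double cur = cost(i0 - 1, j - 1) - u[i0] - v[j];
          if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
          if (minv[j] < delta) { delta = minv[j]; j1 = j; }
        }
      for (int j = 0; j <= n; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do { int j1 = way[j0]; p[j0] = p[j1]; j0 = j1; } while (j0);
  }
  IntegerVector ans(n);
  for (int j = 1; j <= n; ++j) if (p[j] > 0) ans[p[j] - 1] = j;
  return ans;
}
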