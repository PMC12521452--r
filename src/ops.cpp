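#include <Rcpp.h>
#include <cfloat>
#include <cmath>
#include <vector>
#include <queue>
using namespace Rcpp;

// Dense 3-D arrays are passed as numeric vectors in R column-major order
// (x fastest), with an explicit dims vector (nx, ny, nz[, nc]).

// ---- im2col / col2im for 3-D convolution, stride 1, zero padding ----------

// [[Rcpp::export]]
NumericMatrix im2col3(NumericVector x, IntegerVector dims, int k, int pad) {
  int nx = dims[0], ny = dims[1], nz = dims[2], nc = dims[3];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  int kk = k * k * k;
  NumericMatrix out(n, (R_xlen_t)kk * nc);
  const double* xp = REAL(x);
  for (int ci = 0; ci < nc; ++ci) {
    const double* xc = xp + (R_xlen_t)ci * n;
    for (int cz = 0; cz < k; ++cz) for (int cy = 0; cy < k; ++cy) for (int cx = 0; cx < k; ++cx) {
      R_xlen_t col = (R_xlen_t)ci * kk + (R_xlen_t)cz * k * k + cy * k + cx;
      double* o = &out(0, col);
      int dx = cx - pad, dy = cy - pad, dz = cz - pad;
      for (int z = 0; z < nz; ++z) {
        int sz = z + dz;
        bool okz = sz >= 0 && sz < nz;
        for (int y = 0; y < ny; ++y) {
          int sy = y + dy;
          R_xlen_t obase = ((R_xlen_t)z * ny + y) * nx;
          if (!okz || sy < 0 || sy >= ny) {
            for (int xx = 0; xx < nx; ++xx) o[obase + xx] = 0.0;
            continue;
          }
          R_xlen_t sbase = ((R_xlen_t)sz * ny + sy) * nx;
          int x0 = dx < 0 ? -dx : 0;
          int x1 = dx > 0 ? nx - dx : nx;
          for (int xx = 0; xx < x0; ++xx) o[obase + xx] = 0.0;
          for (int xx = x0; xx < x1; ++xx) o[obase + xx] = xc[sbase + xx + dx];
          for (int xx = x1; xx < nx; ++xx) o[obase + xx] = 0.0;
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector col2im3(NumericMatrix cols, IntegerVector dims, int k, int pad) {
  int nx = dims[0], ny = dims[1], nz = dims[2], nc = dims[3];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  int kk = k * k * k;
  NumericVector x(n * nc);
  double* xp = REAL(x);
  for (int ci = 0; ci < nc; ++ci) {
    double* xc = xp + (R_xlen_t)ci * n;
    for (int cz = 0; cz < k; ++cz) for (int cy = 0; cy < k; ++cy) for (int cx = 0; cx < k; ++cx) {
      R_xlen_t col = (R_xlen_t)ci * kk + (R_xlen_t)cz * k * k + cy * k + cx;
      const double* o = &cols(0, col);
      int dx = cx - pad, dy = cy - pad, dz = cz - pad;
      for (int z = 0; z < nz; ++z) {
        int sz = z + dz;
        if (sz < 0 || sz >= nz) continue;
        for (int y = 0; y < ny; ++y) {
          int sy = y + dy;
          if (sy < 0 || sy >= ny) continue;
          R_xlen_t obase = ((R_xlen_t)z * ny + y) * nx;
          R_xlen_t sbase = ((R_xlen_t)sz * ny + sy) * nx;
          int x0 = dx < 0 ? -dx : 0;
          int x1 = dx > 0 ? nx - dx : nx;
          for (int xx = x0; xx < x1; ++xx) xc[sbase + xx + dx] += o[obase + xx];
        }
      }
    }
  }
  return x;
}

// ---- 2x max pooling with argmax indices (for exact backward) --------------

// [[Rcpp::export]]
List maxpool3(NumericVector x, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2], nc = dims[3];
  int ox = nx / 2, oy = ny / 2, oz = nz / 2;
  R_xlen_t n = (R_xlen_t)nx * ny * nz, on = (R_xlen_t)ox * oy * oz;
  NumericVector out(on * nc);
  NumericVector idx(on * nc); // 1-based index into x, stored as double
  const double* xp = REAL(x);
  for (int ci = 0; ci < nc; ++ci) {
    const double* xc = xp + (R_xlen_t)ci * n;
    for (int z = 0; z < oz; ++z) for (int y = 0; y < oy; ++y) for (int xx = 0; xx < ox; ++xx) {
      double best = -DBL_MAX;
      R_xlen_t bi = 0;
      for (int dz = 0; dz < 2; ++dz) for (int dy = 0; dy < 2; ++dy) for (int dx = 0; dx < 2; ++dx) {
        R_xlen_t ii = ((R_xlen_t)(2 * z + dz) * ny + (2 * y + dy)) * nx + (2 * xx + dx);
        if (xc[ii] > best) { best = xc[ii]; bi = ii; }
      }
      R_xlen_t oi = (R_xlen_t)ci * on + ((R_xlen_t)z * oy + y) * ox + xx;
      out[oi] = best;
      idx[oi] = (double)((R_xlen_t)ci * n + bi + 1);
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx,
                      _["dims"] = IntegerVector::create(ox, oy, oz, nc));
}

// [[Rcpp::export]]
NumericVector maxpool3_bwd(NumericVector dout, NumericVector idx, double n_in) {
  NumericVector dx((R_xlen_t)n_in);
  for (R_xlen_t i = 0; i < dout.size(); ++i) dx[(R_xlen_t)idx[i] - 1] += dout[i];
  return dx;
}

// ---- zero-insertion 2x upsampling (fractionally-strided conv support) -----

// [[Rcpp::export]]
NumericVector upsample2_zero(NumericVector x, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2], nc = dims[3];
  int ox = 2 * nx, oy = 2 * ny, oz = 2 * nz;
  R_xlen_t n = (R_xlen_t)nx * ny * nz, on = (R_xlen_t)ox * oy * oz;
  NumericVector out(on * nc);
  const double* xp = REAL(x);
  double* op = REAL(out);
  for (int ci = 0; ci < nc; ++ci)
    for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y) for (int xx = 0; xx < nx; ++xx)
      op[(R_xlen_t)ci * on + ((R_xlen_t)2 * z * oy + 2 * y) * ox + 2 * xx] =
        xp[(R_xlen_t)ci * n + ((R_xlen_t)z * ny + y) * nx + xx];
  return out;
}

// [[Rcpp::export]]
NumericVector downsample2_even(NumericVector x, IntegerVector dims) {
  // adjoint of upsample2_zero: pick even-index voxels
  int ox = dims[0], oy = dims[1], oz = dims[2], nc = dims[3];
  int nx = ox / 2, ny = oy / 2, nz = oz / 2;
  R_xlen_t n = (R_xlen_t)nx * ny * nz, on = (R_xlen_t)ox * oy * oz;
  NumericVector out(n * nc);
  const double* xp = REAL(x);
  double* op = REAL(out);
  for (int ci = 0; ci < nc; ++ci)
    for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y) for (int xx = 0; xx < nx; ++xx)
      op[(R_xlen_t)ci * n + ((R_xlen_t)z * ny + y) * nx + xx] =
        xp[(R_xlen_t)ci * on + ((R_xlen_t)2 * z * oy + 2 * y) * ox + 2 * xx];
  return out;
}

// ---- separable 1-D convolution along one axis, replicate padding ----------

// [[Rcpp::export]]
NumericVector convaxis3(NumericVector x, IntegerVector dims, NumericVector kern, int axis) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int kl = kern.size(), r = kl / 2;
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  const double* xp = REAL(x);
  double* op = REAL(out);
  int len = axis == 0 ? nx : (axis == 1 ? ny : nz);
  R_xlen_t stride = axis == 0 ? 1 : (axis == 1 ? (R_xlen_t)nx : (R_xlen_t)nx * ny);
  for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y) for (int xx = 0; xx < nx; ++xx) {
    int pos = axis == 0 ? xx : (axis == 1 ? y : z);
    R_xlen_t base = ((R_xlen_t)z * ny + y) * nx + xx - (R_xlen_t)pos * stride;
    double acc = 0.0;
    for (int t = 0; t < kl; ++t) {
      int p = pos + t - r;
      if (p < 0) p = 0;
      if (p >= len) p = len - 1;
      acc += kern[t] * xp[base + (R_xlen_t)p * stride];
    }
    op[((R_xlen_t)z * ny + y) * nx + xx] = acc;
  }
  return out;
}

// ---- hysteresis thresholding (2-D, 8-connected BFS from strong seeds) -----

// [[Rcpp::export]]
IntegerMatrix hysteresis2(LogicalMatrix weak, LogicalMatrix strong) {
  int nr = weak.nrow(), nc = weak.ncol();
  IntegerMatrix out(nr, nc);
  std::queue<std::pair<int, int> > q;
  for (int j = 0; j < nc; ++j) for (int i = 0; i < nr; ++i)
    if (strong(i, j) && weak(i, j)) { out(i, j) = 1; q.push(std::make_pair(i, j)); }
  while (!q.empty()) {
    std::pair<int, int> p = q.front(); q.pop();
    for (int dj = -1; dj <= 1; ++dj) for (int di = -1; di <= 1; ++di) {
      int i = p.first + di, j = p.second + dj;
      if (i < 0 || i >= nr || j < 0 || j >= nc) continue;
      if (weak(i, j) && !out(i, j)) { out(i, j) = 1; q.push(std::make_pair(i, j)); }
    }
  }
  return out;
}

// ---- surface extraction + brute-force directed surface distances ----------

static void surface_points(const int* m, int nx, int ny, int nz,
                           const double* sp, std::vector<double>& pts) {
  for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y) for (int x = 0; x < nx; ++x) {
    R_xlen_t i = ((R_xlen_t)z * ny + y) * nx + x;
    if (!m[i]) continue;
    bool surf = false;
    // 6-neighborhood; out-of-bounds counts as background
    if (x == 0 || !m[i - 1]) surf = true;
    else if (x == nx - 1 || !m[i + 1]) surf = true;
    else if (y == 0 || !m[i - nx]) surf = true;
    else if (y == ny - 1 || !m[i + nx]) surf = true;
    else if (z == 0 || !m[i - (R_xlen_t)nx * ny]) surf = true;
    else if (z == nz - 1 || !m[i + (R_xlen_t)nx * ny]) surf = true;
    if (surf) {
      pts.push_back(x * sp[0]);
      pts.push_back(y * sp[1]);
      pts.push_back(z * sp[2]);
    }
  }
}

// [[Rcpp::export]]
List surf_dists(IntegerVector a, IntegerVector b, IntegerVector dims, NumericVector spacing) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<double> pa, pb;
  surface_points(INTEGER(a), nx, ny, nz, REAL(spacing), pa);
  surface_points(INTEGER(b), nx, ny, nz, REAL(spacing), pb);
  size_t na = pa.size() / 3, nb = pb.size() / 3;
  NumericVector dab(na), dba(nb);
  for (size_t i = 0; i < na; ++i) {
    double best = DBL_MAX;
    for (size_t j = 0; j < nb; ++j) {
      double dx = pa[3 * i] - pb[3 * j], dy = pa[3 * i + 1] - pb[3 * j + 1],
             dz = pa[3 * i + 2] - pb[3 * j + 2];
      double d = dx * dx + dy * dy + dz * dz;
      if (d < best) best = d;
    }
    dab[i] = std::sqrt(best);
  }
  for (size_t j = 0; j < nb; ++j) {
    double best = DBL_MAX;
    for (size_t i = 0; i < na; ++i) {
      double dx = pa[3 * i] - pb[3 * j], dy = pa[3 * i + 1] - pb[3 * j + 1],
             dz = pa[3 * i + 2] - pb[3 * j + 2];
      double d = dx * dx + dy * dy + dz * dz;
      if (d < best) best = d;
    }
    dba[j] = std::sqrt(best);
  }
  return List::create(_["dab"] = dab, _["dba"] = dba);
}

// ---- marching tetrahedra iso-surface area ---------------------------------
// Each grid cell is split into 6 tetrahedra sharing the main diagonal; the
// level surface within a tetrahedron is a triangle or a quad with vertices
// linearly interpolated along edges. No case tables required.

static inline double tri_area(const double* p0, const double* p1, const double* p2) {
  double u[3] = { p1[0] - p0[0], p1[1] - p0[1], p1[2] - p0[2] };
  double v[3] = { p2[0] - p0[0], p2[1] - p0[1], p2[2] - p0[2] };
  double cx = u[1] * v[2] - u[2] * v[1];
  double cy = u[2] * v[0] - u[0] * v[2];
  double cz = u[0] * v[1] - u[1] * v[0];
  return 0.5 * std::sqrt(cx * cx + cy * cy + cz * cz);
}

static inline void interp_pt(const double* pa, double fa, const double* pb, double fb,
                             double level, double* out) {
  double t = (level - fa) / (fb - fa);
  out[0] = pa[0] + t * (pb[0] - pa[0]);
  out[1] = pa[1] + t * (pb[1] - pa[1]);
  out[2] = pa[2] + t * (pb[2] - pa[2]);
}

// [[Rcpp::export]]
double mt_area(NumericVector f, IntegerVector dims, NumericVector spacing, double level) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  const double* fp = REAL(f);
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  // cube corner offsets (unit cell)
  static const int co[8][3] = {
    {0, 0, 0}, {1, 0, 0}, {1, 1, 0}, {0, 1, 0},
    {0, 0, 1}, {1, 0, 1}, {1, 1, 1}, {0, 1, 1}
  };
  // 6 tetrahedra sharing diagonal corner0-corner6
  static const int tets[6][4] = {
    {0, 1, 2, 6}, {0, 2, 3, 6}, {0, 3, 7, 6}, {0, 7, 4, 6}, {0, 4, 5, 6}, {0, 5, 1, 6}
  };
  double area = 0.0;
  for (int z = 0; z < nz - 1; ++z) for (int y = 0; y < ny - 1; ++y) for (int x = 0; x < nx - 1; ++x) {
    double fv[8];
    double pv[8][3];
    for (int c = 0; c < 8; ++c) {
      int cx = x + co[c][0], cy = y + co[c][1], cz = z + co[c][2];
      fv[c] = fp[((R_xlen_t)cz * ny + cy) * nx + cx];
      pv[c][0] = cx * sx; pv[c][1] = cy * sy; pv[c][2] = cz * sz;
    }
    for (int t = 0; t < 6; ++t) {
      const int* vt = tets[t];
      int above[4], ab = 0, bl = 0;
      int below[4];
      for (int v = 0; v < 4; ++v) {
        if (fv[vt[v]] > level) above[ab++] = vt[v];
        else below[bl++] = vt[v];
      }
      if (ab == 0 || ab == 4) continue;
      double q[4][3];
      if (ab == 1 || ab == 3) {
        int apex = ab == 1 ? above[0] : below[0];
        const int* others = ab == 1 ? below : above;
        for (int v = 0; v < 3; ++v)
          interp_pt(pv[apex], fv[apex], pv[others[v]], fv[others[v]], level, q[v]);
        area += tri_area(q[0], q[1], q[2]);
      } else {
        // 2 above / 2 below: quad AC, AD, BD, BC (non-crossing order)
        int A = above[0], B = above[1], C = below[0], D = below[1];
        interp_pt(pv[A], fv[A], pv[C], fv[C], level, q[0]);
        interp_pt(pv[A], fv[A], pv[D], fv[D], level, q[1]);
        interp_pt(pv[B], fv[B], pv[D], fv[D], level, q[2]);
        interp_pt(pv[B], fv[B], pv[C], fv[C], level, q[3]);
        area += tri_area(q[0], q[1], q[2]) + tri_area(q[0], q[2], q[3]);
      }
    }
  }
  return area;
}

// ---- affine resampling (trilinear / nearest), for augmentation ------------
// For each 0-based output voxel o, the source location is src = A %*% o + s.

// [[Rcpp::export]]
NumericVector resample3(NumericVector x, IntegerVector dims, NumericMatrix A,
                        NumericVector shift, bool nearest, double background) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  const double* xp = REAL(x);
  double* op = REAL(out);
  for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y) for (int xx = 0; xx < nx; ++xx) {
    double sxd = A(0, 0) * xx + A(0, 1) * y + A(0, 2) * z + shift[0];
    double syd = A(1, 0) * xx + A(1, 1) * y + A(1, 2) * z + shift[1];
    double szd = A(2, 0) * xx + A(2, 1) * y + A(2, 2) * z + shift[2];
    R_xlen_t oi = ((R_xlen_t)z * ny + y) * nx + xx;
    if (nearest) {
      int ix = (int)std::lround(sxd), iy = (int)std::lround(syd), iz = (int)std::lround(szd);
      if (ix < 0 || ix >= nx || iy < 0 || iy >= ny || iz < 0 || iz >= nz) op[oi] = background;
      else op[oi] = xp[((R_xlen_t)iz * ny + iy) * nx + ix];
    } else {
      int ix = (int)std::floor(sxd), iy = (int)std::floor(syd), iz = (int)std::floor(szd);
      double fx = sxd - ix, fy = syd - iy, fz = szd - iz;
      double acc = 0.0;
      for (int dz = 0; dz < 2; ++dz) for (int dy = 0; dy < 2; ++dy) for (int dx = 0; dx < 2; ++dx) {
        double w = (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy) * (dz ? fz : 1 - fz);
        if (w == 0.0) continue;
        int px = ix + dx, py = iy + dy, pz = iz + dz;
        double v = (px < 0 || px >= nx || py < 0 || py >= ny || pz < 0 || pz >= nz)
                     ? background : xp[((R_xlen_t)pz * ny + py) * nx + px];
        acc += w * v;
      }
      op[oi] = acc;
    }
  }
  return out;
}
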