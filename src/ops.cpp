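#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Trilinear interpolation at continuous 0-based voxel coordinates.
// Points outside [0, n-1] on any axis are flagged not-inside.
static inline double interp3(const double* src, int nx, int ny, int nz,
                             double x, double y, double z, bool& inside) {
  if (x < 0.0 || y < 0.0 || z < 0.0 ||
      x > nx - 1.0 || y > ny - 1.0 || z > nz - 1.0) {
    inside = false;
    return 0.0;
  }
  inside = true;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  if (x0 == nx - 1) x0--;
  if (y0 == ny - 1) y0--;
  if (z0 == nz - 1) z0--;
  if (nx == 1) x0 = 0;
  if (ny == 1) y0 = 0;
  if (nz == 1) z0 = 0;
  double fx = x - x0, fy = y - y0, fz = z - z0;
  int x1 = std::min(x0 + 1, nx - 1);
  int y1 = std::min(y0 + 1, ny - 1);
  int z1 = std::min(z0 + 1, nz - 1);
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  double c000 = src[x0 * sx + y0 * sy + z0 * sz];
  double c100 = src[x1 * sx + y0 * sy + z0 * sz];
  double c010 = src[x0 * sx + y1 * sy + z0 * sz];
  double c110 = src[x1 * sx + y1 * sy + z0 * sz];
  double c001 = src[x0 * sx + y0 * sy + z1 * sz];
  double c101 = src[x1 * sx + y0 * sy + z1 * sz];
  double c011 = src[x0 * sx + y1 * sy + z1 * sz];
  double c111 = src[x1 * sx + y1 * sy + z1 * sz];
  double c00 = c000 * (1 - fx) + c100 * fx;
  double c10 = c010 * (1 - fx) + c110 * fx;
  double c01 = c001 * (1 - fx) + c101 * fx;
  double c11 = c011 * (1 - fx) + c111 * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// Resample a source volume onto an output grid. M (4x4) maps output voxel
// indices (0-based, homogeneous) to continuous source voxel coordinates.
// Out-of-field voxels are set to `fill`.
// [[Rcpp::export]]
NumericVector cpp_resample(NumericVector src, IntegerVector sdim,
                           IntegerVector odim, NumericMatrix M, double fill) {
  int nx = sdim[0], ny = sdim[1], nz = sdim[2];
  int ox = odim[0], oy = odim[1], oz = odim[2];
  NumericVector out((R_xlen_t)ox * oy * oz);
  const double* s = src.begin();
  double m00 = M(0,0), m01 = M(0,1), m02 = M(0,2), m03 = M(0,3);
  double m10 = M(1,0), m11 = M(1,1), m12 = M(1,2), m13 = M(1,3);
  double m20 = M(2,0), m21 = M(2,1), m22 = M(2,2), m23 = M(2,3);
  R_xlen_t idx = 0;
  for (int k = 0; k < oz; k++) {
    for (int j = 0; j < oy; j++) {
      double bx = m01 * j + m02 * k + m03;
      double by = m11 * j + m12 * k + m13;
      double bz = m21 * j + m22 * k + m23;
      for (int i = 0; i < ox; i++, idx++) {
        bool inside;
        double v = interp3(s, nx, ny, nz,
                           m00 * i + bx, m10 * i + by, m20 * i + bz, inside);
        out[idx] = inside ? v : fill;
      }
    }
  }
  out.attr("dim") = odim;
  return out;
}

// Interpolate source volume at continuous voxel coordinates (3 x N).
// Outside points yield NA.
// [[Rcpp::export]]
NumericVector cpp_interp_points(NumericVector src, IntegerVector sdim,
                                NumericMatrix pts) {
  int nx = sdim[0], ny = sdim[1], nz = sdim[2];
  R_xlen_t n = pts.ncol();
  NumericVector out(n);
  const double* s = src.begin();
  for (R_xlen_t q = 0; q < n; q++) {
    bool inside;
    double v = interp3(s, nx, ny, nz, pts(0, q), pts(1, q), pts(2, q), inside);
    out[q] = inside ? v : NA_REAL;
  }
  return out;
}

// Mutual information (bits) between fixed-sample intensities and the moving
// volume interpolated at mapped sample locations. `pts` holds fixed-space
// world coordinates (3 x N); M (4x4) maps fixed world -> moving voxel
// coordinates. Intensities are soft-assigned to bins with linear weights,
// which keeps the cost surface smooth under subvoxel motion.
// [[Rcpp::export]]
List cpp_mi(NumericVector fvals, double fmin, double fmax,
            NumericVector src, IntegerVector sdim, NumericMatrix M,
            NumericMatrix pts, double mmin, double mmax, int bins) {
  int nx = sdim[0], ny = sdim[1], nz = sdim[2];
  R_xlen_t n = pts.ncol();
  std::vector<double> joint((size_t)bins * bins, 0.0);
  const double* s = src.begin();
  double m00 = M(0,0), m01 = M(0,1), m02 = M(0,2), m03 = M(0,3);
  double m10 = M(1,0), m11 = M(1,1), m12 = M(1,2), m13 = M(1,3);
  double m20 = M(2,0), m21 = M(2,1), m22 = M(2,2), m23 = M(2,3);
  double fscale = (fmax > fmin) ? (bins - 1) / (fmax - fmin) : 0.0;
  double mscale = (mmax > mmin) ? (bins - 1) / (mmax - mmin) : 0.0;
  double total = 0.0;
  R_xlen_t nov = 0;
  for (R_xlen_t q = 0; q < n; q++) {
    double wx = pts(0, q), wy = pts(1, q), wz = pts(2, q);
    double x = m00 * wx + m01 * wy + m02 * wz + m03;
    double y = m10 * wx + m11 * wy + m12 * wz + m13;
    double z = m20 * wx + m21 * wy + m22 * wz + m23;
    bool inside;
    double mv = interp3(s, nx, ny, nz, x, y, z, inside);
    if (!inside) continue;
    nov++;
    double fu = (fvals[q] - fmin) * fscale;
    double mu = (mv - mmin) * mscale;
    if (fu < 0) fu = 0; if (fu > bins - 1) fu = bins - 1;
    if (mu < 0) mu = 0; if (mu > bins - 1) mu = bins - 1;
    int fi = (int)fu; if (fi == bins - 1) fi--;
    int mi = (int)mu; if (mi == bins - 1) mi--;
    if (bins == 1) { fi = 0; mi = 0; }
    double fw = fu - fi, mw = mu - mi;
    joint[(size_t)fi * bins + mi]           += (1 - fw) * (1 - mw);
    joint[(size_t)fi * bins + mi + 1]       += (1 - fw) * mw;
    joint[(size_t)(fi + 1) * bins + mi]     += fw * (1 - mw);
    joint[(size_t)(fi + 1) * bins + mi + 1] += fw * mw;
    total += 1.0;
  }
  if (nov == 0 || total <= 0.0)
    return List::create(_["mi"] = NA_REAL, _["n_overlap"] = (double)nov);
  std::vector<double> pf(bins, 0.0), pm(bins, 0.0);
  for (int a = 0; a < bins; a++)
    for (int b = 0; b < bins; b++) {
      double p = joint[(size_t)a * bins + b] / total;
      pf[a] += p;
      pm[b] += p;
    }
  double hf = 0.0, hm = 0.0, hj = 0.0;
  const double l2 = std::log(2.0);
  for (int a = 0; a < bins; a++) {
    if (pf[a] > 0) hf -= pf[a] * std::log(pf[a]) / l2;
    if (pm[a] > 0) hm -= pm[a] * std::log(pm[a]) / l2;
    for (int b = 0; b < bins; b++) {
      double p = joint[(size_t)a * bins + b] / total;
      if (p > 0) hj -= p * std::log(p) / l2;
    }
  }
  return List::create(_["mi"] = hf + hm - hj, _["n_overlap"] = (double)nov,
                      _["h_fixed"] = hf, _["h_moving"] = hm,
                      _["h_joint"] = hj);
}

// Correlation ratio of moving intensities conditioned on binned fixed
// intensities: 1 - within-bin variance / total variance. Same sampling
// geometry as cpp_mi.
// [[Rcpp::export]]
List cpp_cr(NumericVector fvals, double fmin, double fmax,
            NumericVector src, IntegerVector sdim, NumericMatrix M,
            NumericMatrix pts, int bins) {
  int nx = sdim[0], ny = sdim[1], nz = sdim[2];
  R_xlen_t n = pts.ncol();
  std::vector<double> cnt(bins, 0.0), sum(bins, 0.0), ssq(bins, 0.0);
  const double* s = src.begin();
  double m00 = M(0,0), m01 = M(0,1), m02 = M(0,2), m03 = M(0,3);
  double m10 = M(1,0), m11 = M(1,1), m12 = M(1,2), m13 = M(1,3);
  double m20 = M(2,0), m21 = M(2,1), m22 = M(2,2), m23 = M(2,3);
  double fscale = (fmax > fmin) ? bins / (fmax - fmin) : 0.0;
  double tsum = 0.0, tssq = 0.0;
  R_xlen_t nov = 0;
  for (R_xlen_t q = 0; q < n; q++) {
    double wx = pts(0, q), wy = pts(1, q), wz = pts(2, q);
    double x = m00 * wx + m01 * wy + m02 * wz + m03;
    double y = m10 * wx + m11 * wy + m12 * wz + m13;
    double z = m20 * wx + m21 * wy + m22 * wz + m23;
    bool inside;
    double mv = interp3(s, nx, ny, nz, x, y, z, inside);
    if (!inside) continue;
    int b = (int)((fvals[q] - fmin) * fscale);
    if (b < 0) b = 0;
    if (b > bins - 1) b = bins - 1;
    cnt[b] += 1.0; sum[b] += mv; ssq[b] += mv * mv;
    tsum += mv; tssq += mv * mv;
    nov++;
  }
  if (nov < 2)
    return List::create(_["cr"] = NA_REAL, _["n_overlap"] = (double)nov,
                        _["total_var"] = NA_REAL);
  double N = (double)nov;
  double totvar = tssq - tsum * tsum / N;
  double within = 0.0;
  for (int b = 0; b < bins; b++)
    if (cnt[b] > 0) within += ssq[b] - sum[b] * sum[b] / cnt[b];
  double cr = (totvar > 0) ? 1.0 - within / totvar : NA_REAL;
  return List::create(_["cr"] = cr, _["n_overlap"] = (double)nov,
                      _["total_var"] = totvar / N);
}

// Separable Gaussian smoothing with per-axis sigma in voxel units.
// Kernels are truncated at 3 sigma and renormalized near edges.
static void smooth_axis(std::vector<double>& a, int nx, int ny, int nz,
                        int axis, double sigma) {
  if (sigma <= 0) return;
  int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> k(2 * r + 1);
  for (int t = -r; t <= r; t++)
    k[t + r] = std::exp(-0.5 * t * t / (sigma * sigma));
  int n[3] = {nx, ny, nz};
  R_xlen_t stride[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
  int len = n[axis];
  R_xlen_t st = stride[axis];
  int u = axis == 0 ? 1 : 0;
  int v = axis == 2 ? 1 : 2;
  std::vector<double> line(len);
  for (int b = 0; b < n[v]; b++) {
    for (int aIdx = 0; aIdx < n[u]; aIdx++) {
      R_xlen_t base = (R_xlen_t)aIdx * stride[u] + (R_xlen_t)b * stride[v];
      for (int t = 0; t < len; t++) line[t] = a[base + (R_xlen_t)t * st];
      for (int t = 0; t < len; t++) {
        double acc = 0.0, wsum = 0.0;
        int lo = std::max(0, t - r), hi = std::min(len - 1, t + r);
        for (int p = lo; p <= hi; p++) {
          double w = k[p - t + r];
          acc += w * line[p];
          wsum += w;
        }
        a[base + (R_xlen_t)t * st] = acc / wsum;
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_gauss3(NumericVector arr, IntegerVector dim,
                         NumericVector sigma_vox) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> a(arr.begin(), arr.end());
  smooth_axis(a, nx, ny, nz, 0, sigma_vox[0]);
  smooth_axis(a, nx, ny, nz, 1, sigma_vox[1]);
  smooth_axis(a, nx, ny, nz, 2, sigma_vox[2]);
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dim;
  return out;
}

// 6-connected component labelling; labels start at 1, background 0.
// [[Rcpp::export]]
IntegerVector cpp_conncomp(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  int next = 0;
  std::vector<R_xlen_t> stack;
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  for (R_xlen_t i = 0; i < n; i++) {
    if (!mask[i] || lab[i] != 0) continue;
    next++;
    lab[i] = next;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t c = stack.back();
      stack.pop_back();
      int z = (int)(c / sz), rem = (int)(c % sz);
      int y = rem / nx, x = rem % nx;
      const int dx[6] = {-1, 1, 0, 0, 0, 0};
      const int dy[6] = {0, 0, -1, 1, 0, 0};
      const int dz[6] = {0, 0, 0, 0, -1, 1};
      for (int d = 0; d < 6; d++) {
        int xx = x + dx[d], yy = y + dy[d], zz = z + dz[d];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
          continue;
        R_xlen_t cc = xx * sx + yy * sy + zz * sz;
        if (mask[cc] && lab[cc] == 0) {
          lab[cc] = next;
          stack.push_back(cc);
        }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// Binary dilation/erosion with a digital ball of the given voxel radius.
// [[Rcpp::export]]
LogicalVector cpp_morph(LogicalVector mask, IntegerVector dim, int radius,
                        bool dilate) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<int> ox, oy, oz;
  for (int dz = -radius; dz <= radius; dz++)
    for (int dy = -radius; dy <= radius; dy++)
      for (int dx = -radius; dx <= radius; dx++)
        if (dx * dx + dy * dy + dz * dz <= radius * radius) {
          ox.push_back(dx); oy.push_back(dy); oz.push_back(dz);
        }
  size_t no = ox.size();
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector out(n);
  const R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny;
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++)
      for (int x = 0; x < nx; x++) {
        bool hit = dilate ? false : true;
        for (size_t t = 0; t < no; t++) {
          int xx = x + ox[t], yy = y + oy[t], zz = z + oz[t];
          bool v;
          if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
            v = false;  // outside the grid counts as background
          else
            v = mask[xx + yy * sy + zz * sz];
          if (dilate) {
            if (v) { hit = true; break; }
          } else {
            if (!v) { hit = false; break; }
          }
        }
        out[x + y * sy + z * sz] = hit;
      }
  out.attr("dim") = dim;
  return out;
}
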