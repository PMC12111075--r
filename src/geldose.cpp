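#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
#include <queue>
using namespace Rcpp;

static inline int sub2ind(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// Trilinear interpolation at fractional 1-based voxel indices.
// Returns NA outside the grid or when any participating corner is NA.
static double trilinear_at(const double *v, int nx, int ny, int nz,
                           double x, double y, double z) {
  // convert to 0-based
  x -= 1.0; y -= 1.0; z -= 1.0;
  if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1)
    return NA_REAL;
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
  if (i0 == nx - 1) i0--;
  if (j0 == ny - 1) j0--;
  if (k0 == nz - 1) k0--;
  if (nx == 1) i0 = 0;
  if (ny == 1) j0 = 0;
  if (nz == 1) k0 = 0;
  double fx = x - i0, fy = y - j0, fz = z - k0;
  int i1 = std::min(i0 + 1, nx - 1), j1 = std::min(j0 + 1, ny - 1),
      k1 = std::min(k0 + 1, nz - 1);
  double c[8] = {
    v[sub2ind(i0, j0, k0, nx, ny)], v[sub2ind(i1, j0, k0, nx, ny)],
    v[sub2ind(i0, j1, k0, nx, ny)], v[sub2ind(i1, j1, k0, nx, ny)],
    v[sub2ind(i0, j0, k1, nx, ny)], v[sub2ind(i1, j0, k1, nx, ny)],
    v[sub2ind(i0, j1, k1, nx, ny)], v[sub2ind(i1, j1, k1, nx, ny)]};
  for (int m = 0; m < 8; ++m)
    if (ISNAN(c[m])) return NA_REAL;
  double w00 = c[0] * (1 - fx) + c[1] * fx;
  double w10 = c[2] * (1 - fx) + c[3] * fx;
  double w01 = c[4] * (1 - fx) + c[5] * fx;
  double w11 = c[6] * (1 - fx) + c[7] * fx;
  double w0 = w00 * (1 - fy) + w10 * fy;
  double w1 = w01 * (1 - fy) + w11 * fy;
  return w0 * (1 - fz) + w1 * fz;
}

// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector vol, IntegerVector dims,
                            NumericMatrix idx) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = idx.nrow();
  NumericVector out(n);
  const double *v = vol.begin();
  for (int p = 0; p < n; ++p)
    out[p] = trilinear_at(v, nx, ny, nz, idx(p, 0), idx(p, 1), idx(p, 2));
  return out;
}

// Separable Gaussian blur with normalized convolution over a mask.
// sigma_vox: per-axis sigma in voxel units. Voxels outside the mask get NA.
// [[Rcpp::export]]
NumericVector cpp_gaussian_blur3(NumericVector vol, IntegerVector dims,
                                 NumericVector sigma_vox, LogicalVector mask) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  long n = (long)nx * ny * nz;
  std::vector<double> num(n), den(n);
  for (long i = 0; i < n; ++i) {
    bool in = mask[i] && !ISNAN(vol[i]);
    num[i] = in ? vol[i] : 0.0;
    den[i] = in ? 1.0 : 0.0;
  }
  int nd[3] = {nx, ny, nz};
  for (int axis = 0; axis < 3; ++axis) {
    double s = sigma_vox[axis];
    if (s <= 0) continue;
    int rad = std::max(1, (int)std::ceil(3.5 * s));
    std::vector<double> ker(2 * rad + 1);
    double ks = 0;
    for (int t = -rad; t <= rad; ++t) {
      ker[t + rad] = std::exp(-0.5 * t * t / (s * s));
      ks += ker[t + rad];
    }
    for (size_t t = 0; t < ker.size(); ++t) ker[t] /= ks;
    int len = nd[axis];
    long stride = 1;
    for (int a = 0; a < axis; ++a) stride *= nd[a];
    long nline = n / len;
    std::vector<double> bufn(len), bufd(len);
    // iterate over all 1D lines along `axis`
    for (long line = 0; line < nline; ++line) {
      // compute base index of this line
      long outer = line / stride, inner = line % stride;
      long base = inner + outer * stride * len;
      for (int t = 0; t < len; ++t) {
        bufn[t] = num[base + (long)t * stride];
        bufd[t] = den[base + (long)t * stride];
      }
      for (int t = 0; t < len; ++t) {
        double an = 0, ad = 0;
        int lo = std::max(0, t - rad), hi = std::min(len - 1, t + rad);
        for (int u = lo; u <= hi; ++u) {
          double w = ker[u - t + rad];
          an += w * bufn[u];
          ad += w * bufd[u];
        }
        num[base + (long)t * stride] = an;
        den[base + (long)t * stride] = ad;
      }
    }
  }
  NumericVector out(n);
  for (long i = 0; i < n; ++i)
    out[i] = (mask[i] && den[i] > 0) ? num[i] / den[i] : NA_REAL;
  out.attr("dim") = dims;
  return out;
}

// 1D squared distance transform (Felzenszwalb & Huttenlocher), anisotropic step h.
static void dt1d(const std::vector<double> &f, std::vector<double> &d, int n,
                 double h) {
  std::vector<int> v(n);
  std::vector<double> zz(n + 1);
  int k = 0;
  v[0] = 0;
  zz[0] = -1e30;
  zz[1] = 1e30;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + h * h * q * q) - (f[p] + h * h * p * p)) /
          (2.0 * h * (q - p));
      if (s <= zz[k]) { k--; } else break;
    }
    k++;
    v[k] = q;
    zz[k] = s;
    zz[k + 1] = 1e30;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zz[k + 1] < h * q) k++;
    int p = v[k];
    d[q] = h * h * (q - p) * (q - p) + f[p];
  }
}

// Exact Euclidean distance (mm) to the nearest feature voxel centre.
// [[Rcpp::export]]
NumericVector cpp_edt3(LogicalVector feature, IntegerVector dims,
                       NumericVector spacing) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  long n = (long)nx * ny * nz;
  std::vector<double> d(n);
  for (long i = 0; i < n; ++i) d[i] = feature[i] ? 0.0 : 1e30;
  int nd[3] = {nx, ny, nz};
  for (int axis = 0; axis < 3; ++axis) {
    int len = nd[axis];
    long stride = 1;
    for (int a = 0; a < axis; ++a) stride *= nd[a];
    long nline = n / len;
    std::vector<double> f(len), dd(len);
    for (long line = 0; line < nline; ++line) {
      long outer = line / stride, inner = line % stride;
      long base = inner + outer * stride * len;
      for (int t = 0; t < len; ++t) f[t] = d[base + (long)t * stride];
      dt1d(f, dd, len, spacing[axis]);
      for (int t = 0; t < len; ++t) d[base + (long)t * stride] = dd[t];
    }
  }
  NumericVector out(n);
  for (long i = 0; i < n; ++i) out[i] = std::sqrt(d[i]);
  out.attr("dim") = dims;
  return out;
}

// 3D global gamma with Wendling-style radially sorted search and early
// termination. ref/eval share the grid; eval may contain NA (invalid).
// dd_abs: dose-difference criterion in absolute dose units.
// Candidate positions are voxel centres offset by multiples of spacing/interp
// within search_radius (Euclidean, mm). Returns NA where not evaluated or no
// valid candidate exists.
// [[Rcpp::export]]
NumericVector cpp_gamma3d(NumericVector ref, NumericVector eval,
                          IntegerVector dims, NumericVector spacing,
                          LogicalVector evaluate, double dta, double dd_abs,
                          double search_radius, int interp, double cap) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  long n = (long)nx * ny * nz;
  double sx = spacing[0] / interp, sy = spacing[1] / interp,
         sz = spacing[2] / interp;
  int mx = (int)std::floor(search_radius / sx);
  int my = (int)std::floor(search_radius / sy);
  int mz = (int)std::floor(search_radius / sz);
  struct Off { double d2; double ox, oy, oz; };
  std::vector<Off> offs;
  offs.reserve((size_t)(2 * mx + 1) * (2 * my + 1) * (2 * mz + 1) / 2 + 8);
  double r2max = search_radius * search_radius;
  for (int a = -mx; a <= mx; ++a)
    for (int b = -my; b <= my; ++b)
      for (int c = -mz; c <= mz; ++c) {
        double dx = a * sx, dy = b * sy, dz = c * sz;
        double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 <= r2max)
          offs.push_back({d2, dx / spacing[0], dy / spacing[1],
                          dz / spacing[2]});
      }
  std::sort(offs.begin(), offs.end(),
            [](const Off &a, const Off &b) { return a.d2 < b.d2; });
  size_t noff = offs.size();
  const double *rv = ref.begin(), *ev = eval.begin();
  NumericVector out(n, NA_REAL);
  double dta2 = dta * dta;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        long id = sub2ind(i, j, k, nx, ny);
        if (!evaluate[id]) continue;
        double dref = rv[id];
        if (ISNAN(dref)) continue;
        double best2 = R_PosInf;
        for (size_t t = 0; t < noff; ++t) {
          double dist2 = offs[t].d2 / dta2;
          if (dist2 >= best2) break;  // sorted: nothing better remains
          double val = trilinear_at(ev, nx, ny, nz, i + 1 + offs[t].ox,
                                    j + 1 + offs[t].oy, k + 1 + offs[t].oz);
          if (ISNAN(val)) continue;
          double dd = (val - dref) / dd_abs;
          double g2 = dist2 + dd * dd;
          if (g2 < best2) best2 = g2;
        }
        if (R_FINITE(best2)) out[id] = std::min(std::sqrt(best2), cap);
      }
  out.attr("dim") = dims;
  return out;
}

// 6-connected components of a 3D logical mask; returns integer labels
// (0 = background), labelled in scan order.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  long n = (long)nx * ny * nz;
  IntegerVector lab(n, 0);
  int next = 0;
  std::queue<long> q;
  const int di[6] = {1, -1, 0, 0, 0, 0};
  const int dj[6] = {0, 0, 1, -1, 0, 0};
  const int dk[6] = {0, 0, 0, 0, 1, -1};
  for (long s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    lab[s] = ++next;
    q.push(s);
    while (!q.empty()) {
      long c = q.front();
      q.pop();
      int i = c % nx, j = (c / nx) % ny, k = c / ((long)nx * ny);
      for (int m = 0; m < 6; ++m) {
        int ii = i + di[m], jj = j + dj[m], kk = k + dk[m];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
          continue;
        long t = sub2ind(ii, jj, kk, nx, ny);
        if (mask[t] && lab[t] == 0) {
          lab[t] = next;
          q.push(t);
        }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}
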