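// 3-D image primitives for crack-network analysis: connected components,
// exact Euclidean distance transforms (Felzenszwalb & Huttenlocher),
// local-thickness, per-slice morphology, separable Gaussian smoothing,
// structure-tensor plane normals, nearest-neighbour rotation resampling.
// All arrays are R column-major with dims (n1, n2, n3) = (z, y, x);
// linear index i = i1 + n1*(i2 + n2*i3), 0-based.

#include <RcppArmadillo.h>
#include <queue>
#include <algorithm>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double INF = 1e30;

// ---------- connected components ----------

// [[Rcpp::export]]
IntegerVector cpp_cc_label(LogicalVector mask, IntegerVector dims,
                           int connectivity) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  if (connectivity != 6 && connectivity != 26)
    stop("connectivity must be 6 or 26");
  std::vector<int> off1, off2, off3;
  for (int d3 = -1; d3 <= 1; ++d3)
    for (int d2 = -1; d2 <= 1; ++d2)
      for (int d1 = -1; d1 <= 1; ++d1) {
        if (d1 == 0 && d2 == 0 && d3 == 0) continue;
        int manh = std::abs(d1) + std::abs(d2) + std::abs(d3);
        if (connectivity == 6 && manh != 1) continue;
        off1.push_back(d1); off2.push_back(d2); off3.push_back(d3);
      }
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack_;
  int next_id = 0;
  std::vector<R_xlen_t> sizes, minidx;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next_id;
    R_xlen_t sz = 0, mi = s;
    lab[s] = next_id;
    stack_.clear();
    stack_.push_back(s);
    while (!stack_.empty()) {
      R_xlen_t cur = stack_.back(); stack_.pop_back();
      ++sz;
      int i1 = cur % n1;
      int i2 = (cur / n1) % n2;
      int i3 = cur / ((R_xlen_t)n1 * n2);
      for (size_t k = 0; k < off1.size(); ++k) {
        int j1 = i1 + off1[k], j2 = i2 + off2[k], j3 = i3 + off3[k];
        if (j1 < 0 || j1 >= n1 || j2 < 0 || j2 >= n2 || j3 < 0 || j3 >= n3)
          continue;
        R_xlen_t t = j1 + (R_xlen_t)n1 * (j2 + (R_xlen_t)n2 * j3);
        if (mask[t] && lab[t] == 0) {
          lab[t] = next_id;
          if (t < mi) mi = t;
          stack_.push_back(t);
        }
      }
    }
    sizes.push_back(sz);
    minidx.push_back(mi);
  }
  // deterministic ids: decreasing size, ties by smallest linear index
  std::vector<int> order(next_id);
  for (int i = 0; i < next_id; ++i) order[i] = i;
  std::sort(order.begin(), order.end(), [&](int a, int b) {
    if (sizes[a] != sizes[b]) return sizes[a] > sizes[b];
    return minidx[a] < minidx[b];
  });
  std::vector<int> remap(next_id + 1, 0);
  for (int r = 0; r < next_id; ++r) remap[order[r] + 1] = r + 1;
  for (R_xlen_t s = 0; s < n; ++s)
    if (lab[s] != 0) lab[s] = remap[lab[s]];
  return lab;
}

// ---------- 1-D squared-distance transform (lower envelope) ----------

static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& arg, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0; z[0] = -INF; z[1] = INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] >= INF && f[v[k]] >= INF) continue; // both infinite: keep earlier
    double s;
    while (true) {
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) {
        if (k == 0) { k = -1; break; }
        --k;
      } else break;
    }
    if (k < 0) { k = 0; v[0] = q; z[0] = -INF; z[1] = INF; }
    else { ++k; v[k] = q; z[k] = s; z[k + 1] = INF; }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = (double)(q - v[k]) * (q - v[k]) + f[v[k]];
    d[q] = dq;
    arg[q] = v[k];
  }
}

// squared EDT of `mask` to nearest background voxel (in-volume only)
static std::vector<double> edt3d_sq(const LogicalVector& mask, int n1, int n2,
                                    int n3) {
  R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  std::vector<double> d(n);
  for (R_xlen_t i = 0; i < n; ++i) d[i] = mask[i] ? INF : 0.0;
  int nmax = std::max(n1, std::max(n2, n3));
  std::vector<double> f(nmax), dd(nmax);
  std::vector<int> arg(nmax);
  // pass along axis 1
  for (int i3 = 0; i3 < n3; ++i3)
    for (int i2 = 0; i2 < n2; ++i2) {
      R_xlen_t base = (R_xlen_t)n1 * (i2 + (R_xlen_t)n2 * i3);
      for (int i1 = 0; i1 < n1; ++i1) f[i1] = d[base + i1];
      dt1d(f, dd, arg, n1);
      for (int i1 = 0; i1 < n1; ++i1) d[base + i1] = dd[i1];
    }
  // axis 2
  for (int i3 = 0; i3 < n3; ++i3)
    for (int i1 = 0; i1 < n1; ++i1) {
      for (int i2 = 0; i2 < n2; ++i2)
        f[i2] = d[i1 + (R_xlen_t)n1 * (i2 + (R_xlen_t)n2 * i3)];
      dt1d(f, dd, arg, n2);
      for (int i2 = 0; i2 < n2; ++i2)
        d[i1 + (R_xlen_t)n1 * (i2 + (R_xlen_t)n2 * i3)] = dd[i2];
    }
  // axis 3
  for (int i2 = 0; i2 < n2; ++i2)
    for (int i1 = 0; i1 < n1; ++i1) {
      for (int i3 = 0; i3 < n3; ++i3)
        f[i3] = d[i1 + (R_xlen_t)n1 * (i2 + (R_xlen_t)n2 * i3)];
      dt1d(f, dd, arg, n3);
      for (int i3 = 0; i3 < n3; ++i3)
        d[i1 + (R_xlen_t)n1 * (i2 + (R_xlen_t)n2 * i3)] = dd[i3];
    }
  return d;
}

// [[Rcpp::export]]
NumericVector cpp_edt3d(LogicalVector mask, IntegerVector dims) {
  std::vector<double> d = edt3d_sq(mask, dims[0], dims[1], dims[2]);
  NumericVector out(d.size());
  for (R_xlen_t i = 0; i < (R_xlen_t)d.size(); ++i)
    out[i] = d[i] >= INF ? R_PosInf : std::sqrt(d[i]);
  return out;
}

// Local thickness: th(v) = 2 * max{ r(c) : |c - v| <= r(c) } over mask
// voxels c, with r(c) = EDT(c) - 0.5 (distance from voxel centre to the
// nearest background centre, pulled back half a voxel to the interface).
// [[Rcpp::export]]
NumericVector cpp_local_thickness(LogicalVector mask, IntegerVector dims) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  std::vector<double> d2 = edt3d_sq(mask, n1, n2, n3);
  NumericVector th(n, 0.0);
  std::vector<R_xlen_t> idx;
  idx.reserve(n / 8);
  for (R_xlen_t i = 0; i < n; ++i)
    if (mask[i] && d2[i] < INF) idx.push_back(i);
  std::sort(idx.begin(), idx.end(), [&](R_xlen_t a, R_xlen_t b) {
    return d2[a] > d2[b];
  });
  for (R_xlen_t c : idx) {
    double r = std::sqrt(d2[c]) - 0.5;
    if (r < 0) r = 0;
    double t = 2.0 * r;
    int ri = (int)std::floor(r);
    int c1 = c % n1, c2 = (c / n1) % n2, c3 = c / ((R_xlen_t)n1 * n2);
    for (int j3 = std::max(0, c3 - ri); j3 <= std::min(n3 - 1, c3 + ri); ++j3)
      for (int j2 = std::max(0, c2 - ri); j2 <= std::min(n2 - 1, c2 + ri); ++j2)
        for (int j1 = std::max(0, c1 - ri); j1 <= std::min(n1 - 1, c1 + ri); ++j1) {
          double dist2 = (double)(j1 - c1) * (j1 - c1) +
                         (double)(j2 - c2) * (j2 - c2) +
                         (double)(j3 - c3) * (j3 - c3);
          if (dist2 <= r * r) {
            R_xlen_t t2i = j1 + (R_xlen_t)n1 * (j2 + (R_xlen_t)n2 * j3);
            if (mask[t2i] && th[t2i] < t) th[t2i] = t;
          }
        }
  }
  return th;
}

// ---------- 2-D nearest-site transform ----------
// For each pixel of an (nr, nc) grid, the value carried by the nearest
// site pixel (exact Euclidean); -1 where no site exists.

// [[Rcpp::export]]
IntegerVector cpp_nearest_site2d(LogicalVector is_site, IntegerVector site_vals,
                                 IntegerVector dims2) {
  const int nr = dims2[0], nc = dims2[1];
  const R_xlen_t n = (R_xlen_t)nr * nc;
  // step 1: per column, nearest site row
  std::vector<double> d1(n, INF);
  std::vector<int> src_row(n, -1);
  std::vector<double> f(std::max(nr, nc)), dd(std::max(nr, nc));
  std::vector<int> arg(std::max(nr, nc));
  for (int c = 0; c < nc; ++c) {
    R_xlen_t base = (R_xlen_t)nr * c;
    bool any = false;
    for (int r = 0; r < nr; ++r) {
      f[r] = is_site[base + r] ? 0.0 : INF;
      any = any || is_site[base + r];
    }
    if (!any) continue;
    dt1d(f, dd, arg, nr);
    for (int r = 0; r < nr; ++r) {
      if (dd[r] < INF) { d1[base + r] = dd[r]; src_row[base + r] = arg[r]; }
    }
  }
  // step 2: per row, lower envelope over columns with source tracking
  IntegerVector out(n, -1);
  std::vector<int> v(nc);
  std::vector<double> z(nc + 1);
  for (int r = 0; r < nr; ++r) {
    // gather g(c) = d1[r, c]
    int k = -1;
    for (int c = 0; c < nc; ++c) {
      double g = d1[r + (R_xlen_t)nr * c];
      if (g >= INF) continue;
      if (k < 0) { k = 0; v[0] = c; z[0] = -INF; z[1] = INF; continue; }
      double s;
      while (true) {
        int vc = v[k];
        double gv = d1[r + (R_xlen_t)nr * vc];
        s = ((g + (double)c * c) - (gv + (double)vc * vc)) / (2.0 * c - 2.0 * vc);
        if (s <= z[k] && k > 0) { --k; } else if (s <= z[k] && k == 0) { k = -1; break; } else break;
      }
      if (k < 0) { k = 0; v[0] = c; z[0] = -INF; z[1] = INF; }
      else { ++k; v[k] = c; z[k] = s; z[k + 1] = INF; }
    }
    if (k < 0) continue;
    int kk = 0;
    for (int c = 0; c < nc; ++c) {
      while (z[kk + 1] < c) ++kk;
      int cs = v[kk];
      int rs = src_row[r + (R_xlen_t)nr * cs];
      if (rs >= 0) out[r + (R_xlen_t)nr * c] = site_vals[rs + (R_xlen_t)nr * cs];
    }
  }
  return out;
}

// ---------- 2-D morphology (square structuring elements) ----------

static void maxfilt1(const std::vector<int>& in, std::vector<int>& out, int n,
                     int r, bool take_max) {
  for (int i = 0; i < n; ++i) {
    int lo = std::max(0, i - r), hi = std::min(n - 1, i + r);
    int b = in[lo];
    for (int j = lo + 1; j <= hi; ++j)
      b = take_max ? std::max(b, in[j]) : std::min(b, in[j]);
    out[i] = b;
  }
}

static LogicalVector morph2d(const LogicalVector& mask, int nr, int nc, int r,
                             bool dilate) {
  R_xlen_t n = (R_xlen_t)nr * nc;
  std::vector<int> a(n), b(n);
  for (R_xlen_t i = 0; i < n; ++i) a[i] = mask[i] ? 1 : 0;
  std::vector<int> col(nr), colo(nr), row(nc), rowo(nc);
  for (int c = 0; c < nc; ++c) {
    for (int i = 0; i < nr; ++i) col[i] = a[i + (R_xlen_t)nr * c];
    maxfilt1(col, colo, nr, r, dilate);
    for (int i = 0; i < nr; ++i) b[i + (R_xlen_t)nr * c] = colo[i];
  }
  for (int i = 0; i < nr; ++i) {
    for (int c = 0; c < nc; ++c) row[c] = b[i + (R_xlen_t)nr * c];
    maxfilt1(row, rowo, nc, r, dilate);
    for (int c = 0; c < nc; ++c) a[i + (R_xlen_t)nr * c] = rowo[c];
  }
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = a[i] == 1;
  return out;
}

static void maxfilt1d(const std::vector<double>& in, std::vector<double>& out,
                      int n, int r, bool take_max) {
  for (int i = 0; i < n; ++i) {
    int lo = std::max(0, i - r), hi = std::min(n - 1, i + r);
    double b = in[lo];
    for (int j = lo + 1; j <= hi; ++j)
      b = take_max ? std::max(b, in[j]) : std::min(b, in[j]);
    out[i] = b;
  }
}

static NumericVector grey_morph2d(const NumericVector& img, int nr, int nc,
                                  int r, bool dilate) {
  R_xlen_t n = (R_xlen_t)nr * nc;
  std::vector<double> a(img.begin(), img.end()), b(n);
  std::vector<double> col(nr), colo(nr), row(nc), rowo(nc);
  for (int c = 0; c < nc; ++c) {
    for (int i = 0; i < nr; ++i) col[i] = a[i + (R_xlen_t)nr * c];
    maxfilt1d(col, colo, nr, r, dilate);
    for (int i = 0; i < nr; ++i) b[i + (R_xlen_t)nr * c] = colo[i];
  }
  for (int i = 0; i < nr; ++i) {
    for (int c = 0; c < nc; ++c) row[c] = b[i + (R_xlen_t)nr * c];
    maxfilt1d(row, rowo, nc, r, dilate);
    for (int c = 0; c < nc; ++c) a[i + (R_xlen_t)nr * c] = rowo[c];
  }
  return NumericVector(a.begin(), a.end());
}

// grey-value closing with a (2r+1)^2 square: local tissue reference that
// fills thin dark cracks with the surrounding tissue grey level
// [[Rcpp::export]]
NumericVector cpp_grey_close2d(NumericVector img, IntegerVector dims2,
                               int radius) {
  if (radius <= 0) return clone(img);
  NumericVector d = grey_morph2d(img, dims2[0], dims2[1], radius, true);
  return grey_morph2d(d, dims2[0], dims2[1], radius, false);
}

// dark-line wall test: pixel has tissue (>= thr) within `maxstep` pixels on
// BOTH sides along at least one of the 4 principal directions
// [[Rcpp::export]]
LogicalVector cpp_walled2d(NumericVector grey, IntegerVector dims2,
                           double thr, int maxstep) {
  const int nr = dims2[0], nc = dims2[1];
  static const int dr[4] = {1, 0, 1, 1};
  static const int dc[4] = {0, 1, 1, -1};
  LogicalVector out((R_xlen_t)nr * nc, false);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      bool ok = false;
      for (int d = 0; d < 4 && !ok; ++d) {
        bool plus = false, minus = false;
        for (int s = 1; s <= maxstep; ++s) {
          int rp = r + s * dr[d], cp = c + s * dc[d];
          if (!plus && rp >= 0 && rp < nr && cp >= 0 && cp < nc &&
              grey[rp + (R_xlen_t)nr * cp] >= thr)
            plus = true;
          int rm = r - s * dr[d], cm = c - s * dc[d];
          if (!minus && rm >= 0 && rm < nr && cm >= 0 && cm < nc &&
              grey[rm + (R_xlen_t)nr * cm] >= thr)
            minus = true;
        }
        ok = plus && minus;
      }
      out[r + (R_xlen_t)nr * c] = ok;
    }
  return out;
}

// [[Rcpp::export]]
LogicalVector cpp_dilate2d(LogicalVector mask, IntegerVector dims2, int radius) {
  if (radius <= 0) return clone(mask);
  return morph2d(mask, dims2[0], dims2[1], radius, true);
}

// [[Rcpp::export]]
LogicalVector cpp_erode2d(LogicalVector mask, IntegerVector dims2, int radius) {
  if (radius <= 0) return clone(mask);
  return morph2d(mask, dims2[0], dims2[1], radius, false);
}

// pixels 4-connected to the image border through non-blocked pixels
// [[Rcpp::export]]
LogicalVector cpp_flood_outside(LogicalVector blocked, IntegerVector dims2) {
  const int nr = dims2[0], nc = dims2[1];
  R_xlen_t n = (R_xlen_t)nr * nc;
  LogicalVector out(n, false);
  std::vector<R_xlen_t> stack_;
  auto push = [&](int r, int c) {
    R_xlen_t i = r + (R_xlen_t)nr * c;
    if (!blocked[i] && !out[i]) { out[i] = true; stack_.push_back(i); }
  };
  for (int c = 0; c < nc; ++c) { push(0, c); push(nr - 1, c); }
  for (int r = 0; r < nr; ++r) { push(r, 0); push(r, nc - 1); }
  while (!stack_.empty()) {
    R_xlen_t cur = stack_.back(); stack_.pop_back();
    int r = cur % nr, c = cur / nr;
    if (r > 0) push(r - 1, c);
    if (r < nr - 1) push(r + 1, c);
    if (c > 0) push(r, c - 1);
    if (c < nc - 1) push(r, c + 1);
  }
  return out;
}

// ---------- separable Gaussian smoothing (reflect boundary) ----------

static std::vector<double> gauss_kernel(double sigma) {
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (auto& v : k) v /= s;
  return k;
}

static inline int reflect(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// [[Rcpp::export]]
NumericVector cpp_gauss3(NumericVector arr, IntegerVector dims, double sigma) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  std::vector<double> k = gauss_kernel(sigma);
  int r = ((int)k.size() - 1) / 2;
  std::vector<double> a(arr.begin(), arr.end()), b(n);
  // axis 1
  for (int i3 = 0; i3 < n3; ++i3)
    for (int i2 = 0; i2 < n2; ++i2) {
      R_xlen_t base = (R_xlen_t)n1 * (i2 + (R_xlen_t)n2 * i3);
      for (int i1 = 0; i1 < n1; ++i1) {
        double s = 0;
        for (int j = -r; j <= r; ++j) s += k[j + r] * a[base + reflect(i1 + j, n1)];
        b[base + i1] = s;
      }
    }
  // axis 2
  for (int i3 = 0; i3 < n3; ++i3)
    for (int i1 = 0; i1 < n1; ++i1)
      for (int i2 = 0; i2 < n2; ++i2) {
        double s = 0;
        for (int j = -r; j <= r; ++j)
          s += k[j + r] * b[i1 + (R_xlen_t)n1 * (reflect(i2 + j, n2) + (R_xlen_t)n2 * i3)];
        a[i1 + (R_xlen_t)n1 * (i2 + (R_xlen_t)n2 * i3)] = s;
      }
  // axis 3
  for (int i2 = 0; i2 < n2; ++i2)
    for (int i1 = 0; i1 < n1; ++i1)
      for (int i3 = 0; i3 < n3; ++i3) {
        double s = 0;
        for (int j = -r; j <= r; ++j)
          s += k[j + r] * a[i1 + (R_xlen_t)n1 * (i2 + (R_xlen_t)n2 * reflect(i3 + j, n3))];
        b[i1 + (R_xlen_t)n1 * (i2 + (R_xlen_t)n2 * i3)] = s;
      }
  return NumericVector(b.begin(), b.end());
}

// ---------- structure-tensor plane normals ----------
// f: smoothed crack indicator. Local plane normal at a voxel of a sheet-like
// structure = dominant eigenvector of the (post-smoothed) gradient outer
// product. Returns an n x 3 matrix of unit normals in (z, y, x) components
// for the requested 0-based linear indices.

// [[Rcpp::export]]
NumericMatrix cpp_plane_normals(NumericVector f, IntegerVector dims,
                                double sigma_tensor, IntegerVector idx) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  std::vector<double> g1(n), g2(n), g3(n);
  auto at = [&](int i1, int i2, int i3) {
    return f[reflect(i1, n1) + (R_xlen_t)n1 *
             (reflect(i2, n2) + (R_xlen_t)n2 * reflect(i3, n3))];
  };
  for (int i3 = 0; i3 < n3; ++i3)
    for (int i2 = 0; i2 < n2; ++i2)
      for (int i1 = 0; i1 < n1; ++i1) {
        R_xlen_t i = i1 + (R_xlen_t)n1 * (i2 + (R_xlen_t)n2 * i3);
        g1[i] = 0.5 * (at(i1 + 1, i2, i3) - at(i1 - 1, i2, i3));
        g2[i] = 0.5 * (at(i1, i2 + 1, i3) - at(i1, i2 - 1, i3));
        g3[i] = 0.5 * (at(i1, i2, i3 + 1) - at(i1, i2, i3 - 1));
      }
  // tensor components, smoothed
  NumericVector t11(n), t22(n), t33(n), t12(n), t13(n), t23(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    t11[i] = g1[i] * g1[i]; t22[i] = g2[i] * g2[i]; t33[i] = g3[i] * g3[i];
    t12[i] = g1[i] * g2[i]; t13[i] = g1[i] * g3[i]; t23[i] = g2[i] * g3[i];
  }
  t11 = cpp_gauss3(t11, dims, sigma_tensor);
  t22 = cpp_gauss3(t22, dims, sigma_tensor);
  t33 = cpp_gauss3(t33, dims, sigma_tensor);
  t12 = cpp_gauss3(t12, dims, sigma_tensor);
  t13 = cpp_gauss3(t13, dims, sigma_tensor);
  t23 = cpp_gauss3(t23, dims, sigma_tensor);
  NumericMatrix out(idx.size(), 3);
  arma::mat33 J;
  arma::vec3 eigval;
  arma::mat33 eigvec;
  for (R_xlen_t q = 0; q < idx.size(); ++q) {
    R_xlen_t i = idx[q];
    J(0, 0) = t11[i]; J(1, 1) = t22[i]; J(2, 2) = t33[i];
    J(0, 1) = J(1, 0) = t12[i];
    J(0, 2) = J(2, 0) = t13[i];
    J(1, 2) = J(2, 1) = t23[i];
    arma::eig_sym(eigval, eigvec, J); // ascending eigenvalues
    out(q, 0) = eigvec(0, 2);
    out(q, 1) = eigvec(1, 2);
    out(q, 2) = eigvec(2, 2);
  }
  return out;
}

// ---------- nearest-neighbour rotation resampling ----------
// out(p) = arr(Rinv %*% (p - centre) + centre); coordinates and Rinv are in
// (z, y, x) voxel units; out-of-range samples are 0.

// [[Rcpp::export]]
NumericVector cpp_rotate_nn(NumericVector arr, IntegerVector dims,
                            NumericMatrix Rinv, NumericVector centre) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  NumericVector out(n, 0.0);
  for (int i3 = 0; i3 < n3; ++i3)
    for (int i2 = 0; i2 < n2; ++i2)
      for (int i1 = 0; i1 < n1; ++i1) {
        double p1 = i1 - centre[0], p2 = i2 - centre[1], p3 = i3 - centre[2];
        double s1 = Rinv(0, 0) * p1 + Rinv(0, 1) * p2 + Rinv(0, 2) * p3 + centre[0];
        double s2 = Rinv(1, 0) * p1 + Rinv(1, 1) * p2 + Rinv(1, 2) * p3 + centre[1];
        double s3 = Rinv(2, 0) * p1 + Rinv(2, 1) * p2 + Rinv(2, 2) * p3 + centre[2];
        int j1 = (int)std::lround(s1), j2 = (int)std::lround(s2),
            j3 = (int)std::lround(s3);
        if (j1 < 0 || j1 >= n1 || j2 < 0 || j2 >= n2 || j3 < 0 || j3 >= n3)
          continue;
        out[i1 + (R_xlen_t)n1 * (i2 + (R_xlen_t)n2 * i3)] =
            arr[j1 + (R_xlen_t)n1 * (j2 + (R_xlen_t)n2 * j3)];
      }
  return out;
}

// ---------- block-mean downsampling ----------

// [[Rcpp::export]]
NumericVector cpp_block_mean(NumericVector arr, IntegerVector dims, int f) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const int m1 = n1 / f, m2 = n2 / f, m3 = n3 / f;
  NumericVector out((R_xlen_t)m1 * m2 * m3, 0.0);
  const double w = 1.0 / ((double)f * f * f);
  for (int o3 = 0; o3 < m3; ++o3)
    for (int o2 = 0; o2 < m2; ++o2)
      for (int o1 = 0; o1 < m1; ++o1) {
        double s = 0;
        for (int b3 = 0; b3 < f; ++b3)
          for (int b2 = 0; b2 < f; ++b2)
            for (int b1 = 0; b1 < f; ++b1)
              s += arr[(o1 * f + b1) +
                       (R_xlen_t)n1 * ((o2 * f + b2) +
                                       (R_xlen_t)n2 * (o3 * f + b3))];
        out[o1 + (R_xlen_t)m1 * (o2 + (R_xlen_t)m2 * o3)] = s * w;
      }
  return out;
}
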