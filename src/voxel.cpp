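// Voxel-grid kernels for 3D FISH territory quantification.
//
// Array convention (shared with the R side): spatial grids are R arrays with
// dim = c(nz, ny, nx); linear index l = k + nz*(j + ny*i), 0-based (k along z).
// Physical position of voxel (k,j,i) is its center: (k*sz, j*sy, i*sx) um.

#include <Rcpp.h>
#include <queue>
#include <cmath>
#include <limits>
using namespace Rcpp;

namespace {

struct Grid {
  int nz, ny, nx;
  Grid(const IntegerVector& dims) : nz(dims[0]), ny(dims[1]), nx(dims[2]) {}
  inline long n() const { return (long)nz * ny * nx; }
  inline long at(int k, int j, int i) const { return k + (long)nz * (j + (long)ny * i); }
};

// neighbour offsets for 6- or 26-connectivity
void neighbour_offsets(int connectivity, std::vector<std::array<int,3>>& out) {
  out.clear();
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        if (dk == 0 && dj == 0 && di == 0) continue;
        int manh = std::abs(dk) + std::abs(dj) + std::abs(di);
        if (connectivity == 6 && manh != 1) continue;
        out.push_back({dk, dj, di});
      }
}

} // namespace

// Connected-component labelling of a binary mask. Labels are 1..n in
// discovery order; the R side relabels by descending volume where required.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims,
                                   int connectivity = 26) {
  Grid g(dims);
  std::vector<std::array<int,3>> off;
  neighbour_offsets(connectivity, off);
  IntegerVector labels(g.n(), 0);
  int next = 0;
  std::vector<long> stack;
  for (int i = 0; i < g.nx; ++i)
    for (int j = 0; j < g.ny; ++j)
      for (int k = 0; k < g.nz; ++k) {
        long l0 = g.at(k, j, i);
        if (!mask[l0] || labels[l0] != 0) continue;
        ++next;
        labels[l0] = next;
        stack.clear();
        stack.push_back(l0);
        while (!stack.empty()) {
          long l = stack.back(); stack.pop_back();
          int kk = l % g.nz;
          int rest = l / g.nz;
          int jj = rest % g.ny;
          int ii = rest / g.ny;
          for (auto& d : off) {
            int k2 = kk + d[0], j2 = jj + d[1], i2 = ii + d[2];
            if (k2 < 0 || k2 >= g.nz || j2 < 0 || j2 >= g.ny || i2 < 0 || i2 >= g.nx)
              continue;
            long l2 = g.at(k2, j2, i2);
            if (mask[l2] && labels[l2] == 0) {
              labels[l2] = next;
              stack.push_back(l2);
            }
          }
        }
      }
  labels.attr("dim") = dims;
  return labels;
}

// Hysteresis labelling: seeds are voxels >= high; each seed's region grows
// through 26-connected voxels >= low. Regions reachable from several seeds
// merge (one label per connected >=low region that contains a seed).
// [[Rcpp::export]]
IntegerVector cpp_hysteresis(NumericVector img, IntegerVector dims,
                             double low, double high) {
  Grid g(dims);
  std::vector<std::array<int,3>> off;
  neighbour_offsets(26, off);
  IntegerVector labels(g.n(), 0);
  int next = 0;
  std::vector<long> stack;
  for (long l0 = 0; l0 < g.n(); ++l0) {
    if (img[l0] < high || labels[l0] != 0) continue;
    ++next;
    labels[l0] = next;
    stack.clear();
    stack.push_back(l0);
    while (!stack.empty()) {
      long l = stack.back(); stack.pop_back();
      int kk = l % g.nz;
      int rest = l / g.nz;
      int jj = rest % g.ny;
      int ii = rest / g.ny;
      for (auto& d : off) {
        int k2 = kk + d[0], j2 = jj + d[1], i2 = ii + d[2];
        if (k2 < 0 || k2 >= g.nz || j2 < 0 || j2 >= g.ny || i2 < 0 || i2 >= g.nx)
          continue;
        long l2 = g.at(k2, j2, i2);
        if (labels[l2] == 0 && img[l2] >= low) {
          labels[l2] = next;
          stack.push_back(l2);
        }
      }
    }
  }
  labels.attr("dim") = dims;
  return labels;
}

namespace {

// separable 1D Gaussian pass along one axis with reflecting boundary
void blur_axis(std::vector<double>& v, const Grid& g, int axis, double sigma) {
  if (sigma <= 0) return;
  int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> kern(2 * r + 1);
  double s = 0;
  for (int t = -r; t <= r; ++t) {
    kern[t + r] = std::exp(-0.5 * t * t / (sigma * sigma));
    s += kern[t + r];
  }
  for (auto& w : kern) w /= s;
  int len = (axis == 0) ? g.nz : (axis == 1) ? g.ny : g.nx;
  std::vector<double> line(len), out(len);
  int n1 = (axis == 0) ? g.ny : g.nz;
  int n2 = (axis == 2) ? g.ny : g.nx;
  for (int a = 0; a < n1; ++a)
    for (int b = 0; b < n2; ++b) {
      for (int t = 0; t < len; ++t) {
        long l = (axis == 0) ? g.at(t, a, b) : (axis == 1) ? g.at(a, t, b) : g.at(a, b, t);
        line[t] = v[l];
      }
      for (int t = 0; t < len; ++t) {
        double acc = 0;
        for (int u = -r; u <= r; ++u) {
          int p = t + u;
          if (p < 0) p = -p - 1;           // reflect
          if (p >= len) p = 2 * len - p - 1;
          if (p < 0) p = 0;                // degenerate len < r
          if (p >= len) p = len - 1;
          acc += kern[u + r] * line[p];
        }
        out[t] = acc;
      }
      for (int t = 0; t < len; ++t) {
        long l = (axis == 0) ? g.at(t, a, b) : (axis == 1) ? g.at(a, t, b) : g.at(a, b, t);
        v[l] = out[t];
      }
    }
}

} // namespace

// Anisotropic separable Gaussian blur; sigma given per axis in *voxels* (z,y,x).
// [[Rcpp::export]]
NumericVector cpp_gaussian_blur(NumericVector img, IntegerVector dims,
                                NumericVector sigma_vox) {
  Grid g(dims);
  std::vector<double> v(img.begin(), img.end());
  blur_axis(v, g, 0, sigma_vox[0]);
  blur_axis(v, g, 1, sigma_vox[1]);
  blur_axis(v, g, 2, sigma_vox[2]);
  NumericVector out(v.begin(), v.end());
  out.attr("dim") = dims;
  return out;
}

namespace {

// Felzenszwalb & Huttenlocher 1D squared distance transform with sample
// spacing s (samples at positions 0, s, 2s, ...).
void dt1d(std::vector<double>& f, double s) {
  int n = f.size();
  static thread_local std::vector<int> v;
  static thread_local std::vector<double> z, d;
  v.assign(n, 0); z.assign(n + 1, 0); d.assign(n, 0);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    if (!std::isfinite(f[q]) && f[q] > 0) continue;  // +Inf source never helps
    double sq = (double)q * s;
    while (true) {
      double sv = (double)v[k] * s;
      double num = (f[q] + sq * sq) - (f[v[k]] + sv * sv);
      double sep = (2.0 * sq - 2.0 * sv);
      double x = (sep > 0) ? num / sep : std::numeric_limits<double>::infinity();
      if (x <= z[k]) {
        if (k == 0) { v[0] = q; z[1] = std::numeric_limits<double>::infinity(); break; }
        --k;
      } else {
        ++k;
        v[k] = q;
        z[k] = x;
        z[k + 1] = std::numeric_limits<double>::infinity();
        break;
      }
    }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double sq = (double)q * s;
    while (z[k + 1] < sq) ++k;
    double sv = (double)v[k] * s;
    d[q] = (sq - sv) * (sq - sv) + f[v[k]];
  }
  for (int q = 0; q < n; ++q) f[q] = d[q];
}

} // namespace

// Exact anisotropic Euclidean distance transform: for every voxel, the
// distance (um) from its center to the nearest feature-voxel center.
// Returns +Inf everywhere when the feature set is empty.
// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector feature, IntegerVector dims,
                      NumericVector spacing) {
  Grid g(dims);
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> v(g.n());
  for (long l = 0; l < g.n(); ++l) v[l] = feature[l] ? 0.0 : INF;
  std::vector<double> line;
  // z axis
  line.resize(g.nz);
  for (int i = 0; i < g.nx; ++i)
    for (int j = 0; j < g.ny; ++j) {
      bool any = false;
      for (int k = 0; k < g.nz; ++k) { line[k] = v[g.at(k, j, i)]; if (std::isfinite(line[k])) any = true; }
      if (any) { dt1d(line, spacing[0]); for (int k = 0; k < g.nz; ++k) v[g.at(k, j, i)] = line[k]; }
    }
  // y axis
  line.resize(g.ny);
  for (int i = 0; i < g.nx; ++i)
    for (int k = 0; k < g.nz; ++k) {
      bool any = false;
      for (int j = 0; j < g.ny; ++j) { line[j] = v[g.at(k, j, i)]; if (std::isfinite(line[j])) any = true; }
      if (any) { dt1d(line, spacing[1]); for (int j = 0; j < g.ny; ++j) v[g.at(k, j, i)] = line[j]; }
    }
  // x axis
  line.resize(g.nx);
  for (int k = 0; k < g.nz; ++k)
    for (int j = 0; j < g.ny; ++j) {
      bool any = false;
      for (int i = 0; i < g.nx; ++i) { line[i] = v[g.at(k, j, i)]; if (std::isfinite(line[i])) any = true; }
      if (any) { dt1d(line, spacing[2]); for (int i = 0; i < g.nx; ++i) v[g.at(k, j, i)] = line[i]; }
    }
  NumericVector out(g.n());
  for (long l = 0; l < g.n(); ++l) out[l] = std::isfinite(v[l]) ? std::sqrt(v[l]) : R_PosInf;
  out.attr("dim") = dims;
  return out;
}

// 26-neighbourhood local maxima inside a mask. Plateaus are broken by linear
// index: a voxel loses to an equal-valued neighbour with a smaller index.
// Returns 1-based linear indices.
// [[Rcpp::export]]
IntegerVector cpp_local_maxima(NumericVector img, IntegerVector dims,
                               LogicalVector mask, double threshold) {
  Grid g(dims);
  std::vector<std::array<int,3>> off;
  neighbour_offsets(26, off);
  std::vector<int> peaks;
  for (int i = 0; i < g.nx; ++i)
    for (int j = 0; j < g.ny; ++j)
      for (int k = 0; k < g.nz; ++k) {
        long l = g.at(k, j, i);
        if (!mask[l]) continue;
        double v = img[l];
        if (v < threshold) continue;
        bool peak = true;
        for (auto& d : off) {
          int k2 = k + d[0], j2 = j + d[1], i2 = i + d[2];
          if (k2 < 0 || k2 >= g.nz || j2 < 0 || j2 >= g.ny || i2 < 0 || i2 >= g.nx)
            continue;
          long l2 = g.at(k2, j2, i2);
          if (img[l2] > v || (img[l2] == v && l2 < l)) { peak = false; break; }
        }
        if (peak) peaks.push_back((int)l + 1);
      }
  return wrap(peaks);
}

// Union of digital balls: mark every voxel whose center lies within
// `radius` um of any bead center (centers in physical um, (z,y,x) order).
// [[Rcpp::export]]
LogicalVector cpp_stamp_balls(NumericMatrix centers, IntegerVector dims,
                              NumericVector spacing, double radius) {
  Grid g(dims);
  LogicalVector mask(g.n(), false);
  double r2 = radius * radius;
  for (int b = 0; b < centers.nrow(); ++b) {
    double cz = centers(b, 0), cy = centers(b, 1), cx = centers(b, 2);
    int k0 = std::max(0, (int)std::floor((cz - radius) / spacing[0]));
    int k1 = std::min(g.nz - 1, (int)std::ceil((cz + radius) / spacing[0]));
    int j0 = std::max(0, (int)std::floor((cy - radius) / spacing[1]));
    int j1 = std::min(g.ny - 1, (int)std::ceil((cy + radius) / spacing[1]));
    int i0 = std::max(0, (int)std::floor((cx - radius) / spacing[2]));
    int i1 = std::min(g.nx - 1, (int)std::ceil((cx + radius) / spacing[2]));
    for (int i = i0; i <= i1; ++i) {
      double dx = i * spacing[2] - cx;
      for (int j = j0; j <= j1; ++j) {
        double dy = j * spacing[1] - cy;
        for (int k = k0; k <= k1; ++k) {
          double dz = k * spacing[0] - cz;
          if (dz * dz + dy * dy + dx * dx <= r2) mask[g.at(k, j, i)] = true;
        }
      }
    }
  }
  mask.attr("dim") = dims;
  return mask;
}

// One-step binary dilation under 26-connectivity (used by the contact rule).
// [[Rcpp::export]]
LogicalVector cpp_dilate26(LogicalVector mask, IntegerVector dims) {
  Grid g(dims);
  std::vector<std::array<int,3>> off;
  neighbour_offsets(26, off);
  LogicalVector out(g.n(), false);
  for (int i = 0; i < g.nx; ++i)
    for (int j = 0; j < g.ny; ++j)
      for (int k = 0; k < g.nz; ++k) {
        long l = g.at(k, j, i);
        if (!mask[l]) continue;
        out[l] = true;
        for (auto& d : off) {
          int k2 = k + d[0], j2 = j + d[1], i2 = i + d[2];
          if (k2 < 0 || k2 >= g.nz || j2 < 0 || j2 >= g.ny || i2 < 0 || i2 >= g.nx)
            continue;
          out[g.at(k2, j2, i2)] = true;
        }
      }
  out.attr("dim") = dims;
  return out;
}

// Camera model in one pass: Poisson shot noise on the expected signal,
// Gaussian read noise, constant offset, clip to 16-bit and round. Uses R's
// RNG stream (caller seeds it).
// [[Rcpp::export]]
NumericVector cpp_camera_noise(NumericVector signal, double read_sd,
                               double background, bool shot) {
  long n = signal.size();
  NumericVector out(n);
  for (long l = 0; l < n; ++l) {
    double v = signal[l];
    if (shot) v = (v > 0) ? R::rpois(v) : 0.0;
    if (read_sd > 0) v += R::rnorm(0.0, read_sd);
    v += background;
    if (v < 0) v = 0;
    if (v > 65535) v = 65535;
    out[l] = (shot || read_sd > 0) ? std::floor(v + 0.5) : v;
  }
  out.attr("dim") = signal.attr("dim");
  return out;
}
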