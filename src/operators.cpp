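// Low-level pixel operators shared by the 2D and 3D segmentation pipelines.
// Arrays arrive in R's column-major layout; index = r + nr*(c + nc*z).
// "Reading order" throughout means lexicographic (row, col, slice).

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

static inline size_t lin(int r, int c, int z, int nr, int nc) {
  return (size_t)r + (size_t)nr * ((size_t)c + (size_t)nc * (size_t)z);
}

// Neighbourhood offsets in lexicographic (dr, dc, dz) order so that flooding
// and labelling are deterministic. connectivity: 4/8 (2D), 6/26 (3D).
static void neighbour_offsets(int connectivity, bool threeD,
                              std::vector<std::array<int, 3>>& off) {
  off.clear();
  if (!threeD) {
    for (int dr = -1; dr <= 1; ++dr)
      for (int dc = -1; dc <= 1; ++dc) {
        if (dr == 0 && dc == 0) continue;
        if (connectivity == 4 && std::abs(dr) + std::abs(dc) != 1) continue;
        off.push_back({dr, dc, 0});
      }
  } else {
    for (int dr = -1; dr <= 1; ++dr)
      for (int dc = -1; dc <= 1; ++dc)
        for (int dz = -1; dz <= 1; ++dz) {
          if (dr == 0 && dc == 0 && dz == 0) continue;
          if (connectivity == 6 &&
              std::abs(dr) + std::abs(dc) + std::abs(dz) != 1)
            continue;
          off.push_back({dr, dc, dz});
        }
  }
}

// Smallest d <= 1024 such that every x*d is integral and window sums of
// k^d values of x*d stay exactly representable in doubles; 0 if none.
// Camera images give d = 1; a 3x3 mean-filtered camera image gives d = 9.
static int integer_scale(const NumericVector& x, double nwin) {
  for (int d = 1; d <= 1024; ++d) {
    double mx = 0.0;
    bool ok = true;
    for (R_xlen_t i = 0; i < x.size(); ++i) {
      double v = x[i] * d;
      if (!R_finite(v) || v != std::floor(v)) { ok = false; break; }
      double a = std::fabs(v);
      if (a > mx) mx = a;
    }
    if (ok && mx * nwin < 9.0e15) return d;
    if (ok) return 0;  // integral but too large for exact sums
  }
  return 0;
}

// Box sum along one axis with edge replication (clamped indices).
// Window covers offsets -hlo..hhi; for odd k, hlo == hhi == (k-1)/2.
static void box_pass(std::vector<double>& a, int nr, int nc, int nz,
                     int axis, int hlo, int hhi) {
  std::vector<double> out(a.size());
  for (int z = 0; z < nz; ++z)
    for (int c = 0; c < nc; ++c)
      for (int r = 0; r < nr; ++r) {
        double s = 0.0;
        for (int d = -hlo; d <= hhi; ++d) {
          int rr = r, cc = c, zz = z;
          if (axis == 0) rr = clampi(r + d, 0, nr - 1);
          else if (axis == 1) cc = clampi(c + d, 0, nc - 1);
          else zz = clampi(z + d, 0, nz - 1);
          s += a[lin(rr, cc, zz, nr, nc)];
        }
        out[lin(r, c, z, nr, nc)] = s;
      }
  a.swap(out);
}

// Centered window statistic: acc(p) = sum over the window of (x_q - x_p).
// Exact zero for constant images, which a plain box sum cannot guarantee.
static void centered_acc(const NumericVector& x, int nr, int nc, int nz,
                         int hlo, int hhi, bool threeD,
                         std::vector<double>& acc) {
  acc.assign(x.size(), 0.0);
  int zlo = threeD ? -hlo : 0, zhi = threeD ? hhi : 0;
  for (int z = 0; z < nz; ++z)
    for (int c = 0; c < nc; ++c)
      for (int r = 0; r < nr; ++r) {
        double xp = x[lin(r, c, z, nr, nc)];
        double s = 0.0;
        for (int dz = zlo; dz <= zhi; ++dz) {
          int zz = clampi(z + dz, 0, nz - 1);
          for (int dc = -hlo; dc <= hhi; ++dc) {
            int cc = clampi(c + dc, 0, nc - 1);
            for (int dr = -hlo; dr <= hhi; ++dr) {
              int rr = clampi(r + dr, 0, nr - 1);
              s += x[lin(rr, cc, zz, nr, nc)] - xp;
            }
          }
        }
        acc[lin(r, c, z, nr, nc)] = s;
      }
}

// [[Rcpp::export]]
// Centered window sum of (x_q - x_p) for a single pixel (exact tie
// resolution and small-kernel fallback).
static double centered_one(const NumericVector& x, int nr, int nc, int nz,
                           int hlo, int hhi, bool threeD,
                           int r, int c, int z) {
  double xp = x[lin(r, c, z, nr, nc)];
  double s = 0.0;
  int zlo = threeD ? -hlo : 0, zhi = threeD ? hhi : 0;
  for (int dz = zlo; dz <= zhi; ++dz) {
    int zz = clampi(z + dz, 0, nz - 1);
    for (int dc = -hlo; dc <= hhi; ++dc) {
      int cc = clampi(c + dc, 0, nc - 1);
      for (int dr = -hlo; dr <= hhi; ++dr) {
        int rr = clampi(r + dr, 0, nr - 1);
        s += x[lin(rr, cc, zz, nr, nc)] - xp;
      }
    }
  }
  return s;
}

// [[Rcpp::export]]
NumericVector cpp_box_mean(NumericVector x, IntegerVector dims, int k) {
  int nr = dims[0], nc = dims[1], nz = dims.size() > 2 ? dims[2] : 1;
  bool threeD = dims.size() > 2;
  int hlo = k / 2, hhi = k - 1 - k / 2;
  double nwin = std::pow((double)k, threeD ? 3.0 : 2.0);
  NumericVector out(x.size());
  int d = integer_scale(x, nwin);
  if (d > 0) {
    std::vector<double> a(x.size());
    for (R_xlen_t i = 0; i < x.size(); ++i) a[i] = x[i] * d;
    box_pass(a, nr, nc, nz, 0, hlo, hhi);
    box_pass(a, nr, nc, nz, 1, hlo, hhi);
    if (threeD) box_pass(a, nr, nc, nz, 2, hlo, hhi);
    for (R_xlen_t i = 0; i < x.size(); ++i) out[i] = a[i] / nwin / d;
  } else {
    std::vector<double> acc;
    centered_acc(x, nr, nc, nz, hlo, hhi, threeD, acc);
    for (R_xlen_t i = 0; i < x.size(); ++i) out[i] = x[i] + acc[i] / nwin;
  }
  return out;
}

// [[Rcpp::export]]
LogicalVector cpp_box_mask(NumericVector x, IntegerVector dims, int k) {
  int nr = dims[0], nc = dims[1], nz = dims.size() > 2 ? dims[2] : 1;
  bool threeD = dims.size() > 2;
  int hlo = k / 2, hhi = k - 1 - k / 2;
  double nwin = std::pow((double)k, threeD ? 3.0 : 2.0);
  LogicalVector out(x.size());
  int d = integer_scale(x, nwin);
  if (d > 0) {
    // exact: rescaled values and their window sums are integers
    std::vector<double> a(x.size());
    for (R_xlen_t i = 0; i < x.size(); ++i) a[i] = x[i] * d;
    std::vector<double> s(a);
    box_pass(s, nr, nc, nz, 0, hlo, hhi);
    box_pass(s, nr, nc, nz, 1, hlo, hhi);
    if (threeD) box_pass(s, nr, nc, nz, 2, hlo, hhi);
    for (R_xlen_t i = 0; i < x.size(); ++i) out[i] = a[i] * nwin > s[i];
  } else {
    // sliding sums, then exact (centered) re-evaluation of the pixels
    // whose decision sits within rounding error of a tie
    std::vector<double> s(x.begin(), x.end());
    box_pass(s, nr, nc, nz, 0, hlo, hhi);
    box_pass(s, nr, nc, nz, 1, hlo, hhi);
    if (threeD) box_pass(s, nr, nc, nz, 2, hlo, hhi);
    const double eps = 1e-12;
    for (int z = 0; z < nz; ++z)
      for (int c = 0; c < nc; ++c)
        for (int r = 0; r < nr; ++r) {
          size_t i = lin(r, c, z, nr, nc);
          double D = x[i] * nwin - s[i];
          double scale = std::fabs(x[i]) * nwin + std::fabs(s[i]);
          if (std::fabs(D) <= eps * scale)
            D = -centered_one(x, nr, nc, nz, hlo, hhi, threeD, r, c, z);
          out[i] = D > 0.0;
        }
  }
  return out;
}

// Correlation along one axis with edge replication; kernels used here are
// symmetric, so this equals convolution.
// [[Rcpp::export]]
NumericVector cpp_convolve_axis(NumericVector x, IntegerVector dims,
                                NumericVector kernel, int axis) {
  int nr = dims[0], nc = dims[1], nz = dims.size() > 2 ? dims[2] : 1;
  int h = ((int)kernel.size() - 1) / 2;
  NumericVector out(x.size());
  for (int z = 0; z < nz; ++z)
    for (int c = 0; c < nc; ++c)
      for (int r = 0; r < nr; ++r) {
        double s = 0.0;
        for (int d = -h; d <= h; ++d) {
          int rr = r, cc = c, zz = z;
          if (axis == 0) rr = clampi(r + d, 0, nr - 1);
          else if (axis == 1) cc = clampi(c + d, 0, nc - 1);
          else zz = clampi(z + d, 0, nz - 1);
          s += kernel[d + h] * x[lin(rr, cc, zz, nr, nc)];
        }
        out[lin(r, c, z, nr, nc)] = s;
      }
  return out;
}

// Connected-component labelling; labels assigned in reading order of the
// first pixel of each component, so label 1 is the component whose first
// pixel comes first in (row, col, slice) order.
// [[Rcpp::export]]
IntegerVector cpp_label(LogicalVector mask, IntegerVector dims,
                        int connectivity) {
  int nr = dims[0], nc = dims[1], nz = dims.size() > 2 ? dims[2] : 1;
  bool threeD = dims.size() > 2;
  std::vector<std::array<int, 3>> off;
  neighbour_offsets(connectivity, threeD, off);
  IntegerVector labels(mask.size());
  std::vector<size_t> stack;
  int next = 0;
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c)
      for (int z = 0; z < nz; ++z) {
        size_t i = lin(r, c, z, nr, nc);
        if (!mask[i] || labels[i]) continue;
        ++next;
        labels[i] = next;
        stack.clear();
        stack.push_back(i);
        std::vector<std::array<int, 3>> coords;
        coords.push_back({r, c, z});
        while (!coords.empty()) {
          auto p = coords.back();
          coords.pop_back();
          for (auto& o : off) {
            int rr = p[0] + o[0], cc = p[1] + o[1], zz = p[2] + o[2];
            if (rr < 0 || rr >= nr || cc < 0 || cc >= nc || zz < 0 ||
                zz >= nz)
              continue;
            size_t j = lin(rr, cc, zz, nr, nc);
            if (mask[j] && !labels[j]) {
              labels[j] = next;
              coords.push_back({rr, cc, zz});
            }
          }
        }
      }
  return labels;
}

struct QE {
  double v;
  long long ord;
  size_t idx;
  int lab;
};
struct QEgt {
  bool operator()(const QE& a, const QE& b) const {
    if (a.v != b.v) return a.v > b.v;
    return a.ord > b.ord;
  }
};

// Seeded immersion watershed: flood the relief from the seed pixels, lower
// relief values first, ties broken by insertion order (seeds in list order,
// then neighbours in the order they were reached, pushed in reading-order
// offset sequence). Every reachable masked pixel is assigned to one seed.
// seeds: K x 3 matrix of 0-based (row, col, slice) coordinates.
// [[Rcpp::export]]
IntegerVector cpp_watershed(NumericVector relief, IntegerVector dims,
                            IntegerMatrix seeds, LogicalVector mask,
                            int connectivity) {
  int nr = dims[0], nc = dims[1], nz = dims.size() > 2 ? dims[2] : 1;
  bool threeD = dims.size() > 2;
  std::vector<std::array<int, 3>> off;
  neighbour_offsets(connectivity, threeD, off);
  IntegerVector labels(relief.size());
  std::priority_queue<QE, std::vector<QE>, QEgt> pq;
  long long ord = 0;
  for (int s = 0; s < seeds.nrow(); ++s) {
    size_t i = lin(seeds(s, 0), seeds(s, 1), seeds(s, 2), nr, nc);
    pq.push({relief[i], ord++, i, s + 1});
  }
  while (!pq.empty()) {
    QE e = pq.top();
    pq.pop();
    if (labels[e.idx]) continue;
    labels[e.idx] = e.lab;
    int z = (int)(e.idx / ((size_t)nr * nc));
    size_t rem = e.idx - (size_t)z * nr * nc;
    int c = (int)(rem / nr), r = (int)(rem % nr);
    for (auto& o : off) {
      int rr = r + o[0], cc = c + o[1], zz = z + o[2];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc || zz < 0 || zz >= nz)
        continue;
      size_t j = lin(rr, cc, zz, nr, nc);
      if (mask[j] && !labels[j]) pq.push({relief[j], ord++, j, e.lab});
    }
  }
  return labels;
}
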