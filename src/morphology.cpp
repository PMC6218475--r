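#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Sentinel for "no site on this line yet"; large enough to dominate any
// in-grid squared distance, small enough that parabola intersections stay
// finite in double arithmetic.
static const double DT_HUGE = 1e15;

// 1D squared-distance transform along a sampled line (Felzenszwalb &
// Huttenlocher lower envelope of parabolas). w2 is the squared sample
// spacing along this axis.
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n,
                 double w2) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s = 0.0;
    while (true) {
      int p = v[k];
      s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) / (2.0 * w2 * (q - p));
      if (s <= z[k]) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    int p = v[k];
    d[q] = w2 * (q - p) * (q - p) + f[p];
  }
}

// Exact squared Euclidean distance from every voxel to the nearest TRUE
// voxel of `site`, with per-axis sample spacing. Column-major (R) layout,
// dim = (n1, n2, n3). Voxels with no site anywhere get >= DT_HUGE.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector site, IntegerVector dim,
                         NumericVector spacing) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  if (site.size() != n) stop("site length does not match dim");
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = site[i] ? 0.0 : DT_HUGE;

  const double w1 = spacing[0] * spacing[0];
  const double w2 = spacing[1] * spacing[1];
  const double w3 = spacing[2] * spacing[2];

  std::vector<double> f(std::max(n1, std::max(n2, n3)));
  std::vector<double> d(f.size());

  // axis 1 (stride 1)
  for (int k = 0; k < n3; ++k) {
    for (int j = 0; j < n2; ++j) {
      const R_xlen_t base = (R_xlen_t)n1 * (j + (R_xlen_t)n2 * k);
      for (int i = 0; i < n1; ++i) f[i] = out[base + i];
      dt1d(f, d, n1, w1);
      for (int i = 0; i < n1; ++i) out[base + i] = d[i];
    }
  }
  // axis 2 (stride n1)
  for (int k = 0; k < n3; ++k) {
    for (int i = 0; i < n1; ++i) {
      const R_xlen_t base = i + (R_xlen_t)n1 * n2 * k;
      for (int j = 0; j < n2; ++j) f[j] = out[base + (R_xlen_t)n1 * j];
      dt1d(f, d, n2, w2);
      for (int j = 0; j < n2; ++j) out[base + (R_xlen_t)n1 * j] = d[j];
    }
  }
  // axis 3 (stride n1*n2)
  const R_xlen_t s3 = (R_xlen_t)n1 * n2;
  for (int j = 0; j < n2; ++j) {
    for (int i = 0; i < n1; ++i) {
      const R_xlen_t base = i + (R_xlen_t)n1 * j;
      for (int k = 0; k < n3; ++k) f[k] = out[base + s3 * k];
      dt1d(f, d, n3, w3);
      for (int k = 0; k < n3; ++k) out[base + s3 * k] = d[k];
    }
  }
  return out;
}

// Fill background components not connected to the volume border
// (6-connected background flood fill from all border background voxels).
// [[Rcpp::export]]
LogicalVector cpp_fill_holes(LogicalVector mask, IntegerVector dim) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  if (mask.size() != n) stop("mask length does not match dim");
  std::vector<char> reach(n, 0);
  std::vector<R_xlen_t> stack;
  stack.reserve(1024);

  const R_xlen_t s2 = n1, s3 = (R_xlen_t)n1 * n2;
  // seed with all background voxels on the border
  for (int k = 0; k < n3; ++k) {
    for (int j = 0; j < n2; ++j) {
      for (int i = 0; i < n1; ++i) {
        if (i == 0 || i == n1 - 1 || j == 0 || j == n2 - 1 || k == 0 ||
            k == n3 - 1) {
          R_xlen_t idx = i + s2 * j + s3 * k;
          if (!mask[idx] && !reach[idx]) {
            reach[idx] = 1;
            stack.push_back(idx);
          }
        }
      }
    }
  }
  while (!stack.empty()) {
    R_xlen_t idx = stack.back();
    stack.pop_back();
    int k = (int)(idx / s3);
    R_xlen_t rem = idx % s3;
    int j = (int)(rem / s2);
    int i = (int)(rem % s2);
    const int di[6] = {-1, 1, 0, 0, 0, 0};
    const int dj[6] = {0, 0, -1, 1, 0, 0};
    const int dk[6] = {0, 0, 0, 0, -1, 1};
    for (int t = 0; t < 6; ++t) {
      int ii = i + di[t], jj = j + dj[t], kk = k + dk[t];
      if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 || kk < 0 || kk >= n3)
        continue;
      R_xlen_t nb = ii + s2 * jj + s3 * kk;
      if (!mask[nb] && !reach[nb]) {
        reach[nb] = 1;
        stack.push_back(nb);
      }
    }
  }
  LogicalVector out(n);
  for (R_xlen_t idx = 0; idx < n; ++idx)
    out[idx] = mask[idx] || !reach[idx];
  return out;
}

// Connected-component labeling of TRUE voxels (connectivity 6 or 26).
// Labels are assigned in column-major scan order of first encounter,
// starting at 1; background stays 0.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  if (mask.size() != n) stop("mask length does not match dim");
  if (connectivity != 6 && connectivity != 26)
    stop("connectivity must be 6 or 26");

  std::vector<int> off_i, off_j, off_k;
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        if (di == 0 && dj == 0 && dk == 0) continue;
        int l1 = std::abs(di) + std::abs(dj) + std::abs(dk);
        if (connectivity == 6 && l1 != 1) continue;
        off_i.push_back(di);
        off_j.push_back(dj);
        off_k.push_back(dk);
      }

  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  const R_xlen_t s2 = n1, s3 = (R_xlen_t)n1 * n2;
  int next = 0;
  for (R_xlen_t idx = 0; idx < n; ++idx) {
    if (!mask[idx] || lab[idx] != 0) continue;
    ++next;
    lab[idx] = next;
    stack.push_back(idx);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int k = (int)(cur / s3);
      R_xlen_t rem = cur % s3;
      int j = (int)(rem / s2);
      int i = (int)(rem % s2);
      for (size_t t = 0; t < off_i.size(); ++t) {
        int ii = i + off_i[t], jj = j + off_j[t], kk = k + off_k[t];
        if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 || kk < 0 || kk >= n3)
          continue;
        R_xlen_t nb = ii + s2 * jj + s3 * kk;
        if (mask[nb] && lab[nb] == 0) {
          lab[nb] = next;
          stack.push_back(nb);
        }
      }
    }
  }
  return lab;
}
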