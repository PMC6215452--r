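// 3D rank/mean filters with ball (3D) or disc (2D) windows and edge
// replication, plus 26-connected component extraction. All grids are R
// arrays in column-major order with dims (d1, d2, d3) = (slice, row, col).
#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <queue>
using namespace Rcpp;

struct Offsets {
  std::vector<int> di, dj, dk;
};

// Discrete ball of given integer radius; dim2d selects a disc in the plane
// perpendicular to axis `axis2d` (1-based array axis), 0 for a full ball.
static Offsets make_window(int radius, int axis2d) {
  Offsets o;
  for (int a = -radius; a <= radius; ++a)
    for (int b = -radius; b <= radius; ++b)
      for (int c = -radius; c <= radius; ++c) {
        if (axis2d == 1 && a != 0) continue;
        if (axis2d == 2 && b != 0) continue;
        if (axis2d == 3 && c != 0) continue;
        if (a * a + b * b + c * c <= radius * radius) {
          o.di.push_back(a); o.dj.push_back(b); o.dk.push_back(c);
        }
      }
  return o;
}

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

static NumericVector rank_filter(const NumericVector& vol, int radius,
                                 int axis2d, int mode) {
  IntegerVector dm = vol.attr("dim");
  const int d1 = dm[0], d2 = dm[1], d3 = dm[2];
  Offsets w = make_window(radius, axis2d);
  const int n = (int)w.di.size();
  NumericVector out(vol.size());
  out.attr("dim") = dm;
  std::vector<double> buf(n);
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i) {
        double mn = R_PosInf, mx = R_NegInf, sum = 0.0;
        for (int t = 0; t < n; ++t) {
          int ii = clampi(i + w.di[t], 0, d1 - 1);
          int jj = clampi(j + w.dj[t], 0, d2 - 1);
          int kk = clampi(k + w.dk[t], 0, d3 - 1);
          double v = vol[ii + (R_xlen_t)d1 * (jj + (R_xlen_t)d2 * kk)];
          if (mode == 0) buf[t] = v;
          else if (mode == 1) sum += v;
          else { if (v < mn) mn = v; if (v > mx) mx = v; }
        }
        R_xlen_t at = i + (R_xlen_t)d1 * (j + (R_xlen_t)d2 * k);
        if (mode == 0) {
          std::nth_element(buf.begin(), buf.begin() + n / 2, buf.end());
          double med = buf[n / 2];
          if (n % 2 == 0) {
            double lo = *std::max_element(buf.begin(), buf.begin() + n / 2);
            med = 0.5 * (lo + med);
          }
          out[at] = med;
        } else if (mode == 1) {
          out[at] = sum / n;
        } else {
          out[at] = (mode == 2) ? mn : mx;
        }
      }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_median_filter(NumericVector vol, int radius, int axis2d) {
  return rank_filter(vol, radius, axis2d, 0);
}

// [[Rcpp::export]]
NumericVector cpp_mean_filter(NumericVector vol, int radius) {
  return rank_filter(vol, radius, 0, 1);
}

// Local min and max over a ball window (for Bernsen thresholding).
// [[Rcpp::export]]
List cpp_minmax_filter(NumericVector vol, int radius) {
  return List::create(_["min"] = rank_filter(vol, radius, 0, 2),
                      _["max"] = rank_filter(vol, radius, 0, 3));
}

// Largest 26-connected foreground component; ties broken by the component
// first encountered in array scan order.
// [[Rcpp::export]]
LogicalVector cpp_largest_component(LogicalVector mask) {
  IntegerVector dm = mask.attr("dim");
  const int d1 = dm[0], d2 = dm[1], d3 = dm[2];
  const R_xlen_t N = mask.size();
  std::vector<int> label(N, 0);
  int best_label = 0, next = 0;
  R_xlen_t best_size = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < N; ++s) {
    if (!mask[s] || label[s]) continue;
    ++next;
    R_xlen_t size = 0;
    stack.clear();
    stack.push_back(s);
    label[s] = next;
    while (!stack.empty()) {
      R_xlen_t cur = stack.back(); stack.pop_back();
      ++size;
      int i = (int)(cur % d1);
      int j = (int)((cur / d1) % d2);
      int k = (int)(cur / ((R_xlen_t)d1 * d2));
      for (int a = -1; a <= 1; ++a)
        for (int b = -1; b <= 1; ++b)
          for (int c = -1; c <= 1; ++c) {
            if (!a && !b && !c) continue;
            int ii = i + a, jj = j + b, kk = k + c;
            if (ii < 0 || jj < 0 || kk < 0 || ii >= d1 || jj >= d2 || kk >= d3)
              continue;
            R_xlen_t q = ii + (R_xlen_t)d1 * (jj + (R_xlen_t)d2 * kk);
            if (mask[q] && !label[q]) {
              label[q] = next;
              stack.push_back(q);
            }
          }
    }
    if (size > best_size) { best_size = size; best_label = next; }
  }
  LogicalVector out(N);
  out.attr("dim") = dm;
  for (R_xlen_t s = 0; s < N; ++s) out[s] = (label[s] == best_label);
  return out;
}

// Separable Gaussian blur with edge replication, sigma in voxels per axis.
// [[Rcpp::export]]
NumericVector cpp_gaussian_blur(NumericVector vol, NumericVector sigma) {
  IntegerVector dm = vol.attr("dim");
  const int d[3] = { dm[0], dm[1], dm[2] };
  NumericVector cur = clone(vol);
  for (int ax = 0; ax < 3; ++ax) {
    double sg = sigma[ax];
    if (sg <= 0) continue;
    int r = (int)std::ceil(3.0 * sg);
    std::vector<double> kern(2 * r + 1);
    double s = 0;
    for (int t = -r; t <= r; ++t) {
      kern[t + r] = std::exp(-0.5 * t * t / (sg * sg));
      s += kern[t + r];
    }
    for (double& kv : kern) kv /= s;
    NumericVector nxt(cur.size());
    nxt.attr("dim") = dm;
    for (int k = 0; k < d[2]; ++k)
      for (int j = 0; j < d[1]; ++j)
        for (int i = 0; i < d[0]; ++i) {
          double acc = 0;
          for (int t = -r; t <= r; ++t) {
            int ii = i, jj = j, kk = k;
            if (ax == 0) ii = clampi(i + t, 0, d[0] - 1);
            else if (ax == 1) jj = clampi(j + t, 0, d[1] - 1);
            else kk = clampi(k + t, 0, d[2] - 1);
            acc += kern[t + r] *
              cur[ii + (R_xlen_t)d[0] * (jj + (R_xlen_t)d[1] * kk)];
          }
          nxt[i + (R_xlen_t)d[0] * (j + (R_xlen_t)d[1] * k)] = acc;
        }
    cur = nxt;
  }
  return cur;
}
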