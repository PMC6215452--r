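// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher lower
// envelope of parabolas, run separably per axis with anisotropic voxel
// spacing) and background local thickness by distance-ridge sphere drawing.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static void dt1d(std::vector<double>& f, double w2) {
  const int n = (int)f.size();
  std::vector<double> d(n);
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = -1;
  // build the lower envelope from finite parabolas only
  for (int q = 0; q < n; ++q) {
    if (!std::isfinite(f[q])) continue;
    if (k < 0) {
      k = 0; v[0] = q; z[0] = -INFINITY; z[1] = INFINITY;
      continue;
    }
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) / (2.0 * w2 * (q - p));
      if (k > 0 && s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INFINITY;
  }
  if (k < 0) return;                 // no finite source on this line
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = w2 * (q - v[k]) * (q - v[k]) + f[v[k]];
  }
  f = d;
}

// Squared Euclidean distance (mm^2) from every voxel to the nearest TRUE
// voxel of `mask`; spacing is per array axis in mm.
// [[Rcpp::export]]
NumericVector cpp_sq_edt(LogicalVector mask, NumericVector spacing) {
  IntegerVector dm = mask.attr("dim");
  const int d1 = dm[0], d2 = dm[1], d3 = dm[2];
  NumericVector out(mask.size());
  out.attr("dim") = dm;
  for (R_xlen_t s = 0; s < mask.size(); ++s)
    out[s] = mask[s] ? 0.0 : R_PosInf;
  std::vector<double> line;
  // axis 1
  line.resize(d1);
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j) {
      R_xlen_t base = (R_xlen_t)d1 * (j + (R_xlen_t)d2 * k);
      for (int i = 0; i < d1; ++i) line[i] = out[base + i];
      dt1d(line, spacing[0] * spacing[0]);
      for (int i = 0; i < d1; ++i) out[base + i] = line[i];
    }
  // axis 2
  line.resize(d2);
  for (int k = 0; k < d3; ++k)
    for (int i = 0; i < d1; ++i) {
      for (int j = 0; j < d2; ++j)
        line[j] = out[i + (R_xlen_t)d1 * (j + (R_xlen_t)d2 * k)];
      dt1d(line, spacing[1] * spacing[1]);
      for (int j = 0; j < d2; ++j)
        out[i + (R_xlen_t)d1 * (j + (R_xlen_t)d2 * k)] = line[j];
    }
  // axis 3
  line.resize(d3);
  for (int j = 0; j < d2; ++j)
    for (int i = 0; i < d1; ++i) {
      for (int k = 0; k < d3; ++k)
        line[k] = out[i + (R_xlen_t)d1 * (j + (R_xlen_t)d2 * k)];
      dt1d(line, spacing[2] * spacing[2]);
      for (int k = 0; k < d3; ++k)
        out[i + (R_xlen_t)d1 * (j + (R_xlen_t)d2 * k)] = line[k];
    }
  return out;
}

// Local thickness of the phase marked TRUE in `phase`: for each phase voxel,
// the diameter (mm) of the largest sphere that fits entirely within the
// phase and contains the voxel (Hildebrand-Ruegsegger definition). Computed
// from the EDT ridge by sphere drawing.
// [[Rcpp::export]]
NumericVector cpp_local_thickness(LogicalVector phase, NumericVector spacing) {
  IntegerVector dm = phase.attr("dim");
  const int d1 = dm[0], d2 = dm[1], d3 = dm[2];
  const R_xlen_t N = phase.size();
  LogicalVector other(N);
  other.attr("dim") = dm;
  for (R_xlen_t s = 0; s < N; ++s) other[s] = !phase[s];
  NumericVector sq = cpp_sq_edt(other, spacing);
  // half-voxel surface offset: the EDT measures to the nearest opposite-
  // phase voxel CENTRE; the phase boundary lies about half a voxel closer
  double half = 0.5 * std::min(spacing[0], std::min(spacing[1], spacing[2]));
  std::vector<double> rad(N);
  for (R_xlen_t s = 0; s < N; ++s)
    rad[s] = std::max(0.0, std::sqrt(sq[s]) - half);
  NumericVector th(N);
  th.attr("dim") = dm;
  // ridge: a voxel whose inscribed sphere is not contained in a neighbour's
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i) {
        R_xlen_t s = i + (R_xlen_t)d1 * (j + (R_xlen_t)d2 * k);
        if (!phase[s]) continue;
        double r = rad[s];
        bool ridge = true;
        for (int a = -1; a <= 1 && ridge; ++a)
          for (int b = -1; b <= 1 && ridge; ++b)
            for (int c = -1; c <= 1; ++c) {
              if (!a && !b && !c) continue;
              int ii = i + a, jj = j + b, kk = k + c;
              if (ii < 0 || jj < 0 || kk < 0 ||
                  ii >= d1 || jj >= d2 || kk >= d3) continue;
              double dd = std::sqrt(a * a * spacing[0] * spacing[0] +
                                    b * b * spacing[1] * spacing[1] +
                                    c * c * spacing[2] * spacing[2]);
              R_xlen_t q = ii + (R_xlen_t)d1 * (jj + (R_xlen_t)d2 * kk);
              if (rad[q] >= r + dd - 1e-9) { ridge = false; break; }
            }
        if (!ridge) continue;
        // paint the inscribed sphere with diameter 2r
        int ri = (int)std::floor(r / spacing[0]);
        int rj = (int)std::floor(r / spacing[1]);
        int rk = (int)std::floor(r / spacing[2]);
        for (int a = -ri; a <= ri; ++a)
          for (int b = -rj; b <= rj; ++b)
            for (int c = -rk; c <= rk; ++c) {
              int ii = i + a, jj = j + b, kk = k + c;
              if (ii < 0 || jj < 0 || kk < 0 ||
                  ii >= d1 || jj >= d2 || kk >= d3) continue;
              double dd2 = a * a * spacing[0] * spacing[0] +
                           b * b * spacing[1] * spacing[1] +
                           c * c * spacing[2] * spacing[2];
              if (dd2 > r * r) continue;
              R_xlen_t q = ii + (R_xlen_t)d1 * (jj + (R_xlen_t)d2 * kk);
              if (phase[q] && th[q] < 2.0 * r) th[q] = 2.0 * r;
            }
      }
  return th;
}
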