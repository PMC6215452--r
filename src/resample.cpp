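// 3D resampling by separable cubic convolution (Keys kernel, a = -0.5 —
// the interpolant behind "bicubic" in common image tools) or by nearest
// neighbour for binary masks. Voxel centre of index i sits at i * spacing
// in each axis (origin held fixed), so input coordinate = out_index / factor.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double cubic_w(double x) {
  const double a = -0.5;
  x = std::fabs(x);
  if (x < 1.0) return ((a + 2.0) * x - (a + 3.0)) * x * x + 1.0;
  if (x < 2.0) return ((a * x - 5.0 * a) * x + 8.0 * a) * x - 4.0 * a;
  return 0.0;
}

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// [[Rcpp::export]]
NumericVector cpp_resample(NumericVector vol, IntegerVector out_dim,
                           NumericVector factor, bool nearest) {
  IntegerVector dm = vol.attr("dim");
  const int d1 = dm[0], d2 = dm[1], d3 = dm[2];
  const int o1 = out_dim[0], o2 = out_dim[1], o3 = out_dim[2];
  NumericVector out((R_xlen_t)o1 * o2 * o3);
  out.attr("dim") = out_dim;
  for (int k = 0; k < o3; ++k) {
    double zc = k / factor[2];
    for (int j = 0; j < o2; ++j) {
      double yc = j / factor[1];
      for (int i = 0; i < o1; ++i) {
        double xc = i / factor[0];
        double val;
        if (nearest) {
          int ii = clampi((int)std::lround(xc), 0, d1 - 1);
          int jj = clampi((int)std::lround(yc), 0, d2 - 1);
          int kk = clampi((int)std::lround(zc), 0, d3 - 1);
          val = vol[ii + (R_xlen_t)d1 * (jj + (R_xlen_t)d2 * kk)];
        } else {
          int i0 = (int)std::floor(xc), j0 = (int)std::floor(yc),
              k0 = (int)std::floor(zc);
          val = 0.0;
          double wsum = 0.0;
          for (int ck = -1; ck <= 2; ++ck) {
            double wk = cubic_w(zc - (k0 + ck));
            if (wk == 0.0) continue;
            int kk = clampi(k0 + ck, 0, d3 - 1);
            for (int cj = -1; cj <= 2; ++cj) {
              double wj = cubic_w(yc - (j0 + cj));
              if (wj == 0.0) continue;
              int jj = clampi(j0 + cj, 0, d2 - 1);
              for (int ci = -1; ci <= 2; ++ci) {
                double wi = cubic_w(xc - (i0 + ci));
                if (wi == 0.0) continue;
                int ii = clampi(i0 + ci, 0, d1 - 1);
                double w = wi * wj * wk;
                val += w * vol[ii + (R_xlen_t)d1 * (jj + (R_xlen_t)d2 * kk)];
                wsum += w;
              }
            }
          }
          val /= wsum;
        }
        out[i + (R_xlen_t)o1 * (j + (R_xlen_t)o2 * k)] = val;
      }
    }
  }
  return out;
}
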