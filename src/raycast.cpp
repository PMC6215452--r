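// Directional sampling inside spherical VOIs: point-sampled star lengths
// (for the star volume distribution) and parallel-line mean intercept
// length, plus fast phantom fills. All coordinates here are in mm in ARRAY
// axis order (slice, row, col); position of voxel (i,j,k) is
// (i*sp1, j*sp2, k*sp3). R wrappers translate world xyz <-> array order.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline bool bone_at(const LogicalVector& grid, const int* d,
                           double p1, double p2, double p3,
                           const double* sp) {
  int i = (int)std::lround(p1 / sp[0]);
  int j = (int)std::lround(p2 / sp[1]);
  int k = (int)std::lround(p3 / sp[2]);
  if (i < 0 || j < 0 || k < 0 || i >= d[0] || j >= d[1] || k >= d[2])
    return false;
  return grid[i + (R_xlen_t)d[0] * (j + (R_xlen_t)d[1] * k)];
}

// For each direction, the mean intercept (star) length and mean cubed length
// over rays cast bidirectionally from each sampled bone point, censored at
// the VOI sphere boundary. Returns n_dirs x 3: meanL, meanL3, censored_frac.
// [[Rcpp::export]]
NumericMatrix cpp_star_sample(LogicalVector grid, NumericVector spacing,
                              NumericVector center, double radius,
                              NumericMatrix dirs, NumericMatrix points,
                              double step) {
  IntegerVector dm = grid.attr("dim");
  int d[3] = { dm[0], dm[1], dm[2] };
  double sp[3] = { spacing[0], spacing[1], spacing[2] };
  const int nd = dirs.nrow(), np = points.nrow();
  const double r2 = radius * radius;
  NumericMatrix out(nd, 3);
  for (int q = 0; q < nd; ++q) {
    double v1 = dirs(q, 0) * step, v2 = dirs(q, 1) * step,
           v3 = dirs(q, 2) * step;
    double sumL = 0, sumL3 = 0;
    int ncens = 0;
    for (int p = 0; p < np; ++p) {
      double p1 = points(p, 0), p2 = points(p, 1), p3 = points(p, 2);
      int steps = 0;
      bool cens = false;
      for (int sgn = -1; sgn <= 1; sgn += 2) {
        double c1 = p1, c2 = p2, c3 = p3;
        while (true) {
          c1 += sgn * v1; c2 += sgn * v2; c3 += sgn * v3;
          double e1 = c1 - center[0], e2 = c2 - center[1], e3 = c3 - center[2];
          if (e1 * e1 + e2 * e2 + e3 * e3 > r2) { cens = true; break; }
          if (!bone_at(grid, d, c1, c2, c3, sp)) break;
          ++steps;
        }
      }
      double L = (steps + 1) * step;
      sumL += L;
      sumL3 += L * L * L;
      if (cens) ++ncens;
    }
    out(q, 0) = sumL / np;
    out(q, 1) = sumL3 / np;
    out(q, 2) = (double)ncens / np;
  }
  return out;
}

// Parallel-line grid mean intercept length. Returns n_dirs x 4:
// total line length in VOI, number of bone/background crossings,
// bone length along lines, number of lines.
// [[Rcpp::export]]
NumericMatrix cpp_mil(LogicalVector grid, NumericVector spacing,
                      NumericVector center, double radius,
                      NumericMatrix dirs, double line_spacing, double step) {
  IntegerVector dm = grid.attr("dim");
  int d[3] = { dm[0], dm[1], dm[2] };
  double sp[3] = { spacing[0], spacing[1], spacing[2] };
  const int nd = dirs.nrow();
  NumericMatrix out(nd, 4);
  for (int q = 0; q < nd; ++q) {
    double u1 = dirs(q, 0), u2 = dirs(q, 1), u3 = dirs(q, 2);
    // orthonormal in-plane basis
    double a1, a2, a3;
    if (std::fabs(u1) < 0.9) { a1 = 1; a2 = 0; a3 = 0; }
    else { a1 = 0; a2 = 1; a3 = 0; }
    double p1 = u2 * a3 - u3 * a2, p2 = u3 * a1 - u1 * a3,
           p3 = u1 * a2 - u2 * a1;
    double pn = std::sqrt(p1 * p1 + p2 * p2 + p3 * p3);
    p1 /= pn; p2 /= pn; p3 /= pn;
    double q1 = u2 * p3 - u3 * p2, q2 = u3 * p1 - u1 * p3,
           q3 = u1 * p2 - u2 * p1;
    double tot = 0, bone = 0;
    int crossings = 0, nlines = 0;
    for (double a = -radius; a <= radius; a += line_spacing)
      for (double b = -radius; b <= radius; b += line_spacing) {
        double h2 = radius * radius - a * a - b * b;
        if (h2 <= 0) continue;
        double smax = std::sqrt(h2);
        ++nlines;
        double o1 = center[0] + a * p1 + b * q1,
               o2 = center[1] + a * p2 + b * q2,
               o3 = center[2] + a * p3 + b * q3;
        std::vector<char> ph;
        for (double s = -smax + 0.5 * step; s < smax; s += step)
          ph.push_back(bone_at(grid, d, o1 + s * u1, o2 + s * u2,
                               o3 + s * u3, sp));
        // median-of-3 debounce: single-sample spikes are staircase
        // artefacts of oblique rays on voxel surfaces, not interfaces
        const int m = (int)ph.size();
        std::vector<char> cl(ph);
        for (int t = 1; t + 1 < m; ++t)
          cl[t] = (ph[t - 1] + ph[t] + ph[t + 1]) >= 2;
        for (int t = 0; t < m; ++t) {
          tot += step;
          if (cl[t]) bone += step;
          if (t > 0 && cl[t] != cl[t - 1]) ++crossings;
        }
      }
    out(q, 0) = tot;
    out(q, 1) = crossings;
    out(q, 2) = bone;
    out(q, 3) = nlines;
  }
  return out;
}

// Fill a grid with parallel cylindrical rods: rod axes run along direction
// `axis`; rod centres sit on a jittered square lattice in the (p,q) plane.
// jitter_u/jitter_v are indexed by lattice cell (ci - ci0 + 1, cj - cj0 + 1).
// [[Rcpp::export]]
LogicalVector cpp_fill_rods(IntegerVector dim, NumericVector spacing,
                            NumericVector p, NumericVector q,
                            double pitch, double radius,
                            int ci0, int cj0,
                            NumericMatrix jitter_u, NumericMatrix jitter_v) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  LogicalVector out((R_xlen_t)d1 * d2 * d3);
  out.attr("dim") = dim;
  const double r2 = radius * radius;
  const int nu = jitter_u.nrow(), nv = jitter_u.ncol();
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i) {
        double x1 = i * spacing[0], x2 = j * spacing[1], x3 = k * spacing[2];
        double u = x1 * p[0] + x2 * p[1] + x3 * p[2];
        double v = x1 * q[0] + x2 * q[1] + x3 * q[2];
        int cu = (int)std::lround(u / pitch), cv = (int)std::lround(v / pitch);
        bool bone = false;
        for (int a = -1; a <= 1 && !bone; ++a)
          for (int b = -1; b <= 1 && !bone; ++b) {
            int iu = cu + a - ci0, iv = cv + b - cj0;
            if (iu < 0 || iv < 0 || iu >= nu || iv >= nv) continue;
            double cuu = (cu + a) * pitch + jitter_u(iu, iv);
            double cvv = (cv + b) * pitch + jitter_v(iu, iv);
            double du = u - cuu, dv = v - cvv;
            if (du * du + dv * dv <= r2) bone = true;
          }
        if (bone)
          out[i + (R_xlen_t)d1 * (j + (R_xlen_t)d2 * k)] = true;
      }
  return out;
}

// Union of spheres added one at a time until the bone fraction reaches
// `target`. Returns the grid with attribute n_used (-1 if centres ran out).
// [[Rcpp::export]]
LogicalVector cpp_fill_spheres(IntegerVector dim, NumericVector spacing,
                               NumericMatrix centers, double radius,
                               double target) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const R_xlen_t N = (R_xlen_t)d1 * d2 * d3;
  LogicalVector out(N);
  out.attr("dim") = dim;
  R_xlen_t nbone = 0;
  const double r2 = radius * radius;
  int used = 0;
  bool reached = false;
  for (int s = 0; s < centers.nrow(); ++s) {
    double c1 = centers(s, 0), c2 = centers(s, 1), c3 = centers(s, 2);
    int i0 = std::max(0, (int)std::floor((c1 - radius) / spacing[0]));
    int i1 = std::min(d1 - 1, (int)std::ceil((c1 + radius) / spacing[0]));
    int j0 = std::max(0, (int)std::floor((c2 - radius) / spacing[1]));
    int j1 = std::min(d2 - 1, (int)std::ceil((c2 + radius) / spacing[1]));
    int k0 = std::max(0, (int)std::floor((c3 - radius) / spacing[2]));
    int k1 = std::min(d3 - 1, (int)std::ceil((c3 + radius) / spacing[2]));
    for (int k = k0; k <= k1; ++k)
      for (int j = j0; j <= j1; ++j)
        for (int i = i0; i <= i1; ++i) {
          double e1 = i * spacing[0] - c1, e2 = j * spacing[1] - c2,
                 e3 = k * spacing[2] - c3;
          if (e1 * e1 + e2 * e2 + e3 * e3 > r2) continue;
          R_xlen_t at = i + (R_xlen_t)d1 * (j + (R_xlen_t)d2 * k);
          if (!out[at]) { out[at] = true; ++nbone; }
        }
    ++used;
    if ((double)nbone / N >= target) { reached = true; break; }
  }
  out.attr("n_used") = reached ? used : -1;
  return out;
}
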