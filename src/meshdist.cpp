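// Unsigned point-to-triangle-mesh distance.
// Closest point on a triangle follows the standard Voronoi-region
// decomposition (vertex / edge / face cases); per-query triangle loop is
// pruned with axis-aligned bounding boxes against the running best.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

namespace {

inline double clamp01(double x) { return x < 0 ? 0 : (x > 1 ? 1 : x); }

// squared distance from p to triangle (a, b, c)
double triDist2(const double* p, const double* a,
                const double* b, const double* c) {
  double ab[3], ac[3], ap[3];
  for (int k = 0; k < 3; ++k) {
    ab[k] = b[k] - a[k];
    ac[k] = c[k] - a[k];
    ap[k] = p[k] - a[k];
  }
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  double u = 0, v = 0;  // barycentric coords of closest point (b and c weights)
  if (d1 <= 0 && d2 <= 0) {
    u = 0; v = 0;                                  // vertex a
  } else {
    double bp[3], cp[3];
    for (int k = 0; k < 3; ++k) { bp[k] = p[k] - b[k]; cp[k] = p[k] - c[k]; }
    double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
    double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
    if (d3 >= 0 && d4 <= d3) {
      u = 1; v = 0;                                // vertex b
    } else {
      double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
      double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
      if (d6 >= 0 && d5 <= d6) {
        u = 0; v = 1;                              // vertex c
      } else {
        double vc = d1 * d4 - d3 * d2;
        if (vc <= 0 && d1 >= 0 && d3 <= 0) {
          u = clamp01(d1 / (d1 - d3)); v = 0;      // edge ab
        } else {
          double vb = d5 * d2 - d1 * d6;
          if (vb <= 0 && d2 >= 0 && d6 <= 0) {
            u = 0; v = clamp01(d2 / (d2 - d6));    // edge ac
          } else {
            double va = d3 * d6 - d5 * d4;
            if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
              u = clamp01((d4 - d3) / ((d4 - d3) + (d5 - d6)));  // edge bc
              v = 1 - u;
            } else {
              double denom = va + vb + vc;         // interior
              u = vb / denom;
              v = vc / denom;
            }
          }
        }
      }
    }
  }
  double dx = 0;
  double q[3];
  for (int k = 0; k < 3; ++k) {
    q[k] = a[k] + u * ab[k] + v * ac[k];
    double d = p[k] - q[k];
    dx += d * d;
  }
  return dx;
}

}  // namespace

// [[Rcpp::export(name = ".point_mesh_distance")]]
NumericVector point_mesh_distance(NumericMatrix pts, NumericMatrix verts,
                                  IntegerMatrix faces) {
  int np = pts.nrow(), nf = faces.nrow();
  if (nf < 1) stop("mesh has no faces");
  // triangle vertex coordinates and AABBs, flattened
  std::vector<double> tv(9 * (size_t)nf), lo(3 * (size_t)nf), hi(3 * (size_t)nf);
  for (int f = 0; f < nf; ++f) {
    for (int j = 0; j < 3; ++j) {
      int vi = faces(f, j) - 1;  // 1-based from R
      for (int k = 0; k < 3; ++k) tv[9 * f + 3 * j + k] = verts(vi, k);
    }
    for (int k = 0; k < 3; ++k) {
      double a = tv[9 * f + k], b = tv[9 * f + 3 + k], c = tv[9 * f + 6 + k];
      lo[3 * f + k] = std::min(a, std::min(b, c));
      hi[3 * f + k] = std::max(a, std::max(b, c));
    }
  }
  NumericVector out(np);
  double p[3];
  for (int i = 0; i < np; ++i) {
    p[0] = pts(i, 0); p[1] = pts(i, 1); p[2] = pts(i, 2);
    double best = std::numeric_limits<double>::infinity();
    for (int f = 0; f < nf; ++f) {
      // lower bound: squared distance to the triangle's AABB
      double lb = 0;
      for (int k = 0; k < 3; ++k) {
        double d = 0;
        if (p[k] < lo[3 * f + k]) d = lo[3 * f + k] - p[k];
        else if (p[k] > hi[3 * f + k]) d = p[k] - hi[3 * f + k];
        lb += d * d;
      }
      if (lb >= best) continue;
      double d2 = triDist2(p, &tv[9 * f], &tv[9 * f + 3], &tv[9 * f + 6]);
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
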