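#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Closest point on triangle (a,b,c) to p. Ericson, Real-Time Collision Detection.
static inline void closest_on_triangle(const double *p, const double *a,
                                       const double *b, const double *c,
                                       double *out) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) {
    ab[i] = b[i] - a[i];
    ac[i] = c[i] - a[i];
    ap[i] = p[i] - a[i];
  }
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) { for (int i = 0; i < 3; ++i) out[i] = a[i]; return; }

  double bp[3];
  for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
  double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
  double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
  if (d3 >= 0.0 && d4 <= d3) { for (int i = 0; i < 3; ++i) out[i] = b[i]; return; }

  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + v * ab[i];
    return;
  }

  double cp[3];
  for (int i = 0; i < 3; ++i) cp[i] = p[i] - c[i];
  double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
  double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
  if (d6 >= 0.0 && d5 <= d6) { for (int i = 0; i < 3; ++i) out[i] = c[i]; return; }

  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + w * ac[i];
    return;
  }

  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int i = 0; i < 3; ++i) out[i] = b[i] + w * (c[i] - b[i]);
    return;
  }

  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int i = 0; i < 3; ++i) out[i] = a[i] + ab[i] * v + ac[i] * w;
}

// Exact minimum point-to-surface distance over all triangles (brute force).
// vertices: M x 3, faces: K x 3 (1-based indices), points: N x 3.
// [[Rcpp::export]]
List cpp_closest_surface(NumericMatrix points, NumericMatrix vertices,
                         IntegerMatrix faces) {
  const int n = points.nrow(), k = faces.nrow();
  NumericVector dist(n);
  NumericMatrix foot(n, 3);
  IntegerVector tri(n);

  std::vector<double> V(vertices.nrow() * 3);
  for (int i = 0; i < vertices.nrow(); ++i)
    for (int j = 0; j < 3; ++j) V[3 * i + j] = vertices(i, j);

  for (int i = 0; i < n; ++i) {
    double p[3] = {points(i, 0), points(i, 1), points(i, 2)};
    double best = R_PosInf, bestq[3] = {0, 0, 0};
    int besttri = -1;
    double q[3];
    for (int t = 0; t < k; ++t) {
      const double *a = &V[3 * (faces(t, 0) - 1)];
      const double *b = &V[3 * (faces(t, 1) - 1)];
      const double *c = &V[3 * (faces(t, 2) - 1)];
      closest_on_triangle(p, a, b, c, q);
      double dx = q[0] - p[0], dy = q[1] - p[1], dz = q[2] - p[2];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) {
        best = d2;
        bestq[0] = q[0]; bestq[1] = q[1]; bestq[2] = q[2];
        besttri = t;
      }
    }
    dist[i] = std::sqrt(best);
    foot(i, 0) = bestq[0]; foot(i, 1) = bestq[1]; foot(i, 2) = bestq[2];
    tri[i] = besttri + 1;
  }
  return List::create(_["distance"] = dist, _["foot"] = foot, _["triangle"] = tri);
}

// Generalized winding number of each point w.r.t. a closed oriented surface.
// ~1 inside, ~0 outside. Robust for watertight meshes.
// [[Rcpp::export]]
NumericVector cpp_winding_number(NumericMatrix points, NumericMatrix vertices,
                                 IntegerMatrix faces) {
  const int n = points.nrow(), k = faces.nrow();
  NumericVector w(n);
  for (int i = 0; i < n; ++i) {
    double px = points(i, 0), py = points(i, 1), pz = points(i, 2);
    double total = 0.0;
    for (int t = 0; t < k; ++t) {
      double ax = vertices(faces(t, 0) - 1, 0) - px;
      double ay = vertices(faces(t, 0) - 1, 1) - py;
      double az = vertices(faces(t, 0) - 1, 2) - pz;
      double bx = vertices(faces(t, 1) - 1, 0) - px;
      double by = vertices(faces(t, 1) - 1, 1) - py;
      double bz = vertices(faces(t, 1) - 1, 2) - pz;
      double cx = vertices(faces(t, 2) - 1, 0) - px;
      double cy = vertices(faces(t, 2) - 1, 1) - py;
      double cz = vertices(faces(t, 2) - 1, 2) - pz;
      double la = std::sqrt(ax * ax + ay * ay + az * az);
      double lb = std::sqrt(bx * bx + by * by + bz * bz);
      double lc = std::sqrt(cx * cx + cy * cy + cz * cz);
      // van Oosterom & Strackee signed solid angle
      double det = ax * (by * cz - bz * cy) - ay * (bx * cz - bz * cx) +
                   az * (bx * cy - by * cx);
      double denom = la * lb * lc +
                     (ax * bx + ay * by + az * bz) * lc +
                     (ax * cx + ay * cy + az * cz) * lb +
                     (bx * cx + by * cy + bz * cz) * la;
      total += 2.0 * std::atan2(det, denom);
    }
    w[i] = total / (4.0 * M_PI);
  }
  return w;
}

// Even-odd point-in-polygon for many points against one polygon (open repr.).
// [[Rcpp::export]]
LogicalVector cpp_points_in_polygon(NumericVector px, NumericVector py,
                                    NumericVector vx, NumericVector vy) {
  const int n = px.size(), m = vx.size();
  LogicalVector inside(n);
  for (int i = 0; i < n; ++i) {
    bool in = false;
    double x = px[i], y = py[i];
    for (int j = 0, k = m - 1; j < m; k = j++) {
      if (((vy[j] > y) != (vy[k] > y)) &&
          (x < (vx[k] - vx[j]) * (y - vy[j]) / (vy[k] - vy[j]) + vx[j]))
        in = !in;
    }
    inside[i] = in;
  }
  return inside;
}
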