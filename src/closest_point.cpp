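#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Closest point on triangle (a,b,c) to p, after Ericson, Real-Time Collision
// Detection, ch. 5.1.5.  Writes the foot point into out[3].
static inline void closest_pt_triangle(const double *p, const double *a,
                                       const double *b, const double *c,
                                       double *out) {
  double ab[3], ac[3], ap[3];
  for (int k = 0; k < 3; ++k) {
    ab[k] = b[k] - a[k];
    ac[k] = c[k] - a[k];
    ap[k] = p[k] - a[k];
  }
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) { // vertex region a
    for (int k = 0; k < 3; ++k) out[k] = a[k];
    return;
  }
  double bp[3];
  for (int k = 0; k < 3; ++k) bp[k] = p[k] - b[k];
  double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
  double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
  if (d3 >= 0.0 && d4 <= d3) { // vertex region b
    for (int k = 0; k < 3; ++k) out[k] = b[k];
    return;
  }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) { // edge ab
    double v = d1 / (d1 - d3);
    for (int k = 0; k < 3; ++k) out[k] = a[k] + v * ab[k];
    return;
  }
  double cp[3];
  for (int k = 0; k < 3; ++k) cp[k] = p[k] - c[k];
  double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
  double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
  if (d6 >= 0.0 && d5 <= d6) { // vertex region c
    for (int k = 0; k < 3; ++k) out[k] = c[k];
    return;
  }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) { // edge ac
    double w = d2 / (d2 - d6);
    for (int k = 0; k < 3; ++k) out[k] = a[k] + w * ac[k];
    return;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) { // edge bc
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int k = 0; k < 3; ++k) out[k] = b[k] + w * (c[k] - b[k]);
    return;
  }
  // interior
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int k = 0; k < 3; ++k) out[k] = a[k] + ab[k] * v + ac[k] * w;
}

// For each query point, exact closest point over all mesh triangles.
// V: n x 3 vertices, F: m x 3 one-based face indices, Q: q x 3 queries.
// A per-face bounding-sphere lower bound prunes most triangles.
// [[Rcpp::export]]
List cpp_mesh_closest(NumericMatrix Q, NumericMatrix V, IntegerMatrix F) {
  const int nq = Q.nrow(), nf = F.nrow();
  NumericVector dist(nq);
  NumericMatrix foot(nq, 3);
  IntegerVector face(nq);

  // face centroids and bounding radii
  std::vector<double> cx(nf), cy(nf), cz(nf), rad(nf);
  std::vector<int> ia(nf), ib(nf), ic(nf);
  for (int f = 0; f < nf; ++f) {
    ia[f] = F(f, 0) - 1; ib[f] = F(f, 1) - 1; ic[f] = F(f, 2) - 1;
    double ax = V(ia[f], 0), ay = V(ia[f], 1), az = V(ia[f], 2);
    double bx = V(ib[f], 0), by = V(ib[f], 1), bz = V(ib[f], 2);
    double gx = V(ic[f], 0), gy = V(ic[f], 1), gz = V(ic[f], 2);
    cx[f] = (ax + bx + gx) / 3.0;
    cy[f] = (ay + by + gy) / 3.0;
    cz[f] = (az + bz + gz) / 3.0;
    double r2 = 0.0, d2;
    d2 = (ax - cx[f]) * (ax - cx[f]) + (ay - cy[f]) * (ay - cy[f]) + (az - cz[f]) * (az - cz[f]);
    if (d2 > r2) r2 = d2;
    d2 = (bx - cx[f]) * (bx - cx[f]) + (by - cy[f]) * (by - cy[f]) + (bz - cz[f]) * (bz - cz[f]);
    if (d2 > r2) r2 = d2;
    d2 = (gx - cx[f]) * (gx - cx[f]) + (gy - cy[f]) * (gy - cy[f]) + (gz - cz[f]) * (gz - cz[f]);
    if (d2 > r2) r2 = d2;
    rad[f] = std::sqrt(r2);
  }

  double p[3], a[3], b[3], c[3], ft[3], best_ft[3];
  for (int i = 0; i < nq; ++i) {
    p[0] = Q(i, 0); p[1] = Q(i, 1); p[2] = Q(i, 2);
    double best = R_PosInf;
    int best_f = -1;
    for (int f = 0; f < nf; ++f) {
      double dx = p[0] - cx[f], dy = p[1] - cy[f], dz = p[2] - cz[f];
      double dc = std::sqrt(dx * dx + dy * dy + dz * dz) - rad[f];
      if (dc >= best) continue; // cannot beat current best
      a[0] = V(ia[f], 0); a[1] = V(ia[f], 1); a[2] = V(ia[f], 2);
      b[0] = V(ib[f], 0); b[1] = V(ib[f], 1); b[2] = V(ib[f], 2);
      c[0] = V(ic[f], 0); c[1] = V(ic[f], 1); c[2] = V(ic[f], 2);
      closest_pt_triangle(p, a, b, c, ft);
      dx = p[0] - ft[0]; dy = p[1] - ft[1]; dz = p[2] - ft[2];
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (d < best) {
        best = d;
        best_f = f;
        best_ft[0] = ft[0]; best_ft[1] = ft[1]; best_ft[2] = ft[2];
      }
    }
    dist[i] = best;
    face[i] = best_f + 1;
    foot(i, 0) = best_ft[0]; foot(i, 1) = best_ft[1]; foot(i, 2) = best_ft[2];
  }
  return List::create(_["distance"] = dist, _["footpoint"] = foot,
                      _["face"] = face);
}
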