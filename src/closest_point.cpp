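#include <Rcpp.h>
using namespace Rcpp;

// Closest point on triangle (a, b, c) to p — Ericson, Real-Time Collision
// Detection, section 5.1.5.
static inline void closest_on_triangle(const double* p, const double* a,
                                       const double* b, const double* c,
                                       double* out) {
  double ab[3], ac[3], ap[3];
  for (int k = 0; k < 3; ++k) {
    ab[k] = b[k] - a[k];
    ac[k] = c[k] - a[k];
    ap[k] = p[k] - a[k];
  }
  double d1 = ab[0]*ap[0] + ab[1]*ap[1] + ab[2]*ap[2];
  double d2 = ac[0]*ap[0] + ac[1]*ap[1] + ac[2]*ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) { for (int k = 0; k < 3; ++k) out[k] = a[k]; return; }

  double bp[3];
  for (int k = 0; k < 3; ++k) bp[k] = p[k] - b[k];
  double d3 = ab[0]*bp[0] + ab[1]*bp[1] + ab[2]*bp[2];
  double d4 = ac[0]*bp[0] + ac[1]*bp[1] + ac[2]*bp[2];
  if (d3 >= 0.0 && d4 <= d3) { for (int k = 0; k < 3; ++k) out[k] = b[k]; return; }

  double vc = d1*d4 - d3*d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    for (int k = 0; k < 3; ++k) out[k] = a[k] + v * ab[k];
    return;
  }

  double cp[3];
  for (int k = 0; k < 3; ++k) cp[k] = p[k] - c[k];
  double d5 = ab[0]*cp[0] + ab[1]*cp[1] + ab[2]*cp[2];
  double d6 = ac[0]*cp[0] + ac[1]*cp[1] + ac[2]*cp[2];
  if (d6 >= 0.0 && d5 <= d6) { for (int k = 0; k < 3; ++k) out[k] = c[k]; return; }

  double vb = d5*d2 - d1*d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    for (int k = 0; k < 3; ++k) out[k] = a[k] + w * ac[k];
    return;
  }

  double va = d3*d6 - d5*d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int k = 0; k < 3; ++k) out[k] = b[k] + w * (c[k] - b[k]);
    return;
  }

  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int k = 0; k < 3; ++k) out[k] = a[k] + ab[k] * v + ac[k] * w;
}

// For each query point, the nearest point on the triangulated surface
// (brute force over faces, with a vertex-distance lower-bound cull).
// [[Rcpp::export]]
List cpp_closest_on_mesh(NumericMatrix P, NumericMatrix V, IntegerMatrix F) {
  const int n = P.nrow(), nf = F.nrow();
  NumericMatrix out(n, 3);
  NumericVector dist(n);

  std::vector<double> fc(nf * 3), fr(nf);  // face centroids and bounding radii
  for (int f = 0; f < nf; ++f) {
    int ia = F(f, 0) - 1, ib = F(f, 1) - 1, ic = F(f, 2) - 1;
    double r2 = 0.0;
    for (int k = 0; k < 3; ++k)
      fc[f*3 + k] = (V(ia, k) + V(ib, k) + V(ic, k)) / 3.0;
    const int idx[3] = {ia, ib, ic};
    for (int j = 0; j < 3; ++j) {
      double d2 = 0.0;
      for (int k = 0; k < 3; ++k) {
        double d = V(idx[j], k) - fc[f*3 + k];
        d2 += d * d;
      }
      if (d2 > r2) r2 = d2;
    }
    fr[f] = std::sqrt(r2);
  }

  for (int i = 0; i < n; ++i) {
    double p[3] = {P(i, 0), P(i, 1), P(i, 2)};
    double best = R_PosInf, bestpt[3] = {0, 0, 0};
    for (int f = 0; f < nf; ++f) {
      double dc2 = 0.0;
      for (int k = 0; k < 3; ++k) {
        double d = p[k] - fc[f*3 + k];
        dc2 += d * d;
      }
      double lower = std::sqrt(dc2) - fr[f];
      if (lower > 0 && lower * lower >= best) continue;
      int ia = F(f, 0) - 1, ib = F(f, 1) - 1, ic = F(f, 2) - 1;
      double a[3] = {V(ia,0), V(ia,1), V(ia,2)};
      double b[3] = {V(ib,0), V(ib,1), V(ib,2)};
      double c[3] = {V(ic,0), V(ic,1), V(ic,2)};
      double q[3];
      closest_on_triangle(p, a, b, c, q);
      double d2 = 0.0;
      for (int k = 0; k < 3; ++k) {
        double d = p[k] - q[k];
        d2 += d * d;
      }
      if (d2 < best) {
        best = d2;
        for (int k = 0; k < 3; ++k) bestpt[k] = q[k];
      }
    }
    dist[i] = std::sqrt(best);
    for (int k = 0; k < 3; ++k) out(i, k) = bestpt[k];
  }
  return List::create(_["points"] = out, _["distance"] = dist);
}
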