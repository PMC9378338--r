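// Closest-point-on-triangle-mesh queries for registration.
// Brute-force over triangles is too slow for iterated nonrigid ICP, so a
// centroid lower bound prunes: exact point-triangle distance is evaluated
// only for triangles whose (centroid distance - circumradius) can beat the
// current best.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

// closest point on triangle (a,b,c) to p (Ericson, Real-Time Collision
// Detection, 5.1.5); returns squared distance, fills cp and bary.
static double closestPointTri(const double* p, const double* a,
                              const double* b, const double* c,
                              double* cp, double* bary) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) { ab[i] = b[i] - a[i]; ac[i] = c[i] - a[i]; ap[i] = p[i] - a[i]; }
  double d1 = dot3(ab, ap), d2 = dot3(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) {
    for (int i = 0; i < 3; ++i) cp[i] = a[i];
    bary[0] = 1; bary[1] = 0; bary[2] = 0;
  } else {
    double bp[3];
    for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
    double d3 = dot3(ab, bp), d4 = dot3(ac, bp);
    if (d3 >= 0.0 && d4 <= d3) {
      for (int i = 0; i < 3; ++i) cp[i] = b[i];
      bary[0] = 0; bary[1] = 1; bary[2] = 0;
    } else {
      double vc = d1 * d4 - d3 * d2;
      if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
        double v = d1 / (d1 - d3);
        for (int i = 0; i < 3; ++i) cp[i] = a[i] + v * ab[i];
        bary[0] = 1 - v; bary[1] = v; bary[2] = 0;
      } else {
        double cpv[3];
        for (int i = 0; i < 3; ++i) cpv[i] = p[i] - c[i];
        double d5 = dot3(ab, cpv), d6 = dot3(ac, cpv);
        if (d6 >= 0.0 && d5 <= d6) {
          for (int i = 0; i < 3; ++i) cp[i] = c[i];
          bary[0] = 0; bary[1] = 0; bary[2] = 1;
        } else {
          double vb = d5 * d2 - d1 * d6;
          if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
            double w = d2 / (d2 - d6);
            for (int i = 0; i < 3; ++i) cp[i] = a[i] + w * ac[i];
            bary[0] = 1 - w; bary[1] = 0; bary[2] = w;
          } else {
            double va = d3 * d6 - d5 * d4;
            if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
              double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
              for (int i = 0; i < 3; ++i) cp[i] = b[i] + w * (c[i] - b[i]);
              bary[0] = 0; bary[1] = 1 - w; bary[2] = w;
            } else {
              double denom = 1.0 / (va + vb + vc);
              double v = vb * denom, w = vc * denom;
              for (int i = 0; i < 3; ++i) cp[i] = a[i] + ab[i] * v + ac[i] * w;
              bary[0] = 1 - v - w; bary[1] = v; bary[2] = w;
            }
          }
        }
      }
    }
  }
  double d[3] = { p[0] - cp[0], p[1] - cp[1], p[2] - cp[2] };
  return dot3(d, d);
}

// [[Rcpp::export(name = ".closestOnMesh")]]
List closestOnMesh(NumericMatrix V, IntegerMatrix F, NumericMatrix Q) {
  const int m = F.nrow(), q = Q.nrow();
  std::vector<double> cx(m), cy(m), cz(m), rad(m);
  std::vector<double> tv(9 * m);
  for (int t = 0; t < m; ++t) {
    for (int k = 0; k < 3; ++k) {
      int vi = F(t, k) - 1;
      tv[9 * t + 3 * k + 0] = V(vi, 0);
      tv[9 * t + 3 * k + 1] = V(vi, 1);
      tv[9 * t + 3 * k + 2] = V(vi, 2);
    }
    cx[t] = (tv[9*t] + tv[9*t+3] + tv[9*t+6]) / 3.0;
    cy[t] = (tv[9*t+1] + tv[9*t+4] + tv[9*t+7]) / 3.0;
    cz[t] = (tv[9*t+2] + tv[9*t+5] + tv[9*t+8]) / 3.0;
    double r2 = 0;
    for (int k = 0; k < 3; ++k) {
      double dx = tv[9*t+3*k] - cx[t], dy = tv[9*t+3*k+1] - cy[t], dz = tv[9*t+3*k+2] - cz[t];
      double rr = dx*dx + dy*dy + dz*dz;
      if (rr > r2) r2 = rr;
    }
    rad[t] = std::sqrt(r2);
  }

  NumericMatrix P(q, 3), B(q, 3);
  NumericVector D(q);
  IntegerVector FI(q);
  double cp[3], bary[3];

  for (int i = 0; i < q; ++i) {
    double p[3] = { Q(i, 0), Q(i, 1), Q(i, 2) };
    // seed with the triangle of nearest centroid
    int seed = 0; double bestC = std::numeric_limits<double>::max();
    for (int t = 0; t < m; ++t) {
      double dx = p[0] - cx[t], dy = p[1] - cy[t], dz = p[2] - cz[t];
      double d2 = dx*dx + dy*dy + dz*dz;
      if (d2 < bestC) { bestC = d2; seed = t; }
    }
    double best = closestPointTri(p, &tv[9*seed], &tv[9*seed+3], &tv[9*seed+6], cp, bary);
    int bestT = seed;
    double bcp[3] = { cp[0], cp[1], cp[2] };
    double bb[3] = { bary[0], bary[1], bary[2] };
    double bestD = std::sqrt(best);
    for (int t = 0; t < m; ++t) {
      if (t == seed) continue;
      double dx = p[0] - cx[t], dy = p[1] - cy[t], dz = p[2] - cz[t];
      double lb = std::sqrt(dx*dx + dy*dy + dz*dz) - rad[t];
      if (lb >= bestD) continue;
      double d2 = closestPointTri(p, &tv[9*t], &tv[9*t+3], &tv[9*t+6], cp, bary);
      if (d2 < best) {
        best = d2; bestT = t; bestD = std::sqrt(best);
        for (int k = 0; k < 3; ++k) { bcp[k] = cp[k]; bb[k] = bary[k]; }
      }
    }
    for (int k = 0; k < 3; ++k) { P(i, k) = bcp[k]; B(i, k) = bb[k]; }
    D[i] = bestD;
    FI[i] = bestT + 1;
  }
  return List::create(_["point"] = P, _["dist"] = D,
                      _["face"] = FI, _["bary"] = B);
}

// [[Rcpp::export(name = ".nearestVertex")]]
List nearestVertex(NumericMatrix V, NumericMatrix Q) {
  const int n = V.nrow(), q = Q.nrow();
  IntegerVector idx(q);
  NumericVector dist(q);
  for (int i = 0; i < q; ++i) {
    double px = Q(i, 0), py = Q(i, 1), pz = Q(i, 2);
    double best = std::numeric_limits<double>::max();
    int bi = 0;
    for (int j = 0; j < n; ++j) {
      double dx = px - V(j, 0), dy = py - V(j, 1), dz = pz - V(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) { best = d2; bi = j; }
    }
    idx[i] = bi + 1;
    dist[i] = std::sqrt(best);
  }
  return List::create(_["index"] = idx, _["dist"] = dist);
}
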