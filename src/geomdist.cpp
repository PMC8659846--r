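#include <Rcpp.h>
#include <cfloat>
using namespace Rcpp;

// Closest point on triangle (a,b,c) to p; Ericson, Real-Time Collision
// Detection, ch. 5.1.5. Writes the foot point into out.
static inline double closest_on_tri(const double* p, const double* a,
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
  if (d1 <= 0.0 && d2 <= 0.0) {
    for (int k = 0; k < 3; ++k) out[k] = a[k];
  } else {
    double bp[3], cp[3];
    for (int k = 0; k < 3; ++k) { bp[k] = p[k] - b[k]; cp[k] = p[k] - c[k]; }
    double d3 = ab[0]*bp[0] + ab[1]*bp[1] + ab[2]*bp[2];
    double d4 = ac[0]*bp[0] + ac[1]*bp[1] + ac[2]*bp[2];
    double d5 = ab[0]*cp[0] + ab[1]*cp[1] + ab[2]*cp[2];
    double d6 = ac[0]*cp[0] + ac[1]*cp[1] + ac[2]*cp[2];
    if (d3 >= 0.0 && d4 <= d3) {
      for (int k = 0; k < 3; ++k) out[k] = b[k];
    } else if (d6 >= 0.0 && d5 <= d6) {
      for (int k = 0; k < 3; ++k) out[k] = c[k];
    } else {
      double vc = d1*d4 - d3*d2;
      if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
        double v = d1 / (d1 - d3);
        for (int k = 0; k < 3; ++k) out[k] = a[k] + v * ab[k];
      } else {
        double vb = d5*d2 - d1*d6;
        if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
          double w = d2 / (d2 - d6);
          for (int k = 0; k < 3; ++k) out[k] = a[k] + w * ac[k];
        } else {
          double va = d3*d6 - d5*d4;
          if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
            double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
            for (int k = 0; k < 3; ++k) out[k] = b[k] + w * (c[k] - b[k]);
          } else {
            double denom = 1.0 / (va + vb + vc);
            double v = vb * denom, w = vc * denom;
            for (int k = 0; k < 3; ++k) out[k] = a[k] + ab[k]*v + ac[k]*w;
          }
        }
      }
    }
  }
  double dx = p[0]-out[0], dy = p[1]-out[1], dz = p[2]-out[2];
  return dx*dx + dy*dy + dz*dz;
}

// [[Rcpp::export]]
List cpp_closest_on_mesh(NumericMatrix P, NumericMatrix V, IntegerMatrix F) {
  const int np = P.nrow(), nf = F.nrow();
  NumericMatrix foot(np, 3);
  NumericVector dist(np);
  IntegerVector face(np);
  std::vector<double> v(V.nrow() * 3), p(3), q(3), best(3);
  for (int i = 0; i < V.nrow(); ++i)
    for (int k = 0; k < 3; ++k) v[3*i + k] = V(i, k);
  for (int i = 0; i < np; ++i) {
    for (int k = 0; k < 3; ++k) p[k] = P(i, k);
    double bd = DBL_MAX; int bf = 0;
    for (int f = 0; f < nf; ++f) {
      const double* a = &v[3*(F(f,0)-1)];
      const double* b = &v[3*(F(f,1)-1)];
      const double* c = &v[3*(F(f,2)-1)];
      double d2 = closest_on_tri(p.data(), a, b, c, q.data());
      if (d2 < bd) { bd = d2; bf = f; best = q; }
    }
    for (int k = 0; k < 3; ++k) foot(i, k) = best[k];
    dist[i] = std::sqrt(bd);
    face[i] = bf + 1;
  }
  return List::create(_["points"] = foot, _["distance"] = dist,
                      _["face"] = face);
}

// Directed nearest-neighbour distances: for each row of A, the distance
// to the closest row of B (unsigned Euclidean). B is sorted on its x
// coordinate; the scan expands outward from the insertion point and
// stops once the x gap alone exceeds the best distance found.
// [[Rcpp::export]]
NumericVector cpp_nn_dist(NumericMatrix A, NumericMatrix B) {
  const int na = A.nrow(), nb = B.nrow();
  NumericVector out(na);
  std::vector<int> ord(nb);
  for (int j = 0; j < nb; ++j) ord[j] = j;
  std::sort(ord.begin(), ord.end(),
            [&](int i, int j) { return B(i, 0) < B(j, 0); });
  std::vector<double> bx(nb), by(nb), bz(nb);
  for (int j = 0; j < nb; ++j) {
    bx[j] = B(ord[j], 0); by[j] = B(ord[j], 1); bz[j] = B(ord[j], 2);
  }
  for (int i = 0; i < na; ++i) {
    const double x = A(i,0), y = A(i,1), z = A(i,2);
    int lo = (int)(std::lower_bound(bx.begin(), bx.end(), x) - bx.begin());
    int hi = lo;
    --lo;
    double bd = DBL_MAX;
    while (lo >= 0 || hi < nb) {
      const double dlo = (lo >= 0) ? x - bx[lo] : DBL_MAX;
      const double dhi = (hi < nb) ? bx[hi] - x : DBL_MAX;
      if (dlo <= dhi) {
        if (dlo * dlo > bd) { if (dhi * dhi > bd) break; }
        else {
          const double dy = y - by[lo], dz = z - bz[lo];
          const double d2 = dlo*dlo + dy*dy + dz*dz;
          if (d2 < bd) bd = d2;
        }
        --lo;
      } else {
        if (dhi * dhi > bd) { if (dlo * dlo > bd) break; }
        else {
          const double dy = y - by[hi], dz = z - bz[hi];
          const double d2 = dhi*dhi + dy*dy + dz*dz;
          if (d2 < bd) bd = d2;
        }
        ++hi;
      }
    }
    out[i] = std::sqrt(bd);
  }
  return out;
}
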