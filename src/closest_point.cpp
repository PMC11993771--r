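#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Closest point on triangle (a,b,c) to p, after Ericson,
// "Real-Time Collision Detection", ch. 5.1.5. Writes result into out[3].
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
  if (d1 <= 0.0 && d2 <= 0.0) {
    for (int i = 0; i < 3; ++i) out[i] = a[i];
    return;
  }
  double bp[3];
  for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
  double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
  double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
  if (d3 >= 0.0 && d4 <= d3) {
    for (int i = 0; i < 3; ++i) out[i] = b[i];
    return;
  }
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
  if (d6 >= 0.0 && d5 <= d6) {
    for (int i = 0; i < 3; ++i) out[i] = c[i];
    return;
  }
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

// For every query point, the nearest point on the triangle surface (V, F)
// and its unsigned distance. A uniform grid over triangle bounding boxes
// accelerates the search; queried cells expand in Chebyshev shells until
// no closer triangle can exist.
// [[Rcpp::export]]
List cpp_closest_on_mesh(NumericMatrix V, IntegerMatrix F, NumericMatrix Q) {
  const int nf = F.nrow(), nq = Q.nrow();
  if (nf < 1) stop("mesh has no faces");
  std::vector<double> ta(3 * nf), tb(3 * nf), tc(3 * nf);
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
  double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int f = 0; f < nf; ++f) {
    int i0 = F(f, 0) - 1, i1 = F(f, 1) - 1, i2 = F(f, 2) - 1;
    for (int k = 0; k < 3; ++k) {
      ta[3 * f + k] = V(i0, k);
      tb[3 * f + k] = V(i1, k);
      tc[3 * f + k] = V(i2, k);
      double mn = std::min(ta[3 * f + k],
                           std::min(tb[3 * f + k], tc[3 * f + k]));
      double mx = std::max(ta[3 * f + k],
                           std::max(tb[3 * f + k], tc[3 * f + k]));
      if (mn < lo[k]) lo[k] = mn;
      if (mx > hi[k]) hi[k] = mx;
    }
  }
  // grid resolution: about 2 triangles per cell on average, capped
  double ext[3];
  for (int k = 0; k < 3; ++k) ext[k] = std::max(hi[k] - lo[k], 1e-9);
  double vol = ext[0] * ext[1] * ext[2];
  double cell = std::cbrt(vol / std::max(nf / 2.0, 1.0));
  int dim[3];
  for (int k = 0; k < 3; ++k) {
    dim[k] = std::max(1, std::min(128, (int)std::ceil(ext[k] / cell)));
  }
  double step[3];
  for (int k = 0; k < 3; ++k) step[k] = ext[k] / dim[k];
  const int ncell = dim[0] * dim[1] * dim[2];
  std::vector<std::vector<int> > bins(ncell);
  for (int f = 0; f < nf; ++f) {
    int c0[3], c1[3];
    for (int k = 0; k < 3; ++k) {
      double mn = std::min(ta[3 * f + k],
                           std::min(tb[3 * f + k], tc[3 * f + k]));
      double mx = std::max(ta[3 * f + k],
                           std::max(tb[3 * f + k], tc[3 * f + k]));
      c0[k] = std::min(dim[k] - 1,
                       std::max(0, (int)((mn - lo[k]) / step[k])));
      c1[k] = std::min(dim[k] - 1,
                       std::max(0, (int)((mx - lo[k]) / step[k])));
    }
    for (int x = c0[0]; x <= c1[0]; ++x)
      for (int y = c0[1]; y <= c1[1]; ++y)
        for (int z = c0[2]; z <= c1[2]; ++z)
          bins[(x * dim[1] + y) * dim[2] + z].push_back(f);
  }
  // termination bound: smallest step among axes that actually have more
  // than one cell (a collapsed axis never advances the shell index)
  double min_step = R_PosInf;
  for (int k = 0; k < 3; ++k)
    if (dim[k] > 1 && step[k] < min_step) min_step = step[k];
  if (!R_FINITE(min_step)) min_step = R_PosInf;  // single-cell grid
  const int max_shell = dim[0] + dim[1] + dim[2] + 2;

  NumericMatrix P(nq, 3);
  NumericVector D(nq);
  IntegerVector FI(nq);
  std::vector<int> stamp(nf, -1);
  double q[3], out[3];
  for (int iq = 0; iq < nq; ++iq) {
    for (int k = 0; k < 3; ++k) q[k] = Q(iq, k);
    int qc[3];
    for (int k = 0; k < 3; ++k)
      qc[k] = std::min(dim[k] - 1,
                       std::max(0, (int)((q[k] - lo[k]) / step[k])));
    double bestd2 = R_PosInf;
    int bestf = -1;
    double bestp[3] = {0, 0, 0};
    for (int r = 0; r <= max_shell; ++r) {
      if (bestf >= 0) {
        double safe = (r - 1) * min_step;  // nearest possible new triangle
        if (safe > 0 && safe * safe > bestd2) break;
      }
      int x0 = std::max(0, qc[0] - r), x1 = std::min(dim[0] - 1, qc[0] + r);
      int y0 = std::max(0, qc[1] - r), y1 = std::min(dim[1] - 1, qc[1] + r);
      int z0 = std::max(0, qc[2] - r), z1 = std::min(dim[2] - 1, qc[2] + r);
      bool any_cell = false;
      for (int x = x0; x <= x1; ++x) {
        for (int y = y0; y <= y1; ++y) {
          for (int z = z0; z <= z1; ++z) {
            // only the shell surface (interior visited at smaller r)
            int cheb = std::max(std::abs(x - qc[0]),
                                std::max(std::abs(y - qc[1]),
                                         std::abs(z - qc[2])));
            if (cheb != r) continue;
            any_cell = true;
            const std::vector<int> &lst =
              bins[(x * dim[1] + y) * dim[2] + z];
            for (size_t t = 0; t < lst.size(); ++t) {
              int f = lst[t];
              if (stamp[f] == iq) continue;
              stamp[f] = iq;
              closest_on_triangle(q, &ta[3 * f], &tb[3 * f], &tc[3 * f],
                                  out);
              double d2 = 0.0;
              for (int k = 0; k < 3; ++k) {
                double d = q[k] - out[k];
                d2 += d * d;
              }
              if (d2 < bestd2) {
                bestd2 = d2;
                bestf = f;
                for (int k = 0; k < 3; ++k) bestp[k] = out[k];
              }
            }
          }
        }
      }
      if (!any_cell && r > 0 && x0 == 0 && y0 == 0 && z0 == 0 &&
          x1 == dim[0] - 1 && y1 == dim[1] - 1 && z1 == dim[2] - 1)
        break;  // grid exhausted
    }
    for (int k = 0; k < 3; ++k) P(iq, k) = bestp[k];
    D[iq] = std::sqrt(bestd2);
    FI[iq] = bestf + 1;
  }
  return List::create(Named("points") = P, Named("distance") = D,
                      Named("face") = FI);
}
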