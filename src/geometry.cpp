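#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Closest point on triangle (A,B,C) to P, after Ericson, "Real-Time
// Collision Detection", ch. 5. Writes the closest point into out[3].
static inline double closest_on_tri(const double *P,
                                    const double *A, const double *B,
                                    const double *C, double *out) {
  double ab[3], ac[3], ap[3];
  for (int k = 0; k < 3; ++k) {
    ab[k] = B[k] - A[k];
    ac[k] = C[k] - A[k];
    ap[k] = P[k] - A[k];
  }
  double d1 = ab[0]*ap[0] + ab[1]*ap[1] + ab[2]*ap[2];
  double d2 = ac[0]*ap[0] + ac[1]*ap[1] + ac[2]*ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) {
    for (int k = 0; k < 3; ++k) out[k] = A[k];
  } else {
    double bp[3];
    for (int k = 0; k < 3; ++k) bp[k] = P[k] - B[k];
    double d3 = ab[0]*bp[0] + ab[1]*bp[1] + ab[2]*bp[2];
    double d4 = ac[0]*bp[0] + ac[1]*bp[1] + ac[2]*bp[2];
    if (d3 >= 0.0 && d4 <= d3) {
      for (int k = 0; k < 3; ++k) out[k] = B[k];
    } else {
      double vc = d1*d4 - d3*d2;
      if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
        double v = d1 / (d1 - d3);
        for (int k = 0; k < 3; ++k) out[k] = A[k] + v*ab[k];
      } else {
        double cp[3];
        for (int k = 0; k < 3; ++k) cp[k] = P[k] - C[k];
        double d5 = ab[0]*cp[0] + ab[1]*cp[1] + ab[2]*cp[2];
        double d6 = ac[0]*cp[0] + ac[1]*cp[1] + ac[2]*cp[2];
        if (d6 >= 0.0 && d5 <= d6) {
          for (int k = 0; k < 3; ++k) out[k] = C[k];
        } else {
          double vb = d5*d2 - d1*d6;
          if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
            double w = d2 / (d2 - d6);
            for (int k = 0; k < 3; ++k) out[k] = A[k] + w*ac[k];
          } else {
            double va = d3*d6 - d5*d4;
            if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
              double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
              for (int k = 0; k < 3; ++k) out[k] = B[k] + w*(C[k] - B[k]);
            } else {
              double denom = 1.0 / (va + vb + vc);
              double v = vb * denom, w = vc * denom;
              for (int k = 0; k < 3; ++k) out[k] = A[k] + ab[k]*v + ac[k]*w;
            }
          }
        }
      }
    }
  }
  double dx = P[0]-out[0], dy = P[1]-out[1], dz = P[2]-out[2];
  return std::sqrt(dx*dx + dy*dy + dz*dz);
}

// For each query point, the nearest point on the triangulated surface
// (V: n x 3 vertices, F: m x 3 zero-based face indices).
// [[Rcpp::export]]
List cpp_closest_points(NumericMatrix V, IntegerMatrix F, NumericMatrix Q) {
  int m = F.nrow(), nq = Q.nrow();
  NumericVector dist(nq);
  IntegerVector face(nq);
  NumericMatrix pts(nq, 3);

  // Flatten, compute per-triangle centroid + bounding radius, and sort by
  // centroid z so queries can sweep outward from their own z and stop once
  // the z gap alone exceeds the best distance found.
  std::vector<double> tv(9 * (size_t)m), cen(3 * (size_t)m), rad(m), cz(m);
  std::vector<int> order(m);
  for (int j = 0; j < m; ++j) {
    for (int c = 0; c < 3; ++c) {
      int vi = F(j, c);
      tv[9*(size_t)j + 3*c + 0] = V(vi, 0);
      tv[9*(size_t)j + 3*c + 1] = V(vi, 1);
      tv[9*(size_t)j + 3*c + 2] = V(vi, 2);
    }
    const double *t = &tv[9*(size_t)j];
    for (int k = 0; k < 3; ++k)
      cen[3*(size_t)j + k] = (t[k] + t[3+k] + t[6+k]) / 3.0;
    double r2 = 0.0;
    for (int c = 0; c < 3; ++c) {
      double dx = t[3*c] - cen[3*(size_t)j],
             dy = t[3*c+1] - cen[3*(size_t)j+1],
             dz = t[3*c+2] - cen[3*(size_t)j+2];
      r2 = std::max(r2, dx*dx + dy*dy + dz*dz);
    }
    rad[j] = std::sqrt(r2);
    order[j] = j;
  }
  double rmax = *std::max_element(rad.begin(), rad.end());
  std::sort(order.begin(), order.end(),
            [&](int a, int b) { return cen[3*(size_t)a+2] < cen[3*(size_t)b+2]; });
  for (int k = 0; k < m; ++k) cz[k] = cen[3*(size_t)order[k]+2];

  double P[3], out[3], best_pt[3];
  for (int i = 0; i < nq; ++i) {
    P[0] = Q(i,0); P[1] = Q(i,1); P[2] = Q(i,2);
    double best = R_PosInf; int bestj = -1;
    int start = (int)(std::lower_bound(cz.begin(), cz.end(), P[2]) - cz.begin());
    int lo = start - 1, hi = start;
    while (lo >= 0 || hi < m) {
      int k;
      double dzlo = (lo >= 0) ? P[2] - cz[lo] : R_PosInf;
      double dzhi = (hi < m) ? cz[hi] - P[2] : R_PosInf;
      double dz = std::min(dzlo, dzhi);
      if (dz - rmax >= best) break;
      if (dzlo <= dzhi) { k = lo--; } else { k = hi++; }
      int j = order[k];
      double dx = P[0]-cen[3*(size_t)j], dy = P[1]-cen[3*(size_t)j+1],
             dzc = P[2]-cen[3*(size_t)j+2];
      if (std::sqrt(dx*dx + dy*dy + dzc*dzc) - rad[j] >= best) continue;
      const double *t = &tv[9*(size_t)j];
      double d = closest_on_tri(P, t, t+3, t+6, out);
      if (d < best) {
        best = d; bestj = j;
        best_pt[0] = out[0]; best_pt[1] = out[1]; best_pt[2] = out[2];
      }
    }
    dist[i] = best;
    face[i] = bestj + 1;
    pts(i,0) = best_pt[0]; pts(i,1) = best_pt[1]; pts(i,2) = best_pt[2];
  }
  return List::create(_["distance"] = dist, _["point"] = pts,
                      _["face"] = face);
}

// Silhouette area of the solid slice of a watertight mesh between two
// horizontal planes z in [zlo, zhi], projected along z. A pixel grid of
// step `pixel` covers [xlo, xlo + nx*pixel) x [ylo, ylo + ny*pixel); a pixel
// counts when the vertical line through its centre meets the solid inside
// the z interval. Solid membership along the line comes from the winding
// number of oriented triangle crossings, so no pre-clipping or capping of
// the slab is needed.
// [[Rcpp::export]]
int cpp_silhouette_count(NumericMatrix V, IntegerMatrix F,
                         double xlo, double ylo, int nx, int ny,
                         double pixel, double zlo, double zhi) {
  int m = F.nrow();
  // Per-triangle projected data.
  std::vector<double> ax(m), ay(m), bx(m), by(m), cx(m), cy(m),
      az(m), bz(m), cz(m), inv_den(m);
  std::vector<int> sgn(m);
  std::vector<double> bb(4 * (size_t)m);
  for (int j = 0; j < m; ++j) {
    int i0 = F(j,0), i1 = F(j,1), i2 = F(j,2);
    ax[j] = V(i0,0); ay[j] = V(i0,1); az[j] = V(i0,2);
    bx[j] = V(i1,0); by[j] = V(i1,1); bz[j] = V(i1,2);
    cx[j] = V(i2,0); cy[j] = V(i2,1); cz[j] = V(i2,2);
    double den = (bx[j]-ax[j])*(cy[j]-ay[j]) - (cx[j]-ax[j])*(by[j]-ay[j]);
    sgn[j] = (den > 0) - (den < 0);
    inv_den[j] = (sgn[j] != 0) ? 1.0 / den : 0.0;
    bb[4*(size_t)j+0] = std::min(ax[j], std::min(bx[j], cx[j]));
    bb[4*(size_t)j+1] = std::max(ax[j], std::max(bx[j], cx[j]));
    bb[4*(size_t)j+2] = std::min(ay[j], std::min(by[j], cy[j]));
    bb[4*(size_t)j+3] = std::max(ay[j], std::max(by[j], cy[j]));
  }

  // Coarse bins over the pixel grid for candidate lookup.
  const int cell_px = 16;
  int ncx = (nx + cell_px - 1) / cell_px;
  int ncy = (ny + cell_px - 1) / cell_px;
  double cell = cell_px * pixel;
  std::vector< std::vector<int> > bins((size_t)ncx * ncy);
  for (int j = 0; j < m; ++j) {
    if (sgn[j] == 0) continue;                  // vertical facet: no crossing
    int c0 = (int)std::floor((bb[4*(size_t)j+0] - xlo) / cell);
    int c1 = (int)std::floor((bb[4*(size_t)j+1] - xlo) / cell);
    int r0 = (int)std::floor((bb[4*(size_t)j+2] - ylo) / cell);
    int r1 = (int)std::floor((bb[4*(size_t)j+3] - ylo) / cell);
    c0 = std::max(c0, 0); r0 = std::max(r0, 0);
    c1 = std::min(c1, ncx - 1); r1 = std::min(r1, ncy - 1);
    for (int r = r0; r <= r1; ++r)
      for (int c = c0; c <= c1; ++c)
        bins[(size_t)r * ncx + c].push_back(j);
  }

  // Small deterministic offset keeps pixel centres off mesh edges.
  const double jit = 1e-4 * pixel;
  std::vector< std::pair<double,int> > hits;
  int count = 0;
  for (int iy = 0; iy < ny; ++iy) {
    double py = ylo + (iy + 0.5) * pixel + jit;
    int r = std::min(iy / cell_px, ncy - 1);
    for (int ix = 0; ix < nx; ++ix) {
      double px = xlo + (ix + 0.5) * pixel + jit;
      int c = std::min(ix / cell_px, ncx - 1);
      const std::vector<int> &cand = bins[(size_t)r * ncx + c];
      if (cand.empty()) continue;
      hits.clear();
      for (size_t k = 0; k < cand.size(); ++k) {
        int j = cand[k];
        if (px < bb[4*(size_t)j+0] || px > bb[4*(size_t)j+1] ||
            py < bb[4*(size_t)j+2] || py > bb[4*(size_t)j+3]) continue;
        // barycentric in the projection
        double u = ((px-ax[j])*(cy[j]-ay[j]) - (cx[j]-ax[j])*(py-ay[j])) * inv_den[j];
        double v = ((bx[j]-ax[j])*(py-ay[j]) - (px-ax[j])*(by[j]-ay[j])) * inv_den[j];
        if (u < 0.0 || v < 0.0 || u + v > 1.0) continue;
        double z = az[j] + u*(bz[j]-az[j]) + v*(cz[j]-az[j]);
        hits.push_back(std::make_pair(z, sgn[j]));
      }
      if (hits.size() < 2) continue;
      std::sort(hits.begin(), hits.end());
      // winding: upward ray enters the solid through downward-facing
      // (negative projected orientation) triangles
      int w = 0; double overlap = 0.0;
      for (size_t k = 0; k + 1 < hits.size(); ++k) {
        w += (hits[k].second < 0) ? 1 : -1;
        if (w > 0) {
          double lo = std::max(hits[k].first, zlo);
          double hi = std::min(hits[k+1].first, zhi);
          if (hi > lo) overlap += hi - lo;
        }
      }
      if (overlap > 1e-9) ++count;
    }
  }
  return count;
}

// Batched variant: silhouette pixel counts for every z interval
// [zlo[s], zhi[s]) in one sweep over a shared pixel grid. The per-pixel
// crossing list is computed once and tested against each interval.
// [[Rcpp::export]]
IntegerVector cpp_slab_counts(NumericMatrix V, IntegerMatrix F,
                              double xlo, double ylo, int nx, int ny,
                              double pixel,
                              NumericVector zlo, NumericVector zhi) {
  int m = F.nrow(), ns = zlo.size();
  std::vector<double> ax(m), ay(m), bx(m), by(m), cx(m), cy(m),
      az(m), bz(m), cz(m), inv_den(m);
  std::vector<int> sgn(m);
  std::vector<double> bb(4 * (size_t)m);
  for (int j = 0; j < m; ++j) {
    int i0 = F(j,0), i1 = F(j,1), i2 = F(j,2);
    ax[j] = V(i0,0); ay[j] = V(i0,1); az[j] = V(i0,2);
    bx[j] = V(i1,0); by[j] = V(i1,1); bz[j] = V(i1,2);
    cx[j] = V(i2,0); cy[j] = V(i2,1); cz[j] = V(i2,2);
    double den = (bx[j]-ax[j])*(cy[j]-ay[j]) - (cx[j]-ax[j])*(by[j]-ay[j]);
    sgn[j] = (den > 0) - (den < 0);
    inv_den[j] = (sgn[j] != 0) ? 1.0 / den : 0.0;
    bb[4*(size_t)j+0] = std::min(ax[j], std::min(bx[j], cx[j]));
    bb[4*(size_t)j+1] = std::max(ax[j], std::max(bx[j], cx[j]));
    bb[4*(size_t)j+2] = std::min(ay[j], std::min(by[j], cy[j]));
    bb[4*(size_t)j+3] = std::max(ay[j], std::max(by[j], cy[j]));
  }
  const int cell_px = 16;
  int ncx = (nx + cell_px - 1) / cell_px;
  int ncy = (ny + cell_px - 1) / cell_px;
  double cell = cell_px * pixel;
  std::vector< std::vector<int> > bins((size_t)ncx * ncy);
  for (int j = 0; j < m; ++j) {
    if (sgn[j] == 0) continue;
    int c0 = std::max((int)std::floor((bb[4*(size_t)j+0] - xlo) / cell), 0);
    int c1 = std::min((int)std::floor((bb[4*(size_t)j+1] - xlo) / cell), ncx - 1);
    int r0 = std::max((int)std::floor((bb[4*(size_t)j+2] - ylo) / cell), 0);
    int r1 = std::min((int)std::floor((bb[4*(size_t)j+3] - ylo) / cell), ncy - 1);
    for (int r = r0; r <= r1; ++r)
      for (int c = c0; c <= c1; ++c)
        bins[(size_t)r * ncx + c].push_back(j);
  }

  const double jit = 1e-4 * pixel;
  IntegerVector counts(ns);
  std::vector< std::pair<double,int> > hits;
  for (int iy = 0; iy < ny; ++iy) {
    double py = ylo + (iy + 0.5) * pixel + jit;
    int r = std::min(iy / cell_px, ncy - 1);
    for (int ix = 0; ix < nx; ++ix) {
      double px = xlo + (ix + 0.5) * pixel + jit;
      int c = std::min(ix / cell_px, ncx - 1);
      const std::vector<int> &cand = bins[(size_t)r * ncx + c];
      if (cand.empty()) continue;
      hits.clear();
      for (size_t k = 0; k < cand.size(); ++k) {
        int j = cand[k];
        if (px < bb[4*(size_t)j+0] || px > bb[4*(size_t)j+1] ||
            py < bb[4*(size_t)j+2] || py > bb[4*(size_t)j+3]) continue;
        double u = ((px-ax[j])*(cy[j]-ay[j]) - (cx[j]-ax[j])*(py-ay[j])) * inv_den[j];
        double v = ((bx[j]-ax[j])*(py-ay[j]) - (px-ax[j])*(by[j]-ay[j])) * inv_den[j];
        if (u < 0.0 || v < 0.0 || u + v > 1.0) continue;
        double z = az[j] + u*(bz[j]-az[j]) + v*(cz[j]-az[j]);
        hits.push_back(std::make_pair(z, sgn[j]));
      }
      if (hits.size() < 2) continue;
      std::sort(hits.begin(), hits.end());
      for (int s = 0; s < ns; ++s) {
        int w = 0; double overlap = 0.0;
        for (size_t k = 0; k + 1 < hits.size(); ++k) {
          w += (hits[k].second < 0) ? 1 : -1;
          if (w > 0) {
            double lo_ = std::max(hits[k].first, zlo[s]);
            double hi_ = std::min(hits[k+1].first, zhi[s]);
            if (hi_ > lo_) overlap += hi_ - lo_;
          }
        }
        if (overlap > 1e-9) ++counts[s];
      }
    }
  }
  return counts;
}
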