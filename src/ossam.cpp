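#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
using namespace Rcpp;

// ---- small vector helpers -------------------------------------------------

static inline void vsub(const double* a, const double* b, double* out) {
  out[0] = a[0] - b[0]; out[1] = a[1] - b[1]; out[2] = a[2] - b[2];
}
static inline double vdot(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline void vcross(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}

// Closest point on triangle (a,b,c) to p. Ericson, Real-Time Collision
// Detection, ch. 5.
static void closest_on_triangle(const double* p, const double* a,
                                const double* b, const double* c,
                                double* out) {
  double ab[3], ac[3], ap[3];
  vsub(b, a, ab); vsub(c, a, ac); vsub(p, a, ap);
  double d1 = vdot(ab, ap), d2 = vdot(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) { out[0]=a[0]; out[1]=a[1]; out[2]=a[2]; return; }
  double bp[3]; vsub(p, b, bp);
  double d3 = vdot(ab, bp), d4 = vdot(ac, bp);
  if (d3 >= 0.0 && d4 <= d3) { out[0]=b[0]; out[1]=b[1]; out[2]=b[2]; return; }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    for (int k = 0; k < 3; ++k) out[k] = a[k] + v * ab[k];
    return;
  }
  double cp[3]; vsub(p, c, cp);
  double d5 = vdot(ab, cp), d6 = vdot(ac, cp);
  if (d6 >= 0.0 && d5 <= d6) { out[0]=c[0]; out[1]=c[1]; out[2]=c[2]; return; }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    for (int k = 0; k < 3; ++k) out[k] = a[k] + w * ac[k];
    return;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int k = 0; k < 3; ++k) out[k] = b[k] + w * (c[k] - b[k]);
    return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int k = 0; k < 3; ++k) out[k] = a[k] + ab[k] * v + ac[k] * w;
}

// [[Rcpp::export]]
List cpp_closest_point_mesh(NumericMatrix P, NumericMatrix V,
                            IntegerMatrix Fm) {
  int np = P.nrow(), nt = Fm.nrow();
  NumericVector dist(np);
  NumericMatrix closest(np, 3);
  IntegerVector tri(np);
  // precompute triangle vertices and per-triangle bounding spheres
  std::vector<double> ta(3 * nt), tb(3 * nt), tc(3 * nt), ctr(3 * nt),
      rad(nt);
  for (int t = 0; t < nt; ++t) {
    int ia = Fm(t, 0) - 1, ib = Fm(t, 1) - 1, ic = Fm(t, 2) - 1;
    for (int k = 0; k < 3; ++k) {
      ta[3 * t + k] = V(ia, k);
      tb[3 * t + k] = V(ib, k);
      tc[3 * t + k] = V(ic, k);
      ctr[3 * t + k] = (V(ia, k) + V(ib, k) + V(ic, k)) / 3.0;
    }
    // bounding radius = max distance centroid->vertex
    double ra = 0, rb = 0, rc = 0;
    for (int k = 0; k < 3; ++k) {
      double da = ta[3*t+k]-ctr[3*t+k], db = tb[3*t+k]-ctr[3*t+k],
             dc = tc[3*t+k]-ctr[3*t+k];
      ra += da*da; rb += db*db; rc += dc*dc;
    }
    rad[t] = std::sqrt(std::max(ra, std::max(rb, rc)));
  }
  for (int i = 0; i < np; ++i) {
    double p[3] = {P(i, 0), P(i, 1), P(i, 2)};
    double best = R_PosInf, bestpt[3] = {0, 0, 0};
    int bestt = -1;
    for (int t = 0; t < nt; ++t) {
      // lower bound: distance to bounding sphere
      double dx = p[0]-ctr[3*t], dy = p[1]-ctr[3*t+1], dz = p[2]-ctr[3*t+2];
      double dc = std::sqrt(dx*dx + dy*dy + dz*dz) - rad[t];
      if (dc * dc >= best && dc > 0) continue;
      double q[3];
      closest_on_triangle(p, &ta[3 * t], &tb[3 * t], &tc[3 * t], q);
      double d2 = 0;
      for (int k = 0; k < 3; ++k) {
        double d = p[k] - q[k]; d2 += d * d;
      }
      if (d2 < best) {
        best = d2; bestt = t;
        bestpt[0] = q[0]; bestpt[1] = q[1]; bestpt[2] = q[2];
      }
    }
    dist[i] = std::sqrt(best);
    tri[i] = bestt + 1;
    for (int k = 0; k < 3; ++k) closest(i, k) = bestpt[k];
  }
  return List::create(_["dist"] = dist, _["closest"] = closest,
                      _["tri"] = tri);
}

// Ray-parity inside test, per labelled component: a point is inside the
// multi-component solid if it is inside (odd parity) any component.
// [[Rcpp::export]]
LogicalVector cpp_inside_mesh(NumericMatrix P, NumericMatrix V,
                              IntegerMatrix Fm, IntegerVector comp) {
  int np = P.nrow(), nt = Fm.nrow();
  int ncomp = 0;
  for (int t = 0; t < nt; ++t) ncomp = std::max(ncomp, comp[t]);
  // fixed irrational-ish ray direction to avoid edge/vertex hits
  double d[3] = {0.5377391, 0.3612783, 0.7613341};
  double nrm = std::sqrt(vdot(d, d));
  for (int k = 0; k < 3; ++k) d[k] /= nrm;
  LogicalVector inside(np);
  std::vector<int> par(ncomp);
  for (int i = 0; i < np; ++i) {
    double p[3] = {P(i, 0), P(i, 1), P(i, 2)};
    std::fill(par.begin(), par.end(), 0);
    for (int t = 0; t < nt; ++t) {
      const double a0[3] = {V(Fm(t,0)-1,0), V(Fm(t,0)-1,1), V(Fm(t,0)-1,2)};
      const double b0[3] = {V(Fm(t,1)-1,0), V(Fm(t,1)-1,1), V(Fm(t,1)-1,2)};
      const double c0[3] = {V(Fm(t,2)-1,0), V(Fm(t,2)-1,1), V(Fm(t,2)-1,2)};
      // Moller-Trumbore
      double e1[3], e2[3], pv[3], tv[3], qv[3];
      vsub(b0, a0, e1); vsub(c0, a0, e2);
      vcross(d, e2, pv);
      double det = vdot(e1, pv);
      if (std::fabs(det) < 1e-12) continue;
      double invdet = 1.0 / det;
      vsub(p, a0, tv);
      double u = vdot(tv, pv) * invdet;
      if (u < 0.0 || u > 1.0) continue;
      vcross(tv, e1, qv);
      double v = vdot(d, qv) * invdet;
      if (v < 0.0 || u + v > 1.0) continue;
      double tt = vdot(e2, qv) * invdet;
      if (tt > 1e-12) par[comp[t] - 1] ^= 1;
    }
    bool in = false;
    for (int c = 0; c < ncomp; ++c) if (par[c]) { in = true; break; }
    inside[i] = in;
  }
  return inside;
}

// Rasterize tetrahedra with per-cell values into a regular grid
// (nearest-containing-tet labelling; later tets do not overwrite).
// dims = c(nx, ny, nz); volume returned as vector, x fastest.
// [[Rcpp::export]]
NumericVector cpp_rasterize_tets(NumericMatrix nodes, IntegerMatrix tets,
                                 NumericVector values, NumericVector origin,
                                 NumericVector spacing, IntegerVector dims,
                                 double background) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector vol((R_xlen_t)nx * ny * nz, background);
  LogicalVector setv((R_xlen_t)nx * ny * nz, false);
  int nt = tets.nrow();
  for (int t = 0; t < nt; ++t) {
    double v0[3], v1[3], v2[3], v3[3];
    for (int k = 0; k < 3; ++k) {
      v0[k] = nodes(tets(t, 0) - 1, k);
      v1[k] = nodes(tets(t, 1) - 1, k);
      v2[k] = nodes(tets(t, 2) - 1, k);
      v3[k] = nodes(tets(t, 3) - 1, k);
    }
    double lo[3], hi[3];
    for (int k = 0; k < 3; ++k) {
      lo[k] = std::min(std::min(v0[k], v1[k]), std::min(v2[k], v3[k]));
      hi[k] = std::max(std::max(v0[k], v1[k]), std::max(v2[k], v3[k]));
    }
    int i0[3], i1[3];
    for (int k = 0; k < 3; ++k) {
      i0[k] = std::max(0, (int)std::ceil((lo[k] - origin[k]) / spacing[k] - 1e-9));
      i1[k] = std::min(dims[k] - 1,
                       (int)std::floor((hi[k] - origin[k]) / spacing[k] + 1e-9));
    }
    // barycentric matrix (columns v1-v0, v2-v0, v3-v0), inverted
    double m[9] = {v1[0]-v0[0], v2[0]-v0[0], v3[0]-v0[0],
                   v1[1]-v0[1], v2[1]-v0[1], v3[1]-v0[1],
                   v1[2]-v0[2], v2[2]-v0[2], v3[2]-v0[2]};
    double det = m[0]*(m[4]*m[8]-m[5]*m[7]) - m[1]*(m[3]*m[8]-m[5]*m[6])
               + m[2]*(m[3]*m[7]-m[4]*m[6]);
    if (std::fabs(det) < 1e-14) continue;
    double inv[9] = {
      (m[4]*m[8]-m[5]*m[7])/det, (m[2]*m[7]-m[1]*m[8])/det, (m[1]*m[5]-m[2]*m[4])/det,
      (m[5]*m[6]-m[3]*m[8])/det, (m[0]*m[8]-m[2]*m[6])/det, (m[2]*m[3]-m[0]*m[5])/det,
      (m[3]*m[7]-m[4]*m[6])/det, (m[1]*m[6]-m[0]*m[7])/det, (m[0]*m[4]-m[1]*m[3])/det};
    double val = values[t];
    for (int kz = i0[2]; kz <= i1[2]; ++kz) {
      double pz = origin[2] + kz * spacing[2] - v0[2];
      for (int ky = i0[1]; ky <= i1[1]; ++ky) {
        double py = origin[1] + ky * spacing[1] - v0[1];
        for (int kx = i0[0]; kx <= i1[0]; ++kx) {
          double px = origin[0] + kx * spacing[0] - v0[0];
          double b1 = inv[0]*px + inv[1]*py + inv[2]*pz;
          double b2 = inv[3]*px + inv[4]*py + inv[5]*pz;
          double b3 = inv[6]*px + inv[7]*py + inv[8]*pz;
          double b0 = 1.0 - b1 - b2 - b3;
          const double eps = -1e-9;
          if (b0 >= eps && b1 >= eps && b2 >= eps && b3 >= eps) {
            R_xlen_t idx = ((R_xlen_t)kz * ny + ky) * nx + kx;
            if (!setv[idx]) { vol[idx] = val; setv[idx] = true; }
          }
        }
      }
    }
  }
  return vol;
}

static inline double sample_nearest(const NumericVector& vol, int nx, int ny,
                                    int nz, const double* origin,
                                    const double* spacing, const double* p,
                                    double background) {
  int i = (int)std::floor((p[0] - origin[0]) / spacing[0] + 0.5);
  int j = (int)std::floor((p[1] - origin[1]) / spacing[1] + 0.5);
  int k = (int)std::floor((p[2] - origin[2]) / spacing[2] + 0.5);
  if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz)
    return background;
  return vol[((R_xlen_t)k * ny + j) * nx + i];
}

// Absorption-only DRR ray casting (parallel or perspective).
// Opacity transfer: op = clamp(op_scale * HU, 0, 1), HU <= 0 -> 0.
// Per sample alpha = clamp(op * step / step_ref, 0, 1); I = 1 - prod(1-alpha).
// [[Rcpp::export]]
NumericMatrix cpp_project_volume(NumericVector vol, IntegerVector dims,
                                 NumericVector spacing, NumericVector origin,
                                 NumericVector det_center, NumericVector uax,
                                 NumericVector vax, NumericVector raydir,
                                 NumericVector source, int nu, int nv,
                                 double pixel_spacing, bool perspective,
                                 double step, double step_ref,
                                 double op_scale, double background) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericMatrix img(nv, nu);
  double lo[3], hi[3];
  for (int k = 0; k < 3; ++k) {
    lo[k] = origin[k] - 0.5 * spacing[k];
    hi[k] = origin[k] + (dims[k] - 0.5) * spacing[k];
  }
  for (int r = 0; r < nv; ++r) {
    for (int c = 0; c < nu; ++c) {
      double pix[3], o[3], d[3];
      for (int k = 0; k < 3; ++k)
        pix[k] = det_center[k] + (c + 0.5 - nu / 2.0) * pixel_spacing * uax[k]
               + (r + 0.5 - nv / 2.0) * pixel_spacing * vax[k];
      if (perspective) {
        for (int k = 0; k < 3; ++k) { o[k] = source[k]; d[k] = pix[k] - source[k]; }
        double nrm = std::sqrt(vdot(d, d));
        for (int k = 0; k < 3; ++k) d[k] /= nrm;
      } else {
        for (int k = 0; k < 3; ++k) { o[k] = pix[k]; d[k] = raydir[k]; }
      }
      // slab clip of the infinite line o + t d to the volume box
      double t0 = R_NegInf, t1 = R_PosInf;
      bool miss = false;
      for (int k = 0; k < 3; ++k) {
        if (std::fabs(d[k]) < 1e-12) {
          if (o[k] < lo[k] || o[k] > hi[k]) { miss = true; break; }
        } else {
          double ta = (lo[k] - o[k]) / d[k], tb = (hi[k] - o[k]) / d[k];
          if (ta > tb) std::swap(ta, tb);
          t0 = std::max(t0, ta); t1 = std::min(t1, tb);
        }
      }
      if (miss || t1 <= t0) { img(r, c) = 0.0; continue; }
      double T = 1.0;
      int nstep = (int)std::ceil((t1 - t0) / step);
      for (int s = 0; s < nstep; ++s) {
        double t = t0 + (s + 0.5) * step;
        if (t > t1) break;
        double p[3] = {o[0] + t * d[0], o[1] + t * d[1], o[2] + t * d[2]};
        double hu = sample_nearest(vol, nx, ny, nz, origin.begin(),
                                   spacing.begin(), p, background);
        if (hu <= 0.0) continue;
        double op = op_scale * hu;
        if (op > 1.0) op = 1.0;
        double alpha = op * step / step_ref;
        if (alpha > 1.0) alpha = 1.0;
        T *= (1.0 - alpha);
      }
      img(r, c) = 1.0 - T;
    }
  }
  return img;
}

// Mean/all distances from 2D points to a (closed) polyline.
// [[Rcpp::export]]
NumericVector cpp_point_polyline_dist(NumericMatrix P, NumericMatrix poly,
                                      bool closed) {
  int np = P.nrow(), m = poly.nrow();
  int nseg = closed ? m : m - 1;
  NumericVector out(np);
  for (int i = 0; i < np; ++i) {
    double px = P(i, 0), py = P(i, 1), best = R_PosInf;
    for (int s = 0; s < nseg; ++s) {
      int s2 = (s + 1) % m;
      double ax = poly(s, 0), ay = poly(s, 1);
      double bx = poly(s2, 0), by = poly(s2, 1);
      double abx = bx - ax, aby = by - ay;
      double len2 = abx * abx + aby * aby;
      double t = len2 > 0 ? ((px - ax) * abx + (py - ay) * aby) / len2 : 0.0;
      if (t < 0) t = 0; else if (t > 1) t = 1;
      double dx = px - (ax + t * abx), dy = py - (ay + t * aby);
      double d2 = dx * dx + dy * dy;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Nearest neighbour among 2D points: for each row of P, index of the
// closest row of Q and the distance.
// [[Rcpp::export]]
List cpp_nn_points(NumericMatrix P, NumericMatrix Q) {
  int n = P.nrow(), m = Q.nrow();
  IntegerVector idx(n);
  NumericVector dist(n);
  for (int i = 0; i < n; ++i) {
    double px = P(i, 0), py = P(i, 1), best = R_PosInf;
    int bj = 0;
    for (int j = 0; j < m; ++j) {
      double dx = px - Q(j, 0), dy = py - Q(j, 1);
      double d2 = dx * dx + dy * dy;
      if (d2 < best) { best = d2; bj = j; }
    }
    idx[i] = bj + 1;
    dist[i] = std::sqrt(best);
  }
  return List::create(_["idx"] = idx, _["dist"] = dist);
}

// Rigid 2D resampling of an image (bilinear). Output pixel (r,c) takes the
// value of the input at the inverse-mapped location; map is in pixel units:
// input = R^T (output - t).
// [[Rcpp::export]]
NumericMatrix cpp_warp_rigid(NumericMatrix img, double cosang, double sinang,
                             double tx, double ty, double fill) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      // forward map: out = R * in + t  =>  in = R^T (out - t)
      double x = c - tx, y = r - ty;
      double xi = cosang * x + sinang * y;
      double yi = -sinang * x + cosang * y;
      int c0 = (int)std::floor(xi), r0 = (int)std::floor(yi);
      double fx = xi - c0, fy = yi - r0;
      if (c0 < 0 || r0 < 0 || c0 + 1 >= nc || r0 + 1 >= nr) {
        out(r, c) = fill;
        continue;
      }
      out(r, c) = (1 - fx) * (1 - fy) * img(r0, c0)
                + fx * (1 - fy) * img(r0, c0 + 1)
                + (1 - fx) * fy * img(r0 + 1, c0)
                + fx * fy * img(r0 + 1, c0 + 1);
    }
  }
  return out;
}

// 4-connected component labelling of a logical matrix.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(r + c * nr);
      lab(r, c) = next;
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int rr = idx % nr, cc = idx / nr;
        const int dr[4] = {1, -1, 0, 0}, dc[4] = {0, 0, 1, -1};
        for (int k = 0; k < 4; ++k) {
          int r2 = rr + dr[k], c2 = cc + dc[k];
          if (r2 < 0 || c2 < 0 || r2 >= nr || c2 >= nc) continue;
          if (mask(r2, c2) && lab(r2, c2) == 0) {
            lab(r2, c2) = next;
            stack.push_back(r2 + c2 * nr);
          }
        }
      }
    }
  }
  return lab;
}
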