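#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Relative tolerance for "strictly inside" tests against the alpha ball:
// points lying numerically on the circle/sphere do not invalidate a face.
static const double REL_TOL = 1e-9;

// Per-neighborhood phenotype counts and summed channel intensities.
// Membership is a closed ball: Euclidean distance <= radius, in x-y only
// (cylindrical window, use_z = false) or in x-y-z (spherical, use_z = true).
// Deliberately an exact all-pairs scan: the contract is the brute-force
// result, and at desk scale this is fast enough without a spatial index.
// [[Rcpp::export]]
List nbhd_count_cpp(NumericMatrix cells, IntegerVector phen, int nphen,
                    NumericMatrix chans, NumericMatrix centers,
                    double radius, bool use_z) {
  const int ncell = cells.nrow(), ncent = centers.nrow(),
            nchan = chans.ncol();
  IntegerMatrix counts(ncent, nphen);
  NumericMatrix mfi(ncent, nchan);
  const double r2 = radius * radius;
  for (int c = 0; c < ncent; ++c) {
    const double cx = centers(c, 0), cy = centers(c, 1), cz = centers(c, 2);
    for (int i = 0; i < ncell; ++i) {
      double dx = cells(i, 0) - cx, dy = cells(i, 1) - cy;
      double d2 = dx * dx + dy * dy;
      if (use_z) {
        double dz = cells(i, 2) - cz;
        d2 += dz * dz;
      }
      if (d2 <= r2) {
        counts(c, phen[i]) += 1;
        for (int k = 0; k < nchan; ++k) mfi(c, k) += chans(i, k);
      }
    }
  }
  return List::create(_["counts"] = counts, _["mfi"] = mfi);
}

// 2D alpha-shape boundary edges by the empty-circumdisk criterion: the
// segment (i, j) lies on the boundary iff one of the two radius-alpha disks
// through both endpoints contains no other input point.
// [[Rcpp::export]]
IntegerMatrix alpha_edges_2d_cpp(NumericVector x, NumericVector y,
                                 double alpha) {
  const int n = x.size();
  const double a2 = alpha * alpha;
  const double inside2 = a2 * (1.0 - REL_TOL);
  std::vector<int> ei, ej;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const double dx = x[j] - x[i], dy = y[j] - y[i];
      const double d2 = dx * dx + dy * dy;
      if (d2 > 4.0 * a2 || d2 == 0.0) continue;
      const double mx = 0.5 * (x[i] + x[j]), my = 0.5 * (y[i] + y[j]);
      const double h = std::sqrt(std::max(0.0, a2 - 0.25 * d2));
      const double invd = 1.0 / std::sqrt(d2);
      // unit perpendicular to the segment
      const double px = -dy * invd, py = dx * invd;
      for (int s = 0; s < 2; ++s) {
        const double sgn = s ? -1.0 : 1.0;
        const double ccx = mx + sgn * h * px, ccy = my + sgn * h * py;
        bool empty = true;
        for (int k = 0; k < n && empty; ++k) {
          if (k == i || k == j) continue;
          const double ex = x[k] - ccx, ey = y[k] - ccy;
          if (ex * ex + ey * ey < inside2) empty = false;
        }
        if (empty) {
          ei.push_back(i + 1);
          ej.push_back(j + 1);
          break;
        }
      }
    }
  }
  IntegerMatrix out(ei.size(), 2);
  for (size_t r = 0; r < ei.size(); ++r) {
    out(r, 0) = ei[r];
    out(r, 1) = ej[r];
  }
  return out;
}

// 3D alpha-shape boundary triangles by the empty-circumsphere criterion:
// the triangle (i, j, k) is a boundary face iff one of the two radius-alpha
// spheres through its vertices contains no other input point.
// [[Rcpp::export]]
IntegerMatrix alpha_faces_3d_cpp(NumericMatrix pts, double alpha) {
  const int n = pts.nrow();
  const double a2 = alpha * alpha;
  const double inside2 = a2 * (1.0 - REL_TOL);
  std::vector<int> fi, fj, fk;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double ab[3], d2ab = 0;
      for (int t = 0; t < 3; ++t) {
        ab[t] = pts(j, t) - pts(i, t);
        d2ab += ab[t] * ab[t];
      }
      if (d2ab > 4.0 * a2 || d2ab == 0.0) continue;
      for (int k = j + 1; k < n; ++k) {
        double ac[3], d2ac = 0, d2bc = 0;
        for (int t = 0; t < 3; ++t) {
          ac[t] = pts(k, t) - pts(i, t);
          d2ac += ac[t] * ac[t];
          const double bc = pts(k, t) - pts(j, t);
          d2bc += bc * bc;
        }
        if (d2ac > 4.0 * a2 || d2bc > 4.0 * a2 || d2ac == 0.0 || d2bc == 0.0)
          continue;
        // triangle circumcenter: A + (|AB|^2 (AC x N) + |AC|^2 (N x AB)) / (2 |N|^2)
        double nrm[3] = {ab[1] * ac[2] - ab[2] * ac[1],
                         ab[2] * ac[0] - ab[0] * ac[2],
                         ab[0] * ac[1] - ab[1] * ac[0]};
        const double n2 = nrm[0] * nrm[0] + nrm[1] * nrm[1] + nrm[2] * nrm[2];
        if (n2 < 1e-18 * d2ab * d2ac) continue;  // degenerate (collinear)
        double t1[3] = {ac[1] * nrm[2] - ac[2] * nrm[1],
                        ac[2] * nrm[0] - ac[0] * nrm[2],
                        ac[0] * nrm[1] - ac[1] * nrm[0]};
        double t2[3] = {nrm[1] * ab[2] - nrm[2] * ab[1],
                        nrm[2] * ab[0] - nrm[0] * ab[2],
                        nrm[0] * ab[1] - nrm[1] * ab[0]};
        double cc[3], rc2 = 0;
        for (int t = 0; t < 3; ++t) {
          cc[t] = pts(i, t) + (d2ab * t1[t] + d2ac * t2[t]) / (2.0 * n2);
          const double d = cc[t] - pts(i, t);
          rc2 += d * d;
        }
        if (rc2 > a2) continue;
        const double h = std::sqrt(std::max(0.0, a2 - rc2));
        const double invn = 1.0 / std::sqrt(n2);
        for (int s = 0; s < 2; ++s) {
          const double sgn = s ? -1.0 : 1.0;
          double sc[3];
          for (int t = 0; t < 3; ++t) sc[t] = cc[t] + sgn * h * nrm[t] * invn;
          bool empty = true;
          for (int m = 0; m < n && empty; ++m) {
            if (m == i || m == j || m == k) continue;
            double e2 = 0;
            for (int t = 0; t < 3; ++t) {
              const double e = pts(m, t) - sc[t];
              e2 += e * e;
            }
            if (e2 < inside2) empty = false;
          }
          if (empty) {
            fi.push_back(i + 1);
            fj.push_back(j + 1);
            fk.push_back(k + 1);
            break;
          }
        }
      }
    }
  }
  IntegerMatrix out(fi.size(), 3);
  for (size_t r = 0; r < fi.size(); ++r) {
    out(r, 0) = fi[r];
    out(r, 1) = fj[r];
    out(r, 2) = fk[r];
  }
  return out;
}

// Even-odd (crossing-number) containment of query points against an
// unordered set of boundary segments forming closed loops.
// [[Rcpp::export]]
LogicalVector crossings_inside_2d_cpp(NumericVector px, NumericVector py,
                                      NumericMatrix seg) {
  const int np = px.size(), ns = seg.nrow();
  LogicalVector inside(np);
  for (int p = 0; p < np; ++p) {
    bool in = false;
    for (int s = 0; s < ns; ++s) {
      const double ax = seg(s, 0), ay = seg(s, 1), bx = seg(s, 2),
                   by = seg(s, 3);
      if ((ay > py[p]) != (by > py[p])) {
        const double xint = ax + (py[p] - ay) * (bx - ax) / (by - ay);
        if (px[p] < xint) in = !in;
      }
    }
    inside[p] = in;
  }
  return inside;
}

// Minimum distance from each query point to a set of 2D segments.
// [[Rcpp::export]]
NumericVector dist_segments_2d_cpp(NumericVector px, NumericVector py,
                                   NumericMatrix seg) {
  const int np = px.size(), ns = seg.nrow();
  NumericVector out(np);
  for (int p = 0; p < np; ++p) {
    double best = R_PosInf;
    for (int s = 0; s < ns; ++s) {
      const double ax = seg(s, 0), ay = seg(s, 1);
      const double vx = seg(s, 2) - ax, vy = seg(s, 3) - ay;
      const double wx = px[p] - ax, wy = py[p] - ay;
      const double vv = vx * vx + vy * vy;
      double t = vv > 0 ? (wx * vx + wy * vy) / vv : 0.0;
      if (t < 0) t = 0;
      if (t > 1) t = 1;
      const double dx = wx - t * vx, dy = wy - t * vy;
      const double d2 = dx * dx + dy * dy;
      if (d2 < best) best = d2;
    }
    out[p] = std::sqrt(best);
  }
  return out;
}

// Ray-parity containment in 3D against a triangle soup forming a closed
// mesh. The ray direction uses irrational-ish components to avoid grazing
// edges/vertices of typical inputs.
// [[Rcpp::export]]
LogicalVector ray_parity_3d_cpp(NumericMatrix q, NumericMatrix pts,
                                IntegerMatrix faces) {
  const int np = q.nrow(), nf = faces.nrow();
  const double dir[3] = {0.5403023058681398, 0.8414709848078965,
                         0.30116867893975674};  // cos(1), sin(1), sin(1)*...
  LogicalVector inside(np);
  for (int p = 0; p < np; ++p) {
    int hits = 0;
    const double o[3] = {q(p, 0), q(p, 1), q(p, 2)};
    for (int f = 0; f < nf; ++f) {
      const int ia = faces(f, 0) - 1, ib = faces(f, 1) - 1,
                ic = faces(f, 2) - 1;
      double e1[3], e2[3];
      for (int t = 0; t < 3; ++t) {
        e1[t] = pts(ib, t) - pts(ia, t);
        e2[t] = pts(ic, t) - pts(ia, t);
      }
      // Moeller-Trumbore
      double pv[3] = {dir[1] * e2[2] - dir[2] * e2[1],
                      dir[2] * e2[0] - dir[0] * e2[2],
                      dir[0] * e2[1] - dir[1] * e2[0]};
      const double det = e1[0] * pv[0] + e1[1] * pv[1] + e1[2] * pv[2];
      if (std::fabs(det) < 1e-14) continue;
      const double inv = 1.0 / det;
      double tv[3];
      for (int t = 0; t < 3; ++t) tv[t] = o[t] - pts(ia, t);
      const double u = (tv[0] * pv[0] + tv[1] * pv[1] + tv[2] * pv[2]) * inv;
      if (u < 0.0 || u > 1.0) continue;
      double qv[3] = {tv[1] * e1[2] - tv[2] * e1[1],
                      tv[2] * e1[0] - tv[0] * e1[2],
                      tv[0] * e1[1] - tv[1] * e1[0]};
      const double v = (dir[0] * qv[0] + dir[1] * qv[1] + dir[2] * qv[2]) * inv;
      if (v < 0.0 || u + v > 1.0) continue;
      const double t = (e2[0] * qv[0] + e2[1] * qv[1] + e2[2] * qv[2]) * inv;
      if (t > 0.0) ++hits;
    }
    inside[p] = (hits % 2) == 1;
  }
  return inside;
}

// Minimum distance from each query point to a set of triangles.
// [[Rcpp::export]]
NumericVector dist_triangles_3d_cpp(NumericMatrix q, NumericMatrix pts,
                                    IntegerMatrix faces) {
  const int np = q.nrow(), nf = faces.nrow();
  NumericVector out(np);
  for (int p = 0; p < np; ++p) {
    double best = R_PosInf;
    const double o[3] = {q(p, 0), q(p, 1), q(p, 2)};
    for (int f = 0; f < nf; ++f) {
      const int ia = faces(f, 0) - 1, ib = faces(f, 1) - 1,
                ic = faces(f, 2) - 1;
      double a[3], e0[3], e1[3], d[3];
      for (int t = 0; t < 3; ++t) {
        a[t] = pts(ia, t);
        e0[t] = pts(ib, t) - a[t];
        e1[t] = pts(ic, t) - a[t];
        d[t] = a[t] - o[t];
      }
      // Eberly's point-triangle distance (quadratic minimization over the
      // barycentric simplex)
      const double aa = e0[0] * e0[0] + e0[1] * e0[1] + e0[2] * e0[2];
      const double bb = e0[0] * e1[0] + e0[1] * e1[1] + e0[2] * e1[2];
      const double cc = e1[0] * e1[0] + e1[1] * e1[1] + e1[2] * e1[2];
      const double dd = e0[0] * d[0] + e0[1] * d[1] + e0[2] * d[2];
      const double ee = e1[0] * d[0] + e1[1] * d[1] + e1[2] * d[2];
      const double det = std::max(aa * cc - bb * bb, 0.0);
      double s = bb * ee - cc * dd, t = bb * dd - aa * ee;
      if (s + t <= det) {
        if (s < 0) {
          if (t < 0) {  // region 4
            if (dd < 0) {
              t = 0;
              s = (-dd >= aa) ? 1 : -dd / aa;
            } else {
              s = 0;
              t = (ee >= 0) ? 0 : ((-ee >= cc) ? 1 : -ee / cc);
            }
          } else {  // region 3
            s = 0;
            t = (ee >= 0) ? 0 : ((-ee >= cc) ? 1 : -ee / cc);
          }
        } else if (t < 0) {  // region 5
          t = 0;
          s = (dd >= 0) ? 0 : ((-dd >= aa) ? 1 : -dd / aa);
        } else {  // region 0
          const double invdet = det > 0 ? 1.0 / det : 0.0;
          s *= invdet;
          t *= invdet;
        }
      } else {
        if (s < 0) {  // region 2
          const double t0 = bb + dd, t1 = cc + ee;
          if (t1 > t0) {
            const double numer = t1 - t0, denom = aa - 2 * bb + cc;
            s = (numer >= denom) ? 1 : numer / denom;
            t = 1 - s;
          } else {
            s = 0;
            t = (t1 <= 0) ? 1 : ((ee >= 0) ? 0 : -ee / cc);
          }
        } else if (t < 0) {  // region 6
          const double t0 = bb + ee, t1 = aa + dd;
          if (t1 > t0) {
            const double numer = t1 - t0, denom = aa - 2 * bb + cc;
            t = (numer >= denom) ? 1 : numer / denom;
            s = 1 - t;
          } else {
            t = 0;
            s = (t1 <= 0) ? 1 : ((dd >= 0) ? 0 : -dd / aa);
          }
        } else {  // region 1
          const double numer = cc + ee - bb - dd;
          if (numer <= 0) {
            s = 0;
          } else {
            const double denom = aa - 2 * bb + cc;
            s = (numer >= denom) ? 1 : numer / denom;
          }
          t = 1 - s;
        }
      }
      double d2 = 0;
      for (int u = 0; u < 3; ++u) {
        const double w = a[u] + s * e0[u] + t * e1[u] - o[u];
        d2 += w * w;
      }
      if (d2 < best) best = d2;
    }
    out[p] = std::sqrt(best);
  }
  return out;
}
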