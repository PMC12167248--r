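#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

// Pixel convention: pixel (row i, col j), 0-based, has its centre at
// continuous image coordinates (u = j, v = i).  Matrices are height x width.

static inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// ---------------------------------------------------------------------------
// Hard z-buffered rasterizer: perspective-correct (1/z interpolation),
// pixel-centre sampling.  Faces with any vertex at depth <= znear are
// clipped away entirely (they cannot be represented by screen-space
// interpolation); callers keep cameras away from the geometry.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_zbuffer_render(NumericMatrix uv, NumericVector depth,
                        IntegerMatrix faces, int width, int height,
                        double znear) {
  const int m = faces.nrow();
  IntegerMatrix face_id(height, width);   // 0 = background, else face row + 1
  NumericMatrix zbuf(height, width);
  std::fill(zbuf.begin(), zbuf.end(), std::numeric_limits<double>::infinity());

  for (int f = 0; f < m; ++f) {
    const int i0 = faces(f, 0), i1 = faces(f, 1), i2 = faces(f, 2);
    const double z0 = depth[i0], z1 = depth[i1], z2 = depth[i2];
    if (!(z0 > znear && z1 > znear && z2 > znear)) continue;
    const double x0 = uv(i0, 0), y0 = uv(i0, 1);
    const double x1 = uv(i1, 0), y1 = uv(i1, 1);
    const double x2 = uv(i2, 0), y2 = uv(i2, 1);
    if (!(R_finite(x0) && R_finite(x1) && R_finite(x2) &&
          R_finite(y0) && R_finite(y1) && R_finite(y2))) continue;
    int jmin = (int)std::ceil(std::min(x0, std::min(x1, x2)));
    int jmax = (int)std::floor(std::max(x0, std::max(x1, x2)));
    int imin = (int)std::ceil(std::min(y0, std::min(y1, y2)));
    int imax = (int)std::floor(std::max(y0, std::max(y1, y2)));
    if (jmin < 0) jmin = 0;
    if (imin < 0) imin = 0;
    if (jmax >= width) jmax = width - 1;
    if (imax >= height) imax = height - 1;
    if (jmin > jmax || imin > imax) continue;
    const double area = (x1 - x0) * (y2 - y0) - (x2 - x0) * (y1 - y0);
    if (std::fabs(area) < 1e-14) continue;
    const double inv0 = 1.0 / z0, inv1 = 1.0 / z1, inv2 = 1.0 / z2;
    for (int i = imin; i <= imax; ++i) {
      const double py = (double)i;
      for (int j = jmin; j <= jmax; ++j) {
        const double px = (double)j;
        double w0 = (x1 - px) * (y2 - py) - (x2 - px) * (y1 - py);
        double w1 = (x2 - px) * (y0 - py) - (x0 - px) * (y2 - py);
        double w2 = (x0 - px) * (y1 - py) - (x1 - px) * (y0 - py);
        w0 /= area; w1 /= area; w2 /= area;
        if (w0 < 0 || w1 < 0 || w2 < 0) continue;
        const double invz = w0 * inv0 + w1 * inv1 + w2 * inv2;
        if (invz <= 0) continue;
        const double z = 1.0 / invz;
        if (z < zbuf(i, j)) {
          zbuf(i, j) = z;
          face_id(i, j) = f + 1;
        }
      }
    }
  }
  return List::create(_["face_id"] = face_id, _["depth"] = zbuf);
}

// ---------------------------------------------------------------------------
// Ray casting (Moller-Trumbore), first hit with front-face priority: the
// nearest front-facing intersection wins; back faces are eligible only when
// no front face is hit (open meshes seen from behind).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_raycast(NumericVector origin, NumericMatrix dirs,
                 NumericMatrix verts, IntegerMatrix faces) {
  const int nray = dirs.nrow(), m = faces.nrow();
  IntegerVector hit_face(nray);             // 1-based, 0 = miss
  NumericVector hit_t(nray, NA_REAL);
  NumericMatrix hit_pt(nray, 3);
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const double eps = 1e-10;

  for (int r = 0; r < nray; ++r) {
    const double dx = dirs(r, 0), dy = dirs(r, 1), dz = dirs(r, 2);
    double best_front = std::numeric_limits<double>::infinity();
    double best_back = std::numeric_limits<double>::infinity();
    int face_front = 0, face_back = 0;
    for (int f = 0; f < m; ++f) {
      const int i0 = faces(f, 0), i1 = faces(f, 1), i2 = faces(f, 2);
      const double ax = verts(i0, 0), ay = verts(i0, 1), az = verts(i0, 2);
      const double e1x = verts(i1, 0) - ax, e1y = verts(i1, 1) - ay,
                   e1z = verts(i1, 2) - az;
      const double e2x = verts(i2, 0) - ax, e2y = verts(i2, 1) - ay,
                   e2z = verts(i2, 2) - az;
      const double px = dy * e2z - dz * e2y;
      const double py = dz * e2x - dx * e2z;
      const double pz = dx * e2y - dy * e2x;
      const double det = e1x * px + e1y * py + e1z * pz;
      if (std::fabs(det) < eps) continue;
      const double invdet = 1.0 / det;
      const double tx = ox - ax, ty = oy - ay, tz = oz - az;
      const double u = (tx * px + ty * py + tz * pz) * invdet;
      if (u < -1e-9 || u > 1 + 1e-9) continue;
      const double qx = ty * e1z - tz * e1y;
      const double qy = tz * e1x - tx * e1z;
      const double qz = tx * e1y - ty * e1x;
      const double v = (dx * qx + dy * qy + dz * qz) * invdet;
      if (v < -1e-9 || u + v > 1 + 1e-9) continue;
      const double t = (e2x * qx + e2y * qy + e2z * qz) * invdet;
      if (t <= 1e-9) continue;
      // det = -2 * area * dot(dir, n): det > 0 <=> the ray opposes the
      // outward normal of a counter-clockwise face (front-facing)
      if (det > 0) {
        if (t < best_front) { best_front = t; face_front = f + 1; }
      } else {
        if (t < best_back) { best_back = t; face_back = f + 1; }
      }
    }
    double t = NA_REAL; int fid = 0;
    if (face_front > 0) { t = best_front; fid = face_front; }
    else if (face_back > 0) { t = best_back; fid = face_back; }
    hit_face[r] = fid;
    if (fid > 0) {
      hit_t[r] = t;
      hit_pt(r, 0) = ox + t * dx;
      hit_pt(r, 1) = oy + t * dy;
      hit_pt(r, 2) = oz + t * dz;
    } else {
      hit_pt(r, 0) = NA_REAL; hit_pt(r, 1) = NA_REAL; hit_pt(r, 2) = NA_REAL;
    }
  }
  return List::create(_["face"] = hit_face, _["t"] = hit_t,
                      _["point"] = hit_pt);
}

// ---------------------------------------------------------------------------
// Soft silhouette renderer.
//
// Per pixel p and projected face T: d(p, T) is the signed 2D distance (px)
// from the pixel centre to the triangle boundary, positive inside.  The
// per-face occupancy is D = sigmoid(d / sigma) and the pixel value is the
// probabilistic union 1 - prod(1 - D) over the K faces with the largest d
// at that pixel.  Faces only touch pixels within pad_sigmas * sigma of
// their screen bounding box; beyond that D < sigmoid(-pad_sigmas) ~ 0.
//
// The backward pass propagates dLoss/d(uv of each projected vertex) for
// Loss = mean((S - ref)^2).  The gradient of the point-segment distance
// concentrates on the closest boundary edge: with foot parameter
// s in [0, 1] on edge (a, b) and unit vector nhat from foot to pixel,
// d dist/d a = -(1 - s) nhat, d dist/d b = -s nhat (terms along the edge
// vanish because pixel - foot is orthogonal to it when s is interior).
// ---------------------------------------------------------------------------

struct Kbuf {
  // fixed-size top-K buffer of (occupancy, face) sorted descending by d
  std::vector<double> d;   // signed distances, npix * K
  std::vector<int> f;      // face ids, npix * K
  std::vector<unsigned char> n;
  int K;
  Kbuf(int npix, int K_) : d(npix * (size_t)K_), f(npix * (size_t)K_),
                           n(npix, 0), K(K_) {}
  void insert(int p, double dist, int face) {
    double *dp = &d[(size_t)p * K];
    int *fp = &f[(size_t)p * K];
    int cnt = n[p];
    if (cnt == K && dist <= dp[K - 1]) return;
    int pos = (cnt < K) ? cnt : K - 1;
    while (pos > 0 && dp[pos - 1] < dist) {
      dp[pos] = dp[pos - 1]; fp[pos] = fp[pos - 1]; --pos;
    }
    dp[pos] = dist; fp[pos] = face;
    if (cnt < K) n[p] = cnt + 1;
  }
};

// signed distance from point (px, py) to triangle with vertices x[3], y[3];
// also reports the closest edge and its foot parameter for the gradient.
static double signed_dist_tri(double px, double py, const double *x,
                              const double *y, int *edge_out,
                              double *s_out) {
  double best = std::numeric_limits<double>::infinity();
  int bedge = 0; double bs = 0;
  for (int e = 0; e < 3; ++e) {
    const int a = e, b = (e + 1) % 3;
    const double ex = x[b] - x[a], ey = y[b] - y[a];
    const double len2 = ex * ex + ey * ey;
    double s = 0;
    if (len2 > 1e-300)
      s = clampd(((px - x[a]) * ex + (py - y[a]) * ey) / len2, 0.0, 1.0);
    const double qx = x[a] + s * ex, qy = y[a] + s * ey;
    const double dx = px - qx, dy = py - qy;
    const double dist = std::sqrt(dx * dx + dy * dy);
    if (dist < best) { best = dist; bedge = e; bs = s; }
  }
  // inside test: all edge functions of one sign
  const double w0 = (x[1] - x[0]) * (py - y[0]) - (px - x[0]) * (y[1] - y[0]);
  const double w1 = (x[2] - x[1]) * (py - y[1]) - (px - x[1]) * (y[2] - y[1]);
  const double w2 = (x[0] - x[2]) * (py - y[2]) - (px - x[2]) * (y[0] - y[2]);
  const bool inside = (w0 >= 0 && w1 >= 0 && w2 >= 0) ||
                      (w0 <= 0 && w1 <= 0 && w2 <= 0);
  *edge_out = bedge;
  *s_out = bs;
  return inside ? best : -best;
}

// [[Rcpp::export]]
List cpp_soft_render(NumericMatrix uv, NumericVector depth,
                     IntegerMatrix faces, int width, int height,
                     double sigma, int K, double pad_sigmas,
                     Nullable<NumericMatrix> ref_, bool want_grad) {
  const int m = faces.nrow(), nvert = uv.nrow();
  const int npix = width * height;
  Kbuf buf(npix, K);
  const double pad = pad_sigmas * sigma;

  std::vector<int> live;   // faces fully in front of the camera
  live.reserve(m);
  for (int f = 0; f < m; ++f) {
    const int i0 = faces(f, 0), i1 = faces(f, 1), i2 = faces(f, 2);
    if (depth[i0] > 1e-9 && depth[i1] > 1e-9 && depth[i2] > 1e-9 &&
        R_finite(uv(i0, 0)) && R_finite(uv(i1, 0)) && R_finite(uv(i2, 0)))
      live.push_back(f);
  }

  for (size_t li = 0; li < live.size(); ++li) {
    const int f = live[li];
    double x[3], y[3];
    for (int k = 0; k < 3; ++k) {
      x[k] = uv(faces(f, k), 0);
      y[k] = uv(faces(f, k), 1);
    }
    int jmin = (int)std::ceil(std::min(x[0], std::min(x[1], x[2])) - pad);
    int jmax = (int)std::floor(std::max(x[0], std::max(x[1], x[2])) + pad);
    int imin = (int)std::ceil(std::min(y[0], std::min(y[1], y[2])) - pad);
    int imax = (int)std::floor(std::max(y[0], std::max(y[1], y[2])) + pad);
    if (jmin < 0) jmin = 0;
    if (imin < 0) imin = 0;
    if (jmax >= width) jmax = width - 1;
    if (imax >= height) imax = height - 1;
    int edge; double s;
    for (int i = imin; i <= imax; ++i)
      for (int j = jmin; j <= jmax; ++j) {
        const double d = signed_dist_tri((double)j, (double)i, x, y,
                                         &edge, &s);
        if (d < -pad) continue;
        buf.insert(i + (size_t)j * height, d, f);
      }
  }

  NumericMatrix img(height, width);
  bool have_ref = ref_.isNotNull();
  NumericMatrix ref;
  if (have_ref) ref = NumericMatrix(ref_);
  double loss = 0.0;
  NumericMatrix grad_uv(want_grad ? nvert : 1, 2);

  for (int p = 0; p < npix; ++p) {
    const int cnt = buf.n[p];
    const double *dp = &buf.d[(size_t)p * K];
    const int *fp = &buf.f[(size_t)p * K];
    const int i = p % height, j = p / height;
    double prod = 1.0;
    double D[32];
    for (int k = 0; k < cnt; ++k) {
      D[k] = 1.0 / (1.0 + std::exp(-dp[k] / sigma));
      prod *= (1.0 - D[k]);
    }
    const double S = 1.0 - prod;
    img(i, j) = S;
    if (!have_ref) continue;
    const double r = S - ref(i, j);
    loss += r * r;
    if (!want_grad || cnt == 0) continue;
    const double dLdS = 2.0 * r / npix;
    for (int k = 0; k < cnt; ++k) {
      // dS/dD_k = prod over the other faces of (1 - D)
      double others = 1.0;
      for (int k2 = 0; k2 < cnt; ++k2)
        if (k2 != k) others *= (1.0 - D[k2]);
      const double dDdd = D[k] * (1.0 - D[k]) / sigma;
      const double dLdd = dLdS * others * dDdd;
      if (dLdd == 0.0) continue;
      // recompute closest-edge geometry for face fp[k] at this pixel
      const int f = fp[k];
      double x[3], y[3];
      for (int t = 0; t < 3; ++t) {
        x[t] = uv(faces(f, t), 0);
        y[t] = uv(faces(f, t), 1);
      }
      int edge; double s;
      const double d = signed_dist_tri((double)j, (double)i, x, y,
                                       &edge, &s);
      const double sign = d >= 0 ? 1.0 : -1.0;
      const int a = edge, b = (edge + 1) % 3;
      const double qx = x[a] + s * (x[b] - x[a]);
      const double qy = y[a] + s * (y[b] - y[a]);
      double nx = (double)j - qx, ny = (double)i - qy;
      const double nn = std::sqrt(nx * nx + ny * ny);
      if (nn < 1e-12) continue;  // pixel exactly on the boundary
      nx /= nn; ny /= nn;
      // d = sign * |p - q|; d|p-q|/da = -(1-s) nhat, d|p-q|/db = -s nhat
      const int va = faces(f, a), vb = faces(f, b);
      grad_uv(va, 0) += dLdd * sign * (-(1.0 - s) * nx);
      grad_uv(va, 1) += dLdd * sign * (-(1.0 - s) * ny);
      grad_uv(vb, 0) += dLdd * sign * (-s * nx);
      grad_uv(vb, 1) += dLdd * sign * (-s * ny);
    }
  }

  List out = List::create(_["image"] = img);
  if (have_ref) out["loss"] = loss / npix;
  if (want_grad) out["grad_uv"] = grad_uv;
  return out;
}

// ---------------------------------------------------------------------------
// Thick polyline rasterization: union of capsules (segments dilated by
// thickness / 2) sampled at pixel centres.  Deterministic by construction.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix cpp_polyline_mask(NumericMatrix pts, int width, int height,
                                double thickness, bool closed) {
  const int n = pts.nrow();
  IntegerMatrix mask(height, width);
  const double r = thickness / 2.0;
  const int nseg = (n == 1) ? 1 : (closed ? n : n - 1);
  for (int sgi = 0; sgi < nseg; ++sgi) {
    const int a = sgi, b = (n == 1) ? sgi : (sgi + 1) % n;
    const double ax = pts(a, 0), ay = pts(a, 1);
    const double bx = pts(b, 0), by = pts(b, 1);
    int jmin = (int)std::ceil(std::min(ax, bx) - r);
    int jmax = (int)std::floor(std::max(ax, bx) + r);
    int imin = (int)std::ceil(std::min(ay, by) - r);
    int imax = (int)std::floor(std::max(ay, by) + r);
    if (jmin < 0) jmin = 0;
    if (imin < 0) imin = 0;
    if (jmax >= width) jmax = width - 1;
    if (imax >= height) imax = height - 1;
    const double ex = bx - ax, ey = by - ay;
    const double len2 = ex * ex + ey * ey;
    for (int i = imin; i <= imax; ++i)
      for (int j = jmin; j <= jmax; ++j) {
        double s = 0;
        if (len2 > 1e-300)
          s = clampd(((j - ax) * ex + (i - ay) * ey) / len2, 0.0, 1.0);
        const double dx = j - (ax + s * ex), dy = i - (ay + s * ey);
        if (dx * dx + dy * dy <= r * r) mask(i, j) = 1;
      }
  }
  return mask;
}

// ---------------------------------------------------------------------------
// Even-odd inside test: parity of ray crossings along +x from each point.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
LogicalVector cpp_inside_mesh(NumericMatrix pts, NumericMatrix verts,
                              IntegerMatrix faces) {
  const int n = pts.nrow(), m = faces.nrow();
  LogicalVector inside(n);
  const double eps = 1e-12;
  for (int r = 0; r < n; ++r) {
    const double ox = pts(r, 0), oy = pts(r, 1), oz = pts(r, 2);
    // fixed slightly-irrational direction to dodge edge-grazing rays
    const double dx = 0.998208137, dy = 0.0522603, dz = 0.0291741;
    int crossings = 0;
    for (int f = 0; f < m; ++f) {
      const int i0 = faces(f, 0), i1 = faces(f, 1), i2 = faces(f, 2);
      const double ax = verts(i0, 0), ay = verts(i0, 1), az = verts(i0, 2);
      const double e1x = verts(i1, 0) - ax, e1y = verts(i1, 1) - ay,
                   e1z = verts(i1, 2) - az;
      const double e2x = verts(i2, 0) - ax, e2y = verts(i2, 1) - ay,
                   e2z = verts(i2, 2) - az;
      const double px = dy * e2z - dz * e2y;
      const double py = dz * e2x - dx * e2z;
      const double pz = dx * e2y - dy * e2x;
      const double det = e1x * px + e1y * py + e1z * pz;
      if (std::fabs(det) < eps) continue;
      const double invdet = 1.0 / det;
      const double tx = ox - ax, ty = oy - ay, tz = oz - az;
      const double u = (tx * px + ty * py + tz * pz) * invdet;
      if (u < 0 || u > 1) continue;
      const double qx = ty * e1z - tz * e1y;
      const double qy = tz * e1x - tx * e1z;
      const double qz = tx * e1y - ty * e1x;
      const double v = (dx * qx + dy * qy + dz * qz) * invdet;
      if (v < 0 || u + v > 1) continue;
      const double t = (e2x * qx + e2y * qy + e2z * qz) * invdet;
      if (t > 0) ++crossings;
    }
    inside[r] = (crossings % 2) == 1;
  }
  return inside;
}
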