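#include "geometry.h"

namespace pmc {

static const double kInf = std::numeric_limits<double>::infinity();

bool Shape::contains(const double* p) const {
  const double dx = p[0] - c[0], dy = p[1] - c[1], dz = p[2] - c[2];
  switch (type) {
  case SHAPE_CYLINDER:
    return dx * dx + dy * dy < r[0] * r[0] && std::fabs(dz) < r[2];
  case SHAPE_SPHERE:
    return dx * dx + dy * dy + dz * dz < r[0] * r[0];
  case SHAPE_ELLIPSOID: {
    const double qx = dx / r[0], qy = dy / r[1], qz = dz / r[2];
    return qx * qx + qy * qy + qz * qz < 1.0;
  }
  case SHAPE_BOX:
    return std::fabs(dx) < r[0] && std::fabs(dy) < r[1] && std::fabs(dz) < r[2];
  case SHAPE_MESH: {
    // ray-parity test along a fixed oblique direction (unit (1,2,3)/sqrt(14))
    static const double d0[3] = {0.2672612419124244, 0.5345224838248488,
                                 0.8017837257372732};
    int crossings = 0;
    const size_t nf = F.size() / 3;
    for (size_t i = 0; i < nf; ++i) {
      const double* a = &V[3 * F[3 * i]];
      const double* b = &V[3 * F[3 * i + 1]];
      const double* cc = &V[3 * F[3 * i + 2]];
      const double t = ray_triangle(p, d0, a, b, cc);
      if (t > kHitEps) ++crossings;
    }
    return (crossings % 2) == 1;
  }
  }
  return false;
}

double ray_triangle(const double* p, const double* d, const double* a,
                    const double* b, const double* c) {
  double e1[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
  double e2[3] = {c[0] - a[0], c[1] - a[1], c[2] - a[2]};
  double h[3];
  cross3(d, e2, h);
  const double det = dot3(e1, h);
  if (std::fabs(det) < kBaryEps) return -1.0;  // parallel or degenerate
  const double inv = 1.0 / det;
  double s[3] = {p[0] - a[0], p[1] - a[1], p[2] - a[2]};
  const double u = dot3(s, h) * inv;
  if (u < -kBaryEps || u > 1.0 + kBaryEps) return -1.0;
  double q[3];
  cross3(s, e1, q);
  const double v = dot3(d, q) * inv;
  if (v < -kBaryEps || u + v > 1.0 + kBaryEps) return -1.0;
  return dot3(e2, q) * inv;
}

bool Shape::ray_hit(const double* p, const double* d, Hit& h) const {
  h.t = kInf;
  const double px = p[0] - c[0], py = p[1] - c[1], pz = p[2] - c[2];
  switch (type) {
  case SHAPE_CYLINDER: {
    const double R = r[0], H = r[2];
    // lateral surface
    const double A = d[0] * d[0] + d[1] * d[1];
    if (A > 1e-300) {
      const double B = 2.0 * (px * d[0] + py * d[1]);
      const double C = px * px + py * py - R * R;
      const double disc = B * B - 4.0 * A * C;
      if (disc >= 0.0) {
        const double sq = std::sqrt(disc);
        for (int k = 0; k < 2; ++k) {
          const double t = (-B + (k ? sq : -sq)) / (2.0 * A);
          if (t > kHitEps && t < h.t) {
            const double z = pz + t * d[2];
            if (std::fabs(z) <= H + 1e-12) {
              h.t = t;
              h.n[0] = (px + t * d[0]) / R;
              h.n[1] = (py + t * d[1]) / R;
              h.n[2] = 0.0;
              h.elem = 1;
            }
          }
        }
      }
    }
    // caps
    if (std::fabs(d[2]) > 1e-300) {
      for (int sgn = -1; sgn <= 1; sgn += 2) {
        const double t = (sgn * H - pz) / d[2];
        if (t > kHitEps && t < h.t) {
          const double x = px + t * d[0], y = py + t * d[1];
          if (x * x + y * y <= R * R + 1e-9) {
            h.t = t;
            h.n[0] = 0.0; h.n[1] = 0.0; h.n[2] = (double)sgn;
            h.elem = sgn < 0 ? 2 : 3;
          }
        }
      }
    }
    break;
  }
  case SHAPE_SPHERE:
  case SHAPE_ELLIPSOID: {
    const double rx = r[0], ry = (type == SHAPE_SPHERE) ? r[0] : r[1],
                 rz = (type == SHAPE_SPHERE) ? r[0] : r[2];
    const double qx = px / rx, qy = py / ry, qz = pz / rz;
    const double ex = d[0] / rx, ey = d[1] / ry, ez = d[2] / rz;
    const double A = ex * ex + ey * ey + ez * ez;
    const double B = 2.0 * (qx * ex + qy * ey + qz * ez);
    const double C = qx * qx + qy * qy + qz * qz - 1.0;
    const double disc = B * B - 4.0 * A * C;
    if (disc >= 0.0 && A > 0.0) {
      const double sq = std::sqrt(disc);
      for (int k = 0; k < 2; ++k) {
        const double t = (-B + (k ? sq : -sq)) / (2.0 * A);
        if (t > kHitEps && t < h.t) {
          h.t = t;
          h.n[0] = (px + t * d[0]) / (rx * rx);
          h.n[1] = (py + t * d[1]) / (ry * ry);
          h.n[2] = (pz + t * d[2]) / (rz * rz);
          normalize3(h.n);
          h.elem = 1;
        }
      }
    }
    break;
  }
  case SHAPE_BOX: {
    double tmin = -kInf, tmax = kInf;
    int amin = -1, amax = -1;
    const double pl[3] = {px, py, pz};
    for (int i = 0; i < 3; ++i) {
      if (std::fabs(d[i]) < 1e-300) {
        if (std::fabs(pl[i]) > r[i]) return false;  // parallel, outside slab
        continue;
      }
      double t1 = (-r[i] - pl[i]) / d[i];
      double t2 = (r[i] - pl[i]) / d[i];
      if (t1 > t2) std::swap(t1, t2);
      if (t1 > tmin) { tmin = t1; amin = i; }
      if (t2 < tmax) { tmax = t2; amax = i; }
    }
    if (tmin > tmax) return false;
    for (int k = 0; k < 2; ++k) {
      const double t = k ? tmax : tmin;
      const int ax = k ? amax : amin;
      if (t > kHitEps && t < h.t && ax >= 0) {
        h.t = t;
        h.n[0] = h.n[1] = h.n[2] = 0.0;
        const double sgn = (pl[ax] + t * d[ax]) > 0 ? 1.0 : -1.0;
        h.n[ax] = sgn;
        h.elem = 2 * ax + (sgn > 0 ? 2 : 1);
      }
    }
    break;
  }
  case SHAPE_MESH: {
    const size_t nf = F.size() / 3;
    for (size_t i = 0; i < nf; ++i) {
      const double* a = &V[3 * F[3 * i]];
      const double* b = &V[3 * F[3 * i + 1]];
      const double* cc = &V[3 * F[3 * i + 2]];
      const double t = ray_triangle(p, d, a, b, cc);
      if (t > kHitEps && t < h.t) {
        double e1[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
        double e2[3] = {cc[0] - a[0], cc[1] - a[1], cc[2] - a[2]};
        double nn[3];
        cross3(e1, e2, nn);
        if (norm3(nn) < 1e-18) continue;  // degenerate face
        normalize3(nn);
        h.t = t;
        h.n[0] = nn[0]; h.n[1] = nn[1]; h.n[2] = nn[2];
        h.elem = (int)i + 1;
      }
    }
    break;
  }
  }
  return h.t < kInf;
}

void Shape::bbox(double* lo, double* hi) const {
  switch (type) {
  case SHAPE_CYLINDER:
    lo[0] = c[0] - r[0]; hi[0] = c[0] + r[0];
    lo[1] = c[1] - r[0]; hi[1] = c[1] + r[0];
    lo[2] = c[2] - r[2]; hi[2] = c[2] + r[2];
    break;
  case SHAPE_SPHERE:
    for (int i = 0; i < 3; ++i) { lo[i] = c[i] - r[0]; hi[i] = c[i] + r[0]; }
    break;
  case SHAPE_ELLIPSOID:
  case SHAPE_BOX:
    for (int i = 0; i < 3; ++i) { lo[i] = c[i] - r[i]; hi[i] = c[i] + r[i]; }
    break;
  case SHAPE_MESH: {
    for (int i = 0; i < 3; ++i) { lo[i] = kInf; hi[i] = -kInf; }
    const size_t nv = V.size() / 3;
    for (size_t v = 0; v < nv; ++v)
      for (int i = 0; i < 3; ++i) {
        lo[i] = std::min(lo[i], V[3 * v + i]);
        hi[i] = std::max(hi[i], V[3 * v + i]);
      }
    break;
  }
  }
}

int Scene::locate_from(int node, const double* p) const {
  for (int ch : regs[node].children)
    if (regs[ch].shape.contains(p)) return locate_from(ch, p);
  return node;
}

int Scene::locate(const double* p) const {
  if (!regs[root].shape.contains(p)) return -1;
  return locate_from(root, p);
}

bool Scene::nearest_boundary(int current, const double* p, const double* d,
                             Hit& best, int& owner) const {
  best.t = kInf;
  owner = -1;
  int a = current;
  while (a >= 0) {
    Hit h;
    if (regs[a].shape.ray_hit(p, d, h) && h.t < best.t) { best = h; owner = a; }
    for (int ch : regs[a].children) {
      if (a != current && ch == current) continue;  // already tested as `a`
      if (regs[ch].shape.ray_hit(p, d, h) && h.t < best.t) { best = h; owner = ch; }
    }
    a = regs[a].parent;
  }
  return best.t < kInf;
}

} // namespace pmc
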