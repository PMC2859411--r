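#pragma once
#include <vector>
#include <cmath>
#include <limits>

namespace pmc {

// Ray-tracing tolerances.  kHitEps rejects re-intersection with the surface a
// packet was just nudged off; kNudge is the post-event advance along the new
// direction; kBaryEps is the barycentric slack of the triangle test.
constexpr double kHitEps  = 1e-9;
constexpr double kNudge   = 1e-7;
constexpr double kBaryEps = 1e-12;

enum ShapeType {
  SHAPE_CYLINDER = 0,  // axis along z
  SHAPE_SPHERE,
  SHAPE_ELLIPSOID,
  SHAPE_BOX,
  SHAPE_MESH
};

struct Hit {
  double t = std::numeric_limits<double>::infinity();
  double n[3] = {0, 0, 0};  // outward unit normal of the hit shape
  int elem = 0;             // 1-based surface part / mesh face id
};

struct Shape {
  int type = SHAPE_SPHERE;
  double c[3] = {0, 0, 0};
  // r[] meaning by type: cylinder r[0]=radius, r[2]=half-height;
  // sphere r[0]=radius; ellipsoid r[0..2]=semi-axes; box r[0..2]=half-extents.
  double r[3] = {1, 1, 1};
  std::vector<double> V;  // mesh vertices, xyz triplets
  std::vector<int> F;     // mesh faces, 0-based vertex index triplets

  bool contains(const double* p) const;
  bool ray_hit(const double* p, const double* d, Hit& h) const;
  void bbox(double* lo, double* hi) const;
};

// positive ray parameter of a ray-triangle intersection, or -1 on miss
double ray_triangle(const double* p, const double* d, const double* a,
                    const double* b, const double* c);

struct Region {
  int id = 0;
  int parent = -1;  // index into Scene::regs; -1 marks the root
  Shape shape;
  double mua = 0, mus = 0, g = 0, n = 1;
  std::vector<int> children;
};

struct Scene {
  std::vector<Region> regs;
  int root = 0;
  double ambient_n = 1.0;

  // deepest region containing p (first-listed child wins on overlap);
  // -1 when p is outside the root
  int locate(const double* p) const;
  int locate_from(int node, const double* p) const;

  // nearest boundary that can change the region of a packet currently in
  // `current`: the surfaces of current, of every ancestor (ancestors clip
  // children that poke out of them), and of the children of each of those.
  // Returns false when no surface lies ahead (non-closed geometry).
  bool nearest_boundary(int current, const double* p, const double* d,
                        Hit& h, int& owner) const;
};

inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
inline void cross3(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}
inline double norm3(const double* a) { return std::sqrt(dot3(a, a)); }
inline void normalize3(double* a) {
  double n = norm3(a);
  if (n > 0) { a[0] /= n; a[1] /= n; a[2] /= n; }
}

} // namespace pmc
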