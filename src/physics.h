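#pragma once
#include <cmath>
#include "geometry.h"
#include "xoshiro.h"

namespace pmc {

// inclination cosine of a Henyey-Greenstein deflection, inverse-CDF sampled
inline double hg_cos_theta(double xi, double g) {
  if (g == 0.0) return 2.0 * xi - 1.0;
  const double tmp = (1.0 - g * g) / (1.0 - g + 2.0 * g * xi);
  double ct = (1.0 + g * g - tmp * tmp) / (2.0 * g);
  if (ct > 1.0) ct = 1.0;
  if (ct < -1.0) ct = -1.0;
  return ct;
}

// direction from azimuth/inclination unit draws: phi = 2*pi*xi_phi,
// theta = acos(2*xi_theta - 1); uniform on the sphere
inline void isotropic_direction(double xi_phi, double xi_theta, double* d) {
  const double ct = 2.0 * xi_theta - 1.0;
  const double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  const double phi = 2.0 * M_PI * xi_phi;
  d[0] = st * std::cos(phi);
  d[1] = st * std::sin(phi);
  d[2] = ct;
}

// rotate (sin t cos p, sin t sin p, cos t) from the frame whose z-axis is
// the old direction; degenerate frame used when the old direction is within
// 1e-6 of +/-z to avoid catastrophic cancellation
inline void deflect_direction(double* u, double cos_t, double phi) {
  const double sin_t = std::sqrt(std::max(0.0, 1.0 - cos_t * cos_t));
  const double cp = std::cos(phi), sp = std::sin(phi);
  double ux = u[0], uy = u[1], uz = u[2];
  if (std::fabs(uz) > 1.0 - 1e-6) {
    u[0] = sin_t * cp;
    u[1] = sin_t * sp;
    u[2] = cos_t * (uz >= 0 ? 1.0 : -1.0);
  } else {
    const double den = std::sqrt(1.0 - uz * uz);
    u[0] = sin_t * (ux * uz * cp - uy * sp) / den + ux * cos_t;
    u[1] = sin_t * (uy * uz * cp + ux * sp) / den + uy * cos_t;
    u[2] = -sin_t * cp * den + uz * cos_t;
  }
  normalize3(u);
}

// unpolarized Fresnel reflectance for incidence cosine cos_i, indices ni->nt.
// Total internal reflection returns 1; normal incidence uses the analytic
// limit ((ni-nt)/(ni+nt))^2 (the angle form is 0/0 there).
inline double fresnel_reflectance_cos(double cos_i, double ni, double nt) {
  if (cos_i > 1.0) cos_i = 1.0;
  if (cos_i < 0.0) cos_i = 0.0;
  const double sin_i = std::sqrt(1.0 - cos_i * cos_i);
  const double sin_t = ni * sin_i / nt;
  if (sin_t >= 1.0) return 1.0;
  if (sin_i < 1e-9) {
    const double r0 = (ni - nt) / (ni + nt);
    return r0 * r0;
  }
  const double ti = std::asin(sin_i < 1.0 ? sin_i : 1.0);
  const double tt = std::asin(sin_t);
  const double sm = std::sin(ti - tt), sp2 = std::sin(ti + tt);
  const double tm = std::tan(ti - tt), tp = std::tan(ti + tt);
  return 0.5 * ((sm * sm) / (sp2 * sp2) + (tm * tm) / (tp * tp));
}

inline void reflect_direction(double* I, const double* N) {
  const double idotn = dot3(I, N);
  for (int i = 0; i < 3; ++i) I[i] -= 2.0 * idotn * N[i];
  normalize3(I);
}

// refraction: T = sin(tt) * tangent_unit + SIGN(I.N) * cos(tt) * N
inline void refract_direction(double* I, const double* N, double ni, double nt) {
  const double idotn = dot3(I, N);
  const double cos_i = std::fabs(idotn) > 1.0 ? 1.0 : std::fabs(idotn);
  const double sin_i = std::sqrt(std::max(0.0, 1.0 - cos_i * cos_i));
  const double sin_t = ni * sin_i / nt;
  const double cos_t = std::sqrt(std::max(0.0, 1.0 - sin_t * sin_t));
  double tang[3];
  for (int i = 0; i < 3; ++i) tang[i] = I[i] - idotn * N[i];
  const double tl = norm3(tang);
  const double sgn = idotn >= 0 ? 1.0 : -1.0;
  if (tl < 1e-12) {
    for (int i = 0; i < 3; ++i) I[i] = sgn * N[i];  // normal incidence
  } else {
    for (int i = 0; i < 3; ++i) I[i] = sin_t * tang[i] / tl + sgn * cos_t * N[i];
  }
  normalize3(I);
}

// Eq.-1-style rejection sampling of a point inside a shape from its bounding
// box; returns false after max_tries consecutive rejections
inline bool sample_in_shape(const Shape& sh, Xoshiro256& rng, double* p,
                            long max_tries = 1000000L) {
  double lo[3], hi[3];
  sh.bbox(lo, hi);
  for (long k = 0; k < max_tries; ++k) {
    for (int i = 0; i < 3; ++i) p[i] = lo[i] + (hi[i] - lo[i]) * rng.unif();
    if (sh.contains(p)) return true;
  }
  return false;
}

} // namespace pmc
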