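#include <Rcpp.h>
#include "xoshiro.h"
#include "geometry.h"
#include "physics.h"
#include "parse.h"

using namespace Rcpp;
using namespace pmc;

// ---- random substreams -----------------------------------------------------

// [[Rcpp::export]]
SEXP rcpp_make_stream(double seed, int jumps) {
  if (jumps < 0) stop("jumps must be >= 0");
  Xoshiro256* s = new Xoshiro256((uint64_t)seed);
  for (int i = 0; i < jumps; ++i) s->jump();
  XPtr<Xoshiro256> ptr(s, true);
  return ptr;
}

// [[Rcpp::export]]
NumericVector rcpp_stream_unif(SEXP stream, int n) {
  XPtr<Xoshiro256> s(stream);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = s->unif();
  return out;
}

// ---- sampling primitives ---------------------------------------------------

// [[Rcpp::export]]
NumericMatrix rcpp_isotropic_dir(NumericVector xi_phi, NumericVector xi_theta) {
  const int n = xi_phi.size();
  if (xi_theta.size() != n) stop("xi_phi and xi_theta lengths differ");
  NumericMatrix out(n, 3);
  double d[3];
  for (int i = 0; i < n; ++i) {
    isotropic_direction(xi_phi[i], xi_theta[i], d);
    out(i, 0) = d[0]; out(i, 1) = d[1]; out(i, 2) = d[2];
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix rcpp_sample_isotropic(SEXP stream, int n) {
  XPtr<Xoshiro256> s(stream);
  NumericMatrix out(n, 3);
  double d[3];
  for (int i = 0; i < n; ++i) {
    const double xp = s->unif(), xt = s->unif();
    isotropic_direction(xp, xt, d);
    out(i, 0) = d[0]; out(i, 1) = d[1]; out(i, 2) = d[2];
  }
  return out;
}

// [[Rcpp::export]]
NumericVector rcpp_hg_cos(NumericVector xi, double g) {
  if (std::fabs(g) >= 1.0) stop("anisotropy g must satisfy -1 < g < 1");
  NumericVector out(xi.size());
  for (int i = 0; i < xi.size(); ++i) out[i] = hg_cos_theta(xi[i], g);
  return out;
}

// [[Rcpp::export]]
NumericMatrix rcpp_sample_scatter(SEXP stream, NumericVector old_dir, double g,
                                  int n) {
  if (std::fabs(g) >= 1.0) stop("anisotropy g must satisfy -1 < g < 1");
  XPtr<Xoshiro256> s(stream);
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    double u[3] = {old_dir[0], old_dir[1], old_dir[2]};
    const double ct = hg_cos_theta(s->unif(), g);
    const double phi = 2.0 * M_PI * s->unif();
    deflect_direction(u, ct, phi);
    out(i, 0) = u[0]; out(i, 1) = u[1]; out(i, 2) = u[2];
  }
  return out;
}

// [[Rcpp::export]]
NumericVector rcpp_free_path(NumericVector xi, double mu_a, double mu_s) {
  const double mut = mu_a + mu_s;
  if (mut <= 0) stop("mu_a + mu_s must be positive");
  NumericVector out(xi.size());
  for (int i = 0; i < xi.size(); ++i) {
    if (xi[i] <= 0 || xi[i] > 1) stop("xi must lie in (0, 1]");
    out[i] = -std::log(xi[i]) / mut;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector rcpp_sample_free_path(SEXP stream, double mu_a, double mu_s,
                                    int n) {
  const double mut = mu_a + mu_s;
  if (mut <= 0) stop("mu_a + mu_s must be positive");
  XPtr<Xoshiro256> s(stream);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = -std::log(s->unif_pos()) / mut;
  return out;
}

// ---- boundary physics ------------------------------------------------------

// [[Rcpp::export]]
double rcpp_critical_angle(double n_i, double n_t) {
  if (n_i > n_t) return std::asin(n_t / n_i);
  return M_PI / 2.0;  // no total internal reflection possible
}

// [[Rcpp::export]]
NumericVector rcpp_fresnel(NumericVector theta_i, double n_i, double n_t) {
  NumericVector out(theta_i.size());
  for (int i = 0; i < theta_i.size(); ++i)
    out[i] = fresnel_reflectance_cos(std::cos(theta_i[i]), n_i, n_t);
  return out;
}

// [[Rcpp::export]]
NumericVector rcpp_reflect(NumericVector I, NumericVector N) {
  double v[3] = {I[0], I[1], I[2]};
  const double nn[3] = {N[0], N[1], N[2]};
  reflect_direction(v, nn);
  return NumericVector::create(v[0], v[1], v[2]);
}

// [[Rcpp::export]]
NumericVector rcpp_refract(NumericVector I, NumericVector N, double n_i,
                           double n_t) {
  double v[3] = {I[0], I[1], I[2]};
  const double nn[3] = {N[0], N[1], N[2]};
  refract_direction(v, nn, n_i, n_t);
  return NumericVector::create(v[0], v[1], v[2]);
}

// [[Rcpp::export]]
NumericVector rcpp_roulette(SEXP stream, NumericVector W, int m) {
  if (m <= 1) stop("roulette m must exceed 1");
  XPtr<Xoshiro256> s(stream);
  NumericVector out(W.size());
  for (int i = 0; i < W.size(); ++i)
    out[i] = (s->unif() <= 1.0 / m) ? m * W[i] : 0.0;
  return out;
}

// ---- geometry queries ------------------------------------------------------

// [[Rcpp::export]]
LogicalVector rcpp_points_in_shape(List shape, NumericMatrix p) {
  Shape sh = shape_from_list(shape);
  LogicalVector out(p.nrow());
  for (int i = 0; i < p.nrow(); ++i) {
    const double q[3] = {p(i, 0), p(i, 1), p(i, 2)};
    out[i] = sh.contains(q);
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix rcpp_sample_in_shape(List shape, SEXP stream, int n) {
  Shape sh = shape_from_list(shape);
  XPtr<Xoshiro256> s(stream);
  NumericMatrix out(n, 3);
  double p[3];
  double lo[3], hi[3];
  sh.bbox(lo, hi);
  long attempts = 0;
  for (int i = 0; i < n; ++i) {
    long rej = 0;
    for (;;) {
      ++attempts;
      for (int k = 0; k < 3; ++k) p[k] = lo[k] + (hi[k] - lo[k]) * s->unif();
      if (sh.contains(p)) break;
      if (++rej >= 1000000L)
        stop("degenerate source: 1e6 consecutive rejections while sampling");
    }
    out(i, 0) = p[0]; out(i, 1) = p[1]; out(i, 2) = p[2];
  }
  out.attr("attempts") = (double)attempts;
  return out;
}

// [[Rcpp::export]]
double rcpp_ray_triangle(NumericVector p, NumericVector d, NumericMatrix tri) {
  const double pp[3] = {p[0], p[1], p[2]};
  const double dd[3] = {d[0], d[1], d[2]};
  const double a[3] = {tri(0, 0), tri(0, 1), tri(0, 2)};
  const double b[3] = {tri(1, 0), tri(1, 1), tri(1, 2)};
  const double c[3] = {tri(2, 0), tri(2, 1), tri(2, 2)};
  // degenerate triangle -> miss
  double e1[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
  double e2[3] = {c[0] - a[0], c[1] - a[1], c[2] - a[2]};
  double nn[3];
  cross3(e1, e2, nn);
  if (norm3(nn) < 1e-18) return -1.0;
  const double t = ray_triangle(pp, dd, a, b, c);
  return (t > kHitEps) ? t : -1.0;
}

// [[Rcpp::export]]
int rcpp_scene_locate(List scene, NumericVector p) {
  Scene sc = scene_from_list(scene);
  const double q[3] = {p[0], p[1], p[2]};
  const int i = sc.locate(q);
  return i < 0 ? 0 : sc.regs[i].id;
}

// [[Rcpp::export]]
List rcpp_nearest_hit(List scene, int current_id, NumericVector p,
                      NumericVector d) {
  Scene sc = scene_from_list(scene);
  int cur = -1;
  for (size_t i = 0; i < sc.regs.size(); ++i)
    if (sc.regs[i].id == current_id) cur = (int)i;
  if (cur < 0) stop("unknown region id %d", current_id);
  const double q[3] = {p[0], p[1], p[2]};
  if (!sc.regs[cur].shape.contains(q))
    stop("geometry inconsistency: point is not inside region %d", current_id);
  const double dd[3] = {d[0], d[1], d[2]};
  Hit h;
  int owner;
  if (!sc.nearest_boundary(cur, q, dd, h, owner))
    return List::create(Named("hit") = false);
  const double past[3] = {q[0] + (h.t + kNudge) * dd[0],
                          q[1] + (h.t + kNudge) * dd[1],
                          q[2] + (h.t + kNudge) * dd[2]};
  const int nxt = sc.locate(past);
  return List::create(
      Named("hit") = true, Named("distance") = h.t,
      Named("point") = NumericVector::create(q[0] + h.t * dd[0],
                                             q[1] + h.t * dd[1],
                                             q[2] + h.t * dd[2]),
      Named("normal") = NumericVector::create(h.n[0], h.n[1], h.n[2]),
      Named("surface_region") = sc.regs[owner].id,
      Named("next_region") = nxt < 0 ? 0 : sc.regs[nxt].id,
      Named("element") = h.elem);
}

// smallest positive hit distance of a ray with one shape, or -1
// [[Rcpp::export]]
NumericVector rcpp_shape_ray_distance(List shape, NumericMatrix origins,
                                      NumericMatrix dirs) {
  Shape sh = shape_from_list(shape);
  const int n = origins.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const double p[3] = {origins(i, 0), origins(i, 1), origins(i, 2)};
    double d[3] = {dirs(i, 0), dirs(i, 1), dirs(i, 2)};
    normalize3(d);
    Hit h;
    out[i] = sh.ray_hit(p, d, h) ? h.t : -1.0;
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix rcpp_shape_bbox(List shape) {
  Shape sh = shape_from_list(shape);
  double lo[3], hi[3];
  sh.bbox(lo, hi);
  NumericMatrix out(2, 3);
  for (int i = 0; i < 3; ++i) { out(0, i) = lo[i]; out(1, i) = hi[i]; }
  return out;
}
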