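#include <Rcpp.h>
#include <vector>
#include "xoshiro.h"
#include "geometry.h"
#include "physics.h"
#include "parse.h"

using namespace Rcpp;
using namespace pmc;

namespace {

struct Tally {
  std::vector<double> grid;
  std::vector<double> exits;  // x, y, z, weight, element per event
  double absorbed = 0, transmitted = 0, lost = 0;
  long n_roulette_kill = 0, n_roulette_survive = 0, n_cap_kill = 0;
  long n_geom_lost = 0;
  long long n_steps = 0;
};

struct GridSpec {
  double lo[3];
  int dim[3];
  double pitch;
  inline long voxel(const double* p) const {
    int ix = (int)std::floor((p[0] - lo[0]) / pitch);
    int iy = (int)std::floor((p[1] - lo[1]) / pitch);
    int iz = (int)std::floor((p[2] - lo[2]) / pitch);
    if (ix < 0) ix = 0; if (ix >= dim[0]) ix = dim[0] - 1;
    if (iy < 0) iy = 0; if (iy >= dim[1]) iy = dim[1] - 1;
    if (iz < 0) iz = 0; if (iz >= dim[2]) iz = dim[2] - 1;
    return (long)ix + (long)dim[0] * ((long)iy + (long)dim[1] * (long)iz);
  }
};

void trace_packet(const Scene& sc, const Shape& src_shape, double packet_power,
                  double roulette_threshold, int roulette_m, long max_events,
                  const GridSpec& gs, bool record_exits, Xoshiro256& rng,
                  Tally& tl) {
  double pos[3], dir[3];
  if (!sample_in_shape(src_shape, rng, pos))
    stop("degenerate source: 1e6 consecutive rejections while sampling");
  isotropic_direction(rng.unif(), rng.unif(), dir);
  int reg = sc.locate(pos);
  if (reg < 0) stop("source sample at (%g, %g, %g) lies outside the scene",
                    pos[0], pos[1], pos[2]);
  double W = packet_power;
  double tau = 0.0;  // dimensionless residual optical path
  long events = 0;
  const double inv_m = 1.0 / roulette_m;

  while (true) {
    if (++events > max_events) { tl.lost += W; ++tl.n_cap_kill; break; }
    ++tl.n_steps;
    const Region& R = sc.regs[reg];
    const double mut = R.mua + R.mus;
    if (mut <= 0.0)
      stop("region %d has mu_a + mu_s == 0; vacuum regions are not tissues",
           R.id);
    if (tau <= 0.0) tau = -std::log(rng.unif_pos());
    const double s = tau / mut;

    Hit h;
    int owner;
    const bool found = sc.nearest_boundary(reg, pos, dir, h, owner);
    if (found && h.t <= s) {
      // boundary interrupts the free path; carry the residual optical path
      for (int i = 0; i < 3; ++i) pos[i] += h.t * dir[i];
      tau -= h.t * mut;
      if (tau < 0) tau = 0;
      double past[3];
      for (int i = 0; i < 3; ++i) past[i] = pos[i] + kNudge * dir[i];
      const int nxt = sc.locate(past);
      const double ni = R.n;
      const double nt = (nxt < 0) ? sc.ambient_n : sc.regs[nxt].n;
      bool transmit = true;
      if (std::fabs(ni - nt) > 1e-12) {
        const double cos_i = std::min(1.0, std::fabs(dot3(dir, h.n)));
        const double Rf = fresnel_reflectance_cos(cos_i, ni, nt);
        if (rng.unif() <= Rf) {
          transmit = false;
          reflect_direction(dir, h.n);
        } else {
          refract_direction(dir, h.n, ni, nt);
        }
      }
      if (transmit && nxt < 0) {
        tl.transmitted += W;
        if (record_exits) {
          tl.exits.push_back(pos[0]);
          tl.exits.push_back(pos[1]);
          tl.exits.push_back(pos[2]);
          tl.exits.push_back(W);
          tl.exits.push_back((double)h.elem);
        }
        break;
      }
      if (transmit) reg = nxt;
      for (int i = 0; i < 3; ++i) pos[i] += kNudge * dir[i];
    } else if (found) {
      // free path completes inside the region: absorb then scatter
      for (int i = 0; i < 3; ++i) pos[i] += s * dir[i];
      tau = 0.0;
      const double dW = W * R.mua / mut;
      W -= dW;
      tl.absorbed += dW;
      tl.grid[gs.voxel(pos)] += dW;
      if (W <= 0.0) break;
      if (W < roulette_threshold) {
        if (rng.unif() <= inv_m) {
          W *= roulette_m;
          ++tl.n_roulette_survive;
        } else {
          ++tl.n_roulette_kill;
          break;
        }
      }
      const double ct = hg_cos_theta(rng.unif(), R.g);
      const double phi = 2.0 * M_PI * rng.unif();
      deflect_direction(dir, ct, phi);
    } else {
      // no surface ahead: geometry is not closed along this ray
      tl.lost += W;
      ++tl.n_geom_lost;
      break;
    }
  }
}

}  // namespace

// [[Rcpp::export]]
List rcpp_run(List scene_list, List source_shape, double total_power,
              double n_packets, int n_workers, double master_seed,
              NumericVector grid_lo, IntegerVector grid_dim, double pitch,
              double roulette_threshold_frac, int roulette_m,
              double max_events, bool record_exits) {
  if (n_packets < 1) stop("n_packets must be >= 1");
  if (n_workers < 1) stop("n_workers must be >= 1");
  Scene sc = scene_from_list(scene_list);
  Shape src = shape_from_list(source_shape);

  GridSpec gs;
  for (int i = 0; i < 3; ++i) { gs.lo[i] = grid_lo[i]; gs.dim[i] = grid_dim[i]; }
  gs.pitch = pitch;
  const long ncell = (long)gs.dim[0] * gs.dim[1] * gs.dim[2];

  const double packet_power = total_power / n_packets;
  const double threshold = roulette_threshold_frac * packet_power;

  Tally master;
  master.grid.assign(ncell, 0.0);

  const long n_total = (long)n_packets;
  const long base = n_total / n_workers;
  const long extra = n_total % n_workers;

  Xoshiro256 rng((uint64_t)master_seed);
  for (int w = 0; w < n_workers; ++w) {
    // worker substream: master seed jumped w times (2^128 apart)
    if (w > 0) rng.jump();
    Xoshiro256 worker_rng = rng;
    const long n_w = base + (w < extra ? 1 : 0);
    Tally tl;
    tl.grid.assign(ncell, 0.0);
    for (long k = 0; k < n_w; ++k) {
      trace_packet(sc, src, packet_power, threshold, roulette_m,
                   (long)max_events, gs, record_exits, worker_rng, tl);
      if ((k & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
    }
    // merge worker tallies into the host tally in worker order
    for (long i = 0; i < ncell; ++i) master.grid[i] += tl.grid[i];
    master.exits.insert(master.exits.end(), tl.exits.begin(), tl.exits.end());
    master.absorbed += tl.absorbed;
    master.transmitted += tl.transmitted;
    master.lost += tl.lost;
    master.n_roulette_kill += tl.n_roulette_kill;
    master.n_roulette_survive += tl.n_roulette_survive;
    master.n_cap_kill += tl.n_cap_kill;
    master.n_geom_lost += tl.n_geom_lost;
    master.n_steps += tl.n_steps;
  }

  NumericVector grid(master.grid.begin(), master.grid.end());
  grid.attr("dim") = IntegerVector::create(gs.dim[0], gs.dim[1], gs.dim[2]);

  const long n_exit = (long)(master.exits.size() / 5);
  NumericMatrix exits(n_exit, 5);
  for (long i = 0; i < n_exit; ++i)
    for (int j = 0; j < 5; ++j) exits(i, j) = master.exits[5 * i + j];

  return List::create(
      Named("absorption") = grid, Named("exits") = exits,
      Named("n_launched") = (double)n_total,
      Named("packet_power") = packet_power,
      Named("absorbed") = master.absorbed,
      Named("transmitted") = master.transmitted,
      Named("lost") = master.lost,
      Named("n_roulette_kill") = (double)master.n_roulette_kill,
      Named("n_roulette_survive") = (double)master.n_roulette_survive,
      Named("n_cap_kill") = (double)master.n_cap_kill,
      Named("n_geom_lost") = (double)master.n_geom_lost,
      Named("n_steps") = (double)master.n_steps);
}
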