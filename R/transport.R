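# The photon-packet Monte Carlo engine and its sampling primitives.
#
# A packet carries power weight W = total source power / packet count.  Its
# life cycle: birth uniformly inside the source shape with an isotropic
# direction; exponential free paths with rate mu_t = mu_a + mu_s; at the end
# of a completed free path it deposits dW = W mu_a / mu_t into the voxel at
# the interaction site and scatters through a Henyey-Greenstein deflection;
# a boundary reached mid-path triggers a Fresnel reflect-or-refract event
# (the unconsumed dimensionless path is carried across and rescaled by the
# new medium's mu_t); weights below the roulette threshold survive with
# probability 1/m at weight mW or die; escape to the ambient medium records
# the residual weight in the transmission tally.

#' Internal isotropic light source
#'
#' @param shape A [shapes] object with positive volume, lying inside a tissue
#'   region of the scene it is used with.  Sources are emissive only: packets
#'   start transport in the enclosing tissue, and the source volume has no
#'   optical properties of its own.
#' @param power Total emitted power in W.
#' @return A list of class `photon_source`.
#' @examples
#' source_spec(shape_cylinder(center = c(8, 0, 0), radius = 1, height = 2),
#'             power = 1e-9)
#' @export
source_spec <- function(shape, power) {
  stopifnot(inherits(shape, "photon_shape"))
  if (!is.numeric(power) || power <= 0) abort("source power must be positive")
  structure(list(shape = shape, power = power), class = "photon_source")
}

#' Sample initial packet positions inside a source
#'
#' Draws axis-aligned uniform candidates over the source bounding box
#' (x = xmin + (xmax - xmin) xi, and likewise in y, z) and rejects candidates
#' outside the shape, redrawing until one is accepted.
#'
#' @param src A [source_spec()] (or a bare shape).
#' @param stream A [substreams()] stream.
#' @param n Number of positions.
#' @return Tibble with columns `x`, `y`, `z` (mm).
#' @export
sample_source_position <- function(src, stream, n = 1) {
  shape <- if (inherits(src, "photon_source")) src$shape else src
  stopifnot(inherits(shape, "photon_shape"), inherits(stream, "photon_stream"))
  m <- rcpp_sample_in_shape(unclass(shape), stream$ptr, as.integer(n))
  tibble(x = m[, 1], y = m[, 2], z = m[, 3])
}

#' Isotropic emission directions
#'
#' `isotropic_direction()` maps the two unit draws deterministically:
#' `phi = 2 pi xi_phi`, `theta = acos(2 xi_theta - 1)`, direction
#' `(sin theta cos phi, sin theta sin phi, cos theta)` - uniform on the unit
#' sphere.  `sample_isotropic_direction()` draws the pair from a stream.
#'
#' @param xi_phi,xi_theta Uniform unit numbers in `[0, 1)`.
#' @param stream A [substreams()] stream.
#' @param n Number of directions.
#' @return Tibble with unit-norm columns `dx`, `dy`, `dz`.
#' @export
isotropic_direction <- function(xi_phi, xi_theta) {
  m <- rcpp_isotropic_dir(as.numeric(xi_phi), as.numeric(xi_theta))
  tibble(dx = m[, 1], dy = m[, 2], dz = m[, 3])
}

#' @rdname isotropic_direction
#' @export
sample_isotropic_direction <- function(stream, n = 1) {
  stopifnot(inherits(stream, "photon_stream"))
  m <- rcpp_sample_isotropic(stream$ptr, as.integer(n))
  tibble(dx = m[, 1], dy = m[, 2], dz = m[, 3])
}

#' Exponential free path
#'
#' `free_path()` is the deterministic inverse-CDF map
#' `s = -log(xi) / (mu_a + mu_s)`; `sample_free_path()` draws `xi` from a
#' stream (zero remapped to the next draw).
#'
#' @param xi Uniform unit numbers in `(0, 1]`.
#' @param props An [optical_properties()].
#' @param stream A [substreams()] stream.
#' @param n Number of draws.
#' @return Numeric path lengths (mm).
#' @export
free_path <- function(xi, props) {
  rcpp_free_path(as.numeric(xi), props$mu_a, props$mu_s)
}

#' @rdname free_path
#' @export
sample_free_path <- function(props, stream, n = 1) {
  stopifnot(inherits(stream, "photon_stream"))
  rcpp_sample_free_path(stream$ptr, props$mu_a, props$mu_s, as.integer(n))
}

#' Absorption deposit of one interaction
#'
#' At the end of a completed free path a packet of weight `w` deposits
#' `delta_w = w * mu_a / (mu_a + mu_s)` at the interaction site.
#'
#' @param w Packet weight(s) (W).
#' @param props An [optical_properties()].
#' @return Tibble with columns `delta_w` (deposited) and `w_after`.
#' @export
deposit_absorption <- function(w, props) {
  frac <- props$mu_a / (props$mu_a + props$mu_s)
  tibble(delta_w = w * frac, w_after = w * (1 - frac))
}

#' Henyey-Greenstein scattering
#'
#' `hg_cos_theta()` is the inverse-CDF deflection cosine: for `g != 0`,
#' `cos theta = (1 + g^2 - ((1 - g^2) / (1 - g + 2 g xi))^2) / (2 g)`;
#' for `g = 0`, `cos theta = 2 xi - 1`.  `sample_scatter_direction()` draws
#' the deflection and a uniform azimuth and rotates them into the frame whose
#' z-axis is the previous direction.
#'
#' @param xi Uniform unit numbers.
#' @param g Anisotropy factor in (-1, 1).
#' @param old_dir Length-3 unit direction before scattering.
#' @param stream A [substreams()] stream.
#' @param n Number of directions.
#' @return `hg_cos_theta()`: numeric cosines; `sample_scatter_direction()`:
#'   tibble with unit columns `dx`, `dy`, `dz`.
#' @export
hg_cos_theta <- function(xi, g) {
  if (abs(g) >= 1) abort("anisotropy g must satisfy -1 < g < 1")
  rcpp_hg_cos(as.numeric(xi), g)
}

#' @rdname hg_cos_theta
#' @export
sample_scatter_direction <- function(old_dir, g, stream, n = 1) {
  stopifnot(inherits(stream, "photon_stream"), length(old_dir) == 3)
  m <- rcpp_sample_scatter(stream$ptr, as.numeric(old_dir), g, as.integer(n))
  tibble(dx = m[, 1], dy = m[, 2], dz = m[, 3])
}

#' Critical angle for total internal reflection
#'
#' `asin(n_t / n_i)` when passing into a rarer medium (`n_i > n_t`);
#' otherwise `pi / 2`: no incidence angle can totally reflect when entering
#' an equally dense or denser medium, so Fresnel reflectance applies at all
#' angles.
#'
#' @param n_i,n_t Refractive indices of the incident and far-side media.
#' @return Critical angle in radians.
#' @export
critical_angle <- function(n_i, n_t) {
  stopifnot(n_i >= 1, n_t >= 1)
  rcpp_critical_angle(n_i, n_t)
}

#' Unpolarized Fresnel reflectance
#'
#' The average of the s- and p-polarized reflectances,
#' `R = (sin^2(ti - tt) / sin^2(ti + tt) + tan^2(ti - tt) / tan^2(ti + tt)) / 2`
#' with the transmission angle from Snell's law `n_i sin ti = n_t sin tt`.
#' Beyond the critical angle `R = 1`; normal incidence uses the analytic
#' limit `((n_i - n_t) / (n_i + n_t))^2`.
#'
#' @param theta_i Incidence angle(s) in radians, in `[0, pi/2]`.
#' @param n_i,n_t Refractive indices.
#' @return Reflectance in `[0, 1]`, vectorized over `theta_i`.
#' @examples
#' fresnel_reflectance(0, 1, 1.5)  # 0.04
#' @export
fresnel_reflectance <- function(theta_i, n_i, n_t) {
  stopifnot(all(theta_i >= 0), all(theta_i <= pi / 2 + 1e-12))
  rcpp_fresnel(as.numeric(theta_i), n_i, n_t)
}

#' Specular reflection and refraction of a direction
#'
#' `reflect_direction()`: `R = I - 2 (I . N) N`.  `refract_direction()` bends
#' `I` across the interface: the unit tangential component scaled to
#' `sin theta_t` plus `sign(I . N) cos theta_t N`.
#'
#' @param I Incident unit direction (length 3).
#' @param N Boundary unit normal (length 3).
#' @param n_i,n_t Refractive indices on the incident and far sides.
#' @return Unit direction vector (length 3).
#' @export
reflect_direction <- function(I, N) {
  check_unit(I, "I"); check_unit(N, "N")
  rcpp_reflect(as.numeric(I), as.numeric(N))
}

#' @rdname reflect_direction
#' @export
refract_direction <- function(I, N, n_i, n_t) {
  check_unit(I, "I"); check_unit(N, "N")
  rcpp_refract(as.numeric(I), as.numeric(N), n_i, n_t)
}

check_unit <- function(v, name) {
  if (length(v) != 3 || abs(sqrt(sum(v^2)) - 1) > 1e-9)
    abort(sprintf("%s must be a unit-norm length-3 vector", name))
}

#' Russian roulette termination
#'
#' A low-weight packet survives with probability `1/m` at amplified weight
#' `m * w`, otherwise its weight drops to zero - an unbiased termination rule.
#'
#' @param w Packet weight(s) (W).
#' @param stream A [substreams()] stream.
#' @param m Survival denominator (> 1; default 10).
#' @return Numeric post-roulette weights (either `m * w` or `0`).
#' @export
roulette <- function(w, stream, m = 10) {
  stopifnot(inherits(stream, "photon_stream"))
  if (m <= 1) abort("roulette m must exceed 1")
  rcpp_roulette(stream$ptr, as.numeric(w), as.integer(m))
}

#' Run a photon-packet Monte Carlo simulation
#'
#' Traces `n_packets` packets from an internal isotropic source through the
#' scene's region tree, accumulating absorbed power on a voxel grid covering
#' the root region's bounding box and escaped power as per-packet exit events
#' on the outer surface.  Work is split across `workers` logical workers,
#' each drawing from its own non-overlapping random substream
#' (jump-ahead partitioning); per-worker tallies are summed in worker order,
#' so results for a given `(seed, workers)` pair are bit-identical across
#' runs, and different `workers` values agree within Monte Carlo noise.
#'
#' @param scene A [scene()].
#' @param source A [source_spec()] whose shape lies inside the scene.
#' @param n_packets Number of photon packets (each carries
#'   `power / n_packets` W).
#' @param seed Integer master seed.
#' @param workers Number of logical workers (substreams).
#' @param voxel_pitch Absorption-grid voxel edge (mm).
#' @param roulette_threshold Roulette trigger as a fraction of the initial
#'   packet weight.
#' @param roulette_m Roulette survival denominator.
#' @param max_events Per-packet event cap; packets exceeding it are killed
#'   and their weight booked as lost.
#' @param record_exits Keep per-packet exit events (needed for surface maps).
#' @return A `photon_sim` object: `absorption` (3D array, W per voxel),
#'   `grid` (origin/pitch/dim), `exits` (tibble: `x`, `y`, `z`, `weight`,
#'   `element`), and a `summary` list (launched/absorbed/transmitted/lost
#'   power, event counts).  Use [glance()] for a one-row summary and
#'   [tidy()] for the exit events.
#' @examples
#' \donttest{
#' fx <- homogeneous_cylinder_phantom()
#' sim <- simulate_photons(fx$scene, fx$source, n_packets = 2000, seed = 1)
#' glance(sim)
#' }
#' @export
simulate_photons <- function(scene, source, n_packets, seed = 1, workers = 1,
                             voxel_pitch = 0.5, roulette_threshold = 1e-4,
                             roulette_m = 10, max_events = 1e6,
                             record_exits = TRUE) {
  stopifnot(inherits(scene, "photon_scene"), inherits(source, "photon_source"))
  if (n_packets < 1) abort("n_packets must be >= 1")
  root <- scene_root(scene)
  bb <- shape_bbox(root$shape)
  dim <- pmax(1L, as.integer(ceiling((bb["hi", ] - bb["lo", ]) / voxel_pitch - 1e-9)))
  res <- rcpp_run(scene_as_list(scene), unclass(source$shape), source$power,
                  as.double(n_packets), as.integer(workers), as.double(seed),
                  as.numeric(bb["lo", ]), dim, voxel_pitch,
                  roulette_threshold, as.integer(roulette_m),
                  as.double(max_events), record_exits)
  exits <- res$exits
  colnames(exits) <- c("x", "y", "z", "weight", "element")
  structure(list(
    absorption = res$absorption,
    grid = list(lo = as.numeric(bb["lo", ]), pitch = voxel_pitch, dim = dim),
    exits = as_tibble(as.data.frame(exits)),
    summary = list(
      n_packets = n_packets, packet_power = res$packet_power,
      launched = res$packet_power * n_packets,
      absorbed = res$absorbed, transmitted = res$transmitted,
      lost = res$lost, n_roulette_kill = res$n_roulette_kill,
      n_roulette_survive = res$n_roulette_survive,
      n_cap_kill = res$n_cap_kill, n_geom_lost = res$n_geom_lost,
      n_steps = res$n_steps),
    scene = scene, source = source,
    controls = list(seed = seed, workers = workers, voxel_pitch = voxel_pitch,
                    roulette_threshold = roulette_threshold,
                    roulette_m = roulette_m, max_events = max_events)),
    class = "photon_sim")
}

#' @export
print.photon_sim <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<photon_sim> %s packets (seed %s, %d worker(s))\n",
              format(s$n_packets, big.mark = ","),
              format(x$controls$seed), x$controls$workers))
  cat(sprintf("  launched    %.4g W\n", s$launched))
  cat(sprintf("  absorbed    %.4g W (%.2f%%)\n", s$absorbed,
              100 * s$absorbed / s$launched))
  cat(sprintf("  transmitted %.4g W (%.2f%%)\n", s$transmitted,
              100 * s$transmitted / s$launched))
  cat(sprintf("  lost (caps) %.4g W; %g roulette kills, %g survivals\n",
              s$lost, s$n_roulette_kill, s$n_roulette_survive))
  invisible(x)
}

#' @describeIn simulate_photons One-row run summary (powers in W).
#' @param x,... Method arguments.
#' @export
glance.photon_sim <- function(x, ...) {
  s <- x$summary
  tibble(n_packets = s$n_packets, packet_power = s$packet_power,
         launched = s$launched, absorbed = s$absorbed,
         transmitted = s$transmitted, lost = s$lost,
         energy_closure = (s$absorbed + s$transmitted + s$lost) / s$launched,
         n_roulette_kill = s$n_roulette_kill,
         n_roulette_survive = s$n_roulette_survive,
         n_cap_kill = s$n_cap_kill, n_steps = s$n_steps,
         seed = x$controls$seed, workers = x$controls$workers)
}

#' @describeIn simulate_photons Exit events as a tibble (`x`, `y`, `z` exit
#'   point in mm, `weight` escaped power in W, `element` surface part or mesh
#'   face id).
#' @export
tidy.photon_sim <- function(x, ...) x$exits

#' Absorption grid as a tidy table
#'
#' @param sim A `photon_sim`.
#' @param drop_empty Drop zero-valued voxels.
#' @return Tibble with voxel centers `x`, `y`, `z` (mm) and `absorbed` (W).
#' @export
absorption_table <- function(sim, drop_empty = TRUE) {
  g <- sim$grid
  idx <- which(sim$absorption != 0 | !drop_empty, arr.ind = TRUE)
  tibble(x = g$lo[1] + (idx[, 1] - 0.5) * g$pitch,
         y = g$lo[2] + (idx[, 2] - 0.5) * g$pitch,
         z = g$lo[3] + (idx[, 3] - 0.5) * g$pitch,
         absorbed = sim$absorption[idx])
}

#' Agreement of two absorption tallies
#'
#' Compares per-voxel absorbed power of two runs of the same configuration
#' (e.g. different worker counts).  The pooled standard error per voxel is
#' bounded by `sqrt((v1 + v2) * w_max)` where `w_max` is the initial packet
#' weight - an upper bound on any single deposit - so the reported fraction
#' of voxels within `k` pooled SE is conservative.
#'
#' @param a,b `photon_sim` objects on identical grids.
#' @param k Tolerance in pooled standard errors.
#' @return One-row tibble: `n_voxels` (nonempty), `fraction_within`,
#'   `max_sigma` (largest discrepancy in pooled-SE units).
#' @export
tally_agreement <- function(a, b, k = 5) {
  stopifnot(all(dim(a$absorption) == dim(b$absorption)))
  va <- as.numeric(a$absorption)
  vb <- as.numeric(b$absorption)
  keep <- va > 0 | vb > 0
  va <- va[keep]; vb <- vb[keep]
  wmax <- max(a$summary$packet_power, b$summary$packet_power)
  se <- sqrt((va + vb) * wmax)
  z <- abs(va - vb) / se
  tibble(n_voxels = sum(keep), fraction_within = mean(z < k),
         max_sigma = max(z))
}
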