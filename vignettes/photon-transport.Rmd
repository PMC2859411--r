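---
title: "Photon-packet Monte Carlo transport and lens-coupled detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Photon-packet Monte Carlo transport and lens-coupled detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photonmc)
```

photonmc simulates steady-state light propagation from an internal isotropic
source — the situation of bioluminescence-style optical molecular imaging —
in two stages: a photon-packet Monte Carlo solver for the turbid tissue
interior, and a radiosity-radiance model that carries the escaped surface
flux through free space onto a lens-coupled planar detector. This vignette
documents the model, its tunable parameters, the numerical choices, and what
the bundled phantoms and tests do and do not establish.

## The transport model

Light in tissue is described by the radiative transport equation; the
package solves it by direct stochastic simulation of *photon packets*. A
packet is not a photon: it is an abstract carrier of power. With a source of
total power $P_0$ and $N$ packets, each starts with weight
$W_0 = P_0 / N$ watts, so every tally is an estimate of a steady-state
power, not an energy.

Each region of the scene is homogeneous with absorption coefficient
$\mu_a$ (mm$^{-1}$), scattering coefficient $\mu_s$ (mm$^{-1}$), scattering
anisotropy $g \in (-1, 1)$ and refractive index $n \ge 1$. The packet life
cycle is:

1. **Birth.** The position is drawn uniformly inside the source shape by
   rejection from its bounding box, $x = x_{\min} + (x_{\max} - x_{\min})\xi$
   per axis; candidates outside the shape are redrawn. The direction is
   uniform on the sphere: $\varphi = 2\pi\xi_\varphi$,
   $\theta = \arccos(2\xi_\theta - 1)$. Sources are emissive only — the
   source volume has no optical properties, and transport starts in the
   enclosing tissue.
2. **Free flight.** Step lengths are exponential with rate
   $\mu_t = \mu_a + \mu_s$, sampled as $s = -\ln\xi / \mu_t$ (an exact zero
   draw is remapped before the logarithm).
3. **Interaction.** If the step completes without reaching a boundary, the
   packet deposits $\Delta W = W \mu_a / \mu_t$ into the absorption voxel at
   the interaction site and scatters: the deflection cosine follows the
   Henyey-Greenstein distribution,
   $\cos\theta = \frac{1}{2g}\left[1 + g^2 - \left(\frac{1 - g^2}{1 - g + 2g\xi}\right)^2\right]$
   for $g \ne 0$ and $\cos\theta = 2\xi - 1$ for $g = 0$, with uniform
   azimuth, rotated into the frame whose z-axis is the incoming direction.
4. **Boundary events.** A boundary reached mid-step triggers a Fresnel
   decision. With incidence angle $\theta_i$ and Snell's law
   $n_i \sin\theta_i = n_t \sin\theta_t$, the unpolarized reflectance is
   $R = \tfrac12\left[\frac{\sin^2(\theta_i - \theta_t)}{\sin^2(\theta_i + \theta_t)} + \frac{\tan^2(\theta_i - \theta_t)}{\tan^2(\theta_i + \theta_t)}\right]$,
   with the analytic limit $((n_i - n_t)/(n_i + n_t))^2$ at normal incidence
   and $R = 1$ beyond the critical angle
   $\theta_c = \arcsin(n_t/n_i)$ (which exists only for $n_i > n_t$; when
   entering an equally dense or denser medium no angle reflects totally and
   Fresnel applies throughout). Rather than splitting the packet, a single
   uniform draw reflects it totally ($\xi \le R$, direction
   $I - 2(I \cdot N)N$) or transmits it totally (direction bent by Snell's
   law); the weight is unchanged either way.
5. **Termination.** Escape into the ambient medium records the residual
   weight as a transmission (exit) event at the crossing point. Weights that
   fall below a threshold face Russian roulette: survival with probability
   $1/m$ at weight $mW$, death otherwise — unbiased in expectation.

### Residual path across boundaries

The model is silent in many published descriptions on what happens to the
unconsumed part of a step interrupted by a boundary. photonmc carries the
*dimensionless* residual $\tau = s_{\text{remaining}} \mu_t$ across the
interface and rescales it by the new medium's $\mu_t$ — the convention of
the multi-layer reference codes. Re-sampling a fresh step instead would bias
transport through thin layers toward too many interactions.

### Where deposits happen

Absorption and scattering occur only at the end of a *completed* free path,
and the deposit is booked at the interaction site (the end of the step), not
at its start. For any one interaction the deposited fraction is exactly the
single-interaction albedo complement $\mu_a/\mu_t$, which the tests exploit
as a closed-form identity.

## Parallel substreams and reproducibility

Runs are split across logical workers. Each worker draws from its own
substream of a xoshiro256++ generator: worker $k$ uses the master-seeded
state advanced by $k$ jumps of $2^{128}$ states, so substreams are pairwise
non-overlapping *by construction* — the guarantee a contiguous partition of
one sequence is meant to provide, but provable and generator-agnostic. A
literal "first number of each subsequence becomes that worker's seed" scheme
is only correct for generators whose output equals their state, so the
package mandates jump-ahead partitioning instead. Per-worker tallies are
summed in worker order, making a run bit-identical for a fixed
`(seed, workers)` pair; different worker counts agree within Monte Carlo
noise. One R-level consequence: `simulate_photons()` never touches R's own
RNG state.

## Geometry

Scenes are containment trees: one root region (the organism outline) with
nested inclusions. Analytic shapes (cylinder, sphere, ellipsoid, box; all
axes along z, lengths in mm) are first-class and exact; closed triangle
meshes (OFF/PLY/STL) are supported with validation of closedness and
consistent outward orientation at load. Membership is a strict interior
test; points within about $10^{-9}$ mm of a surface may resolve to either
side, and after every boundary event the packet is nudged $10^{-7}$ mm along
its new direction to avoid re-intersection. Ray-triangle tests use a
Möller-Trumbore formulation with $10^{-12}$ barycentric slack; zero-area
triangles warn once at load and are ignored thereafter. A packet landing
exactly on a shared edge or vertex is resolved by the same epsilon nudge — a
choice, not a published convention.

Sibling regions are required to be disjoint and children to lie inside
their parents; validation samples points inside each child and checks them
against the parent and every sibling. Under the `"clip"` policy (used by
the heterogeneous fixture, below) violations are recorded rather than
fatal, and membership is resolved by clipping: ancestors clip descendants,
and the first-listed sibling wins where siblings overlap. The transport
loop re-locates the region after *every* crossing, so the discretization
stays self-consistent even for clipped geometry, at the cost that a clipped
region's effective shape is its printed shape minus whatever higher-priority
regions cover.

## Tallies

* **Absorption** accumulates on a voxel grid covering the root region's
  bounding box; the default pitch of 0.5 mm resolves the bundled phantoms
  while keeping the grid small, and is configurable (the Beer-Lambert
  acceptance check uses 0.1 mm to keep voxel-center binning error well under
  its 1 % tolerance).
* **Transmission** is kept as per-packet exit events (position, weight,
  surface element). For a cylindrical root the events are binned onto the
  unwrapped side surface — rows over $z$, columns over arc length
  $R\varphi$ with $\varphi = 0$ at $+x$ — and divided by the exact patch
  area to give flux density $J_n$ in W/mm$^2$; end caps are tallied
  separately. With a 0.06 mm pixel the 15 mm $\times$ 30 mm cylinder
  unwraps to the canonical 500 $\times$ 1570 raster (the whole number of
  pixels fitting each extent; a misfit beyond half a pixel warns).

Roulette is the only non-conserving step (it trades weight for variance,
unbiased in expectation), so launched = absorbed + transmitted holds to
Monte Carlo accuracy; packets exceeding the per-packet event cap (default
$10^6$) are killed with their weight booked to a "lost" counter that the
run summary reports.

## Free-space model

Each surface element of area $dS$ with flux density $J_n$ radiates as a
Lambertian source of radiance $L = J_n/\pi$. A detector pixel of area $dA$
at distance $d$ receives
$dP = \frac{1}{\pi} J_n \cos\theta_s \cos\theta_d \, dS \, dA / d^2$ —
cosine law at the source, detector foreshortening, inverse-square law.
SIMPLE mode sums this over all elements with sign-of-cosine visibility and
is the well-defined reference model (hemispherical integration over pixels
recovers $J_n dS$, which the tests verify to 1 %).

LENS mode adds a thin-lens system ($1/f = 1/u + 1/v$, magnification
$t = v/u$): a visibility factor that discards elements facing away from the
lens centre (a zero-radiance limb counts as invisible — strict inequality)
or occluded by the root surface, the factor $t^2$, and a modified distance
$|r_d - r - (t\,u_2/(f\cos\theta))\,s|^2$ where $s$ is the unit line of
sight and $\theta$ its angle to the optical axis. The symbol $u_2$ in the
source derivation is not defined self-containedly; photonmc reads it as the
*defocus* — the element's axial distance from the lens minus the in-focus
object distance $u$ — which vanishes on the in-focus plane, reproduces the
advertised depth-of-field behaviour, and recovers the SIMPLE image (times
$t^2$) in the ideal-lens limit $f \to \infty$ at fixed $t$, a limit the
tests check at coarse tolerance. Treat LENS magnitudes as a documented
interpretation, not an externally validated quantity; aperture (f-number)
blur is explicitly out of scope. Pixel powers use the midpoint rule at
pixel centres; one global in-focus plane is assumed.

## The bundled phantoms

`homogeneous_cylinder_phantom()` is a cylinder of radius 15 mm and height
30 mm centred at the origin, $\mu_a = 0.0138$ mm$^{-1}$, *reduced*
scattering $\mu_s' = (1 - g)\mu_s = 0.91$ mm$^{-1}$, with a cylindrical
source (radius 1 mm, height 2 mm, 1 nW) centred at (8, 0, 0) mm. Two
choices deserve comment:

* Only $\mu_s'$ is specified, but transport needs the $(\mu_s, g)$ pair.
  The default $g = 0.9$ (typical of soft tissue) un-reduces to
  $\mu_s = 9.1$ mm$^{-1}$; by the similarity relation the diffusive-regime
  results are insensitive to the split, which a test verifies by comparing
  $g = 0.9$ against $g = 0.7$ profiles at fixed $\mu_s'$.
* The refractive index is unstated. The default is matched ($n = 1$), which
  makes energy-conservation checks exact up to roulette noise; `n = 1.37`
  exercises the mismatched boundary code.

`heterogeneous_phantom()` is the five-tissue cylinder (radius 8 mm, height
20 mm) with a central ellipsoid, two large flanking ellipsoids and a thin
rod, at the tabulated optical properties. As printed the geometry is
neither strictly nested (the flanking ellipsoids extend 2 mm past the
cylinder in z) nor disjoint (the central ellipsoid intersects both
flanking ones, and the rod intersects one), so the fixture is built with
the clip policy described above and attaches its validation report to the
scene. The published source location, (15, 40, 12) mm, lies outside the
phantom entirely in the phantom-centred frame; reading it as a corner-based
frame with the cylinder centre near (15, 40, 10) puts the source 2 mm above
the centre, inside the central ellipsoid, which is where the fixture places
its 0.5 $\times$ 0.5 $\times$ 1 mm ellipsoidal 1 nW source.

### What the phantoms do and do not establish

The fixtures reproduce idealized laboratory geometry: homogeneous analytic
regions, a matched or single-step refractive index, a steady source of
known power, no noise sources other than Monte Carlo counting statistics.
Passing tests on them establishes the correctness of the sampling
distributions, the conservation laws, the boundary physics and the
detector geometry — not fidelity to any particular animal: real tissue has
continuous property gradients, rough surfaces, spectrally varying
coefficients and autofluorescence, none of which are modelled.

## Numerical and statistical choices

* Roulette triggers below $10^{-4} W_0$ with $m = 10$; the threshold is a
  compromise (deep-weight accuracy vs run time) and both are configurable.
* The event cap ($10^6$) exists to bound pathological trajectories; on the
  bundled phantoms it never fires.
* NRMSE between two curves is $\sqrt{\tfrac1N \sum_i (d^1_i - d^2_i)^2}$
  after each is normalized; "normalized flux density" conventions are never
  fully stated alongside such figures, so the package defaults to dividing
  each curve by its own maximum and exposes `"sum"` and `"none"` as
  alternatives.
* Profile extraction takes the raster row whose centre is nearest the
  requested z, ties resolved to the lower row.
* Problem sizes in the shipped tests were chosen to keep the full suite
  within a couple of minutes while leaving comfortable statistical margins:
  unit tests run $10^3$-$10^4$ packets, the end-to-end property checks
  $10^5$ packets ($\approx$ 10 s each), moment checks $10^6$ draws, and the
  surface maps in statistical tests use a 30 $\times$ 90 raster rather than
  the full 500 $\times$ 1570 (whose per-pixel counts would be dominated by
  shot noise at these packet counts).
* The convergence check compares the z = 0 profile NRMSE between
  independent seed pairs at $2.5 \times 10^4$ vs $10^5$ packets; the ratio
  concentrates near the theoretical $1/2$ but a *single* pair scatters by
  roughly a quarter of its value (the max-normalization adds noise), so the
  acceptance script averages three pairs per packet count.

## A worked example

```{r example, eval = FALSE}
fx <- homogeneous_cylinder_phantom()
sim <- simulate_photons(fx$scene, fx$source, n_packets = 1e5, seed = 1)
glance(sim)

map <- rasterize_cylinder_surface(sim, rows = 100, cols = 314)
autoplot(map)
profile_z0 <- extract_profile(map, z = 0)

det <- detector_spec(c(256, 0, 0), c(-1, 0, 0), 16, 16, 64, 64)
lens <- lens_spec(f = 55, u = 200, center = c(200, 0, 0), axis = c(1, 0, 0))
img <- render_detector(surface_elements(map), det, mode = "lens",
                       lens = lens, scene = fx$scene)
autoplot(img)
```

## Known limitations

* Steady-state only: no time-resolved or frequency-domain transport.
* One spectral band per run; no fluorescence coupling or polarization.
* Internal isotropic sources only — no external or collimated illumination.
* LENS mode implements a documented interpretation of an under-specified
  lens term and ignores aperture blur; use SIMPLE mode when magnitudes
  matter.
* The free-space renderer is $O(\text{elements} \times \text{pixels})$;
  rendering the full 500 $\times$ 1570 surface raster against a large
  detector is expensive — coarsen the map first.
* Voxel tallies bin at the interaction site; gradients sharper than the
  voxel pitch are resolution-limited.
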