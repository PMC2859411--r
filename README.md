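# photonmc

Forward simulation of light transport for optical molecular imaging: a
photon-packet Monte Carlo engine for steady internal isotropic sources in
heterogeneous biological tissue, plus a radiosity-radiance free-space model
that renders the escaped surface flux through a thin lens onto a CCD-like
detector. It is aimed at researchers who need a forward model for
bioluminescence-style imaging — to study where emitted light is absorbed,
what flux density reaches the skin, and what a noncontact camera would
record — without building a physical phantom.

## The model in brief

Light emitted by an internal source of power `P0` is carried by `N` packets
of weight `W0 = P0/N` (watts). Each packet takes exponential steps with
rate `mu_t = mu_a + mu_s`, sampled by `s = -ln(xi)/mu_t`; at the end of a
completed step it deposits `dW = W mu_a/mu_t` into a voxel tally and
deflects through a Henyey-Greenstein angle,

    cos(theta) = [1 + g^2 - ((1 - g^2)/(1 - g + 2 g xi))^2] / (2g),   g != 0

with uniform azimuth. Boundaries apply Snell's law and the unpolarized
Fresnel reflectance (total internal reflection beyond
`theta_c = asin(n_t/n_i)`); a single draw reflects or transmits the whole
packet. Low weights face Russian roulette (survive with probability `1/m`
at weight `mW`). Escaped weight accumulates as surface flux density
`J_n` (W/mm^2), which the free-space stage treats as a Lambertian radiance
`L = J_n/pi` and integrates per detector pixel with cosine factors and the
inverse-square law — directly (SIMPLE mode) or through a thin-lens system
with visibility, magnification `t = v/u` and a defocus-modified distance
(LENS mode).

Workers draw from provably non-overlapping xoshiro256++ substreams
(jump-ahead partitioning), so a run is bit-identical for a fixed
`(seed, workers)` and statistically invariant to the worker count.

## Worked example

A 15 mm x 30 mm homogeneous cylinder (`mu_a = 0.0138 mm^-1`,
`mu_s' = 0.91 mm^-1`, matched index) with a 1 nW cylindrical source at
(8, 0, 0) mm:

```r
library(photonmc)

fx  <- homogeneous_cylinder_phantom()
sim <- simulate_photons(fx$scene, fx$source, n_packets = 1e5, seed = 1)
sim
#> <photon_sim> 1e+05 packets (seed 1, 1 worker(s))
#>   launched    1e-09 W
#>   absorbed    6.408e-10 W (64.08%)
#>   transmitted 3.592e-10 W (35.92%)
#>   lost (caps) 0 W; 32 roulette kills, 2 survivals
```

About 64% of the emitted nanowatt is absorbed in the phantom and 36%
escapes; absorbed + transmitted matches the launched power to Monte Carlo
accuracy (roulette is the only non-conserving step). Unwrap the side
surface into a flux-density map and take the `z = 0` profile:

```r
map <- rasterize_cylinder_surface(sim, rows = 100, cols = 314)
map
#> <cylinder_surface_map> 100 x 314 pixels (0.09 mm^2 each), side power 3.16e-10 W, caps 4.321e-11 W

p <- extract_profile(map, z = 0)
max(p$value)          # 2.19e-12 W/mm^2, peaking at arc length ~2.3 mm,
                      # i.e. the surface point nearest the source at +x
autoplot(map)         # unwrapped heatmap (ggplot2)
```

Render what a 16 x 16 mm detector at (256, 0, 0) mm behind an f = 55 mm
lens focused at u = 200 mm would receive:

```r
det  <- detector_spec(c(256, 0, 0), c(-1, 0, 0), 16, 16, 64, 64)
lens <- lens_spec(f = 55, u = 200, center = c(200, 0, 0), axis = c(1, 0, 0))
img  <- render_detector(surface_elements(map), det, mode = "lens",
                        lens = lens, scene = fx$scene)
img
#> <detector_image> 64 x 64 pixels, mode lens, total 4.934e-14 W
autoplot(img)
```

`glance(sim)` gives the one-row run summary, `tidy(sim)` the per-packet
exit events, `absorption_table(sim)` the voxel tally as a tibble.
`heterogeneous_phantom()` builds the bundled five-tissue phantom, and
`read_run_config()`/`write_run_config()` round-trip complete runs through
YAML (with OFF/PLY/STL meshes as regions). A command-line front end with
`simulate`, `render`, `profile`, `nrmse` and `fixtures` subcommands is
installed at `inst/cli/photonmc.R`:

```sh
Rscript inst/cli/photonmc.R fixtures --out phantoms
Rscript inst/cli/photonmc.R simulate --config phantoms/homogeneous_cylinder.yaml \
    --packets 100000 --seed 1 --out run1
```

See the methods vignette (`vignettes/photon-transport.Rmd`) for the full
model description, parameter defaults and design decisions.

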