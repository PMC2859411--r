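Package: photonmc
Title: Monte Carlo Photon Transport in Tissue with Lens-Coupled Free-Space Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Forward simulation of steady-state light propagation from internal
    isotropic sources in heterogeneous biological tissue, for optical molecular
    imaging. A photon-packet Monte Carlo engine (exponential free paths,
    Henyey-Greenstein scattering, Fresnel/Snell boundary events, Russian
    roulette) tallies absorbed power on a voxel grid and escaped power on the
    outer surface; reproducible multi-worker runs use provably non-overlapping
    random substreams. A hybrid radiosity-radiance free-space model converts
    surface flux density to Lambertian radiance and renders it through a
    thin-lens system onto a planar detector, so both contact and noncontact
    measurement geometries can be simulated. Includes analytic and triangle-mesh
    region geometry (OFF/PLY/STL readers), cylinder surface-map unwrapping,
    normalized root-mean-square error comparison, phantom fixture generators,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
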