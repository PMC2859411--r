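# Phantom fixture generators, cylinder surface-map unwrapping and the NRMSE
# comparison metric.

#' Homogeneous cylindrical phantom
#'
#' A cylinder of 15 mm radius and 30 mm height centred at the origin with
#' absorption 0.0138 mm^-1 and reduced scattering 0.91 mm^-1, holding an
#' internal cylindrical source of 1 mm radius and 2 mm height centred at
#' (8, 0, 0) mm with total power 1 nW.  The reduced scattering coefficient
#' pins `mu_s = mu_s_prime / (1 - g)`; `g` itself is configurable (transport
#' in the diffusive regime is insensitive to the split by similarity).  The
#' refractive index defaults to matched (n = 1), which keeps conservation
#' checks free of boundary reflection; pass `n = 1.37` for a tissue-like
#' mismatched boundary.
#'
#' @param g Anisotropy factor used to un-reduce the scattering coefficient.
#' @param n Phantom refractive index.
#' @param mu_a Absorption coefficient (mm^-1).
#' @param mu_s_prime Reduced scattering coefficient (mm^-1).
#' @return List with elements `scene` and `source`.
#' @examples
#' fx <- homogeneous_cylinder_phantom()
#' fx$scene
#' @export
homogeneous_cylinder_phantom <- function(g = 0.9, n = 1.0, mu_a = 0.0138,
                                         mu_s_prime = 0.91) {
  mu_s <- mu_s_prime / (1 - g)
  sc <- scene(region(1, shape_cylinder(c(0, 0, 0), radius = 15, height = 30),
                     optical_properties(mu_a, mu_s, g = g, n = n),
                     label = "phantom"))
  src <- source_spec(shape_cylinder(c(8, 0, 0), radius = 1, height = 2),
                     power = 1e-9)
  list(scene = sc, source = src)
}

#' Heterogeneous five-tissue phantom
#'
#' A cylinder of 8 mm radius and 20 mm height (tissue 1) holding four
#' inclusions: a central ellipsoid (tissue 2, semi-axes 4, 4, 5), two large
#' ellipsoids at (0, -4, 0) and (0, 4, 0) (tissues 3.1/3.2, semi-axes
#' 6, 3, 12) and an off-centre cylinder of radius 1 and height 18 at
#' (0, 6, 0) (tissue 4), with the optical properties listed below.  As
#' printed this geometry is neither strictly nested (tissues 3.1/3.2 extend
#' past the outer cylinder in z) nor disjoint (tissue 2 intersects 3.1/3.2,
#' tissue 4 intersects 3.2), so the fixture is built with clipped containment
#' semantics: the root clips all inclusions, and first-listed inclusions take
#' priority where they overlap.  The recorded validation report is attached
#' to the scene.  The source is a 0.5 x 0.5 x 1 mm ellipsoid of 1 nW placed
#' 2 mm above the phantom centre (inside tissue 2); see the methods vignette
#' for the coordinate-frame reading behind that placement.
#'
#' | tissue | shape | mu_a | mu_s | g |
#' |---|---|---|---|---|
#' | 1 | cylinder r=8 h=20 | 0.01 | 4 | 0.90 |
#' | 2 | ellipsoid 4,4,5 | 0.2 | 16 | 0.85 |
#' | 3.1 | ellipsoid 6,3,12 at (0,-4,0) | 0.35 | 23 | 0.94 |
#' | 3.2 | ellipsoid 6,3,12 at (0,4,0) | 0.35 | 23 | 0.94 |
#' | 4 | cylinder r=1 h=18 at (0,6,0) | 0.002 | 20 | 0.90 |
#'
#' @param n Refractive index shared by all tissues.
#' @return List with elements `scene` and `source`.
#' @export
heterogeneous_phantom <- function(n = 1.0) {
  sc <- suppressWarnings(scene(
    region(1, shape_cylinder(c(0, 0, 0), radius = 8, height = 20),
           optical_properties(0.01, 4, g = 0.90, n = n), label = "tissue 1"),
    region(2, shape_ellipsoid(c(0, 0, 0), radii = c(4, 4, 5)),
           optical_properties(0.2, 16, g = 0.85, n = n), parent = 1,
           label = "tissue 2"),
    region(3, shape_ellipsoid(c(0, -4, 0), radii = c(6, 3, 12)),
           optical_properties(0.35, 23, g = 0.94, n = n), parent = 1,
           label = "tissue 3.1"),
    region(4, shape_ellipsoid(c(0, 4, 0), radii = c(6, 3, 12)),
           optical_properties(0.35, 23, g = 0.94, n = n), parent = 1,
           label = "tissue 3.2"),
    region(5, shape_cylinder(c(0, 6, 0), radius = 1, height = 18),
           optical_properties(0.002, 20, g = 0.90, n = n), parent = 1,
           label = "tissue 4"),
    containment = "clip"))
  src <- source_spec(shape_ellipsoid(c(0, 0, 2), radii = c(0.5, 0.5, 1)),
                     power = 1e-9)
  list(scene = sc, source = src)
}

#' Cylinder surface-map geometry
#'
#' Describes the unwrapped side surface of a cylinder: rows bin z over
#' `[-H/2, H/2)` (bottom row first), columns bin the arc length `R * phi`
#' over `[0, 2 pi R)` with `phi = 0` at +x increasing counterclockwise
#' viewed from +z.  Either give a pixel size (rows/cols are the whole number
#' of pixels fitting each extent; a warning is raised if the pixel misfits an
#' extent by more than half a pixel) or explicit `rows` and `cols`.
#'
#' @param radius,height Cylinder dimensions (mm).
#' @param pixel Square pixel edge (mm), or `NULL`.
#' @param rows,cols Explicit map dimensions (used when `pixel` is `NULL`).
#' @return A list of class `cylinder_map_spec`.
#' @export
cylinder_map_spec <- function(radius, height, pixel = NULL, rows = NULL,
                              cols = NULL) {
  circumference <- 2 * pi * radius
  if (!is.null(pixel)) {
    rows <- max(1L, as.integer(floor(height / pixel + 1e-9)))
    cols <- max(1L, as.integer(floor(circumference / pixel + 1e-9)))
    if (abs(rows * pixel - height) > 0.5 * pixel ||
        abs(cols * pixel - circumference) > 0.5 * pixel)
      warn("pixel size does not divide the cylinder extents within 0.5 pixel")
  }
  if (is.null(rows) || is.null(cols))
    abort("give either `pixel` or both `rows` and `cols`")
  structure(list(radius = radius, height = height, rows = as.integer(rows),
                 cols = as.integer(cols),
                 pixel_area = (height / rows) * (circumference / cols)),
            class = "cylinder_map_spec")
}

#' Unwrap transmitted power into a cylinder side-surface flux map
#'
#' Bins the exit events of a run whose root region is an analytic cylinder
#' into the unwrapped side-surface raster and divides by the pixel area,
#' yielding flux density J_n in W/mm^2.  End caps are excluded from the map;
#' their escaped power is reported separately.
#'
#' @param sim A `photon_sim` with recorded exit events.
#' @param spec A [cylinder_map_spec()]; defaults to the root cylinder's
#'   dimensions with `pixel`/`rows`/`cols` forwarded.
#' @param pixel,rows,cols Forwarded to [cylinder_map_spec()] when `spec` is
#'   `NULL`.
#' @return A `cylinder_surface_map`: `map` (rows x cols matrix, W/mm^2),
#'   `z_centers`, `z_edges`, `arc_centers` (mm), `phi_centers` (rad),
#'   `pixel_area` (mm^2), `side_power`, `cap_power` (W).
#' @export
rasterize_cylinder_surface <- function(sim, spec = NULL, pixel = NULL,
                                       rows = NULL, cols = NULL) {
  stopifnot(inherits(sim, "photon_sim"))
  root <- scene_root(sim$scene)
  if (root$shape$type != "cylinder")
    abort("surface unwrapping needs a cylinder root region")
  R <- root$shape$radius
  H <- root$shape$height
  ctr <- root$shape$center
  if (is.null(spec))
    spec <- cylinder_map_spec(R, H, pixel = pixel, rows = rows, cols = cols)
  stopifnot(inherits(spec, "cylinder_map_spec"))

  ex <- sim$exits
  side <- ex$element == 1
  phi <- atan2(ex$y[side] - ctr[2], ex$x[side] - ctr[1]) %% (2 * pi)
  zrel <- ex$z[side] - (ctr[3] - H / 2)
  ci <- pmin(spec$cols, pmax(1L, as.integer(floor(phi / (2 * pi) * spec$cols)) + 1L))
  ri <- pmin(spec$rows, pmax(1L, as.integer(floor(zrel / H * spec$rows)) + 1L))
  pw <- ex$weight[side]
  flat <- numeric(spec$rows * spec$cols)
  if (length(pw)) {
    idx <- (ci - 1L) * spec$rows + ri
    agg <- rowsum(pw, group = idx)
    flat[as.integer(rownames(agg))] <- agg[, 1]
  }
  m <- matrix(flat, spec$rows, spec$cols) / spec$pixel_area

  z_edges <- ctr[3] - H / 2 + H * (0:spec$rows) / spec$rows
  phi_centers <- 2 * pi * (seq_len(spec$cols) - 0.5) / spec$cols
  structure(list(map = m,
                 z_centers = (z_edges[-1] + z_edges[-length(z_edges)]) / 2,
                 z_edges = z_edges,
                 arc_centers = R * phi_centers, phi_centers = phi_centers,
                 radius = R, height = H, center = ctr,
                 pixel_area = spec$pixel_area,
                 side_power = sum(pw), cap_power = sum(ex$weight[!side])),
            class = "cylinder_surface_map")
}

#' @export
print.cylinder_surface_map <- function(x, ...) {
  cat(sprintf("<cylinder_surface_map> %d x %d pixels (%.3g mm^2 each), side power %.4g W, caps %.4g W\n",
              nrow(x$map), ncol(x$map), x$pixel_area, x$side_power,
              x$cap_power))
  invisible(x)
}

#' Surface elements of an unwrapped cylinder map
#'
#' Converts map pixels into discrete Lambertian surface elements for
#' free-space rendering: centroid on the cylinder surface, outward radial
#' normal, exact patch area and flux density.
#'
#' @param map A `cylinder_surface_map`.
#' @param drop_empty Drop zero-flux pixels (they contribute nothing).
#' @return Tibble with columns `x`, `y`, `z`, `nx`, `ny`, `nz`, `area`,
#'   `j_n`.
#' @export
surface_elements <- function(map, drop_empty = TRUE) {
  stopifnot(inherits(map, "cylinder_surface_map"))
  nr <- nrow(map$map); nc <- ncol(map$map)
  phi <- rep(map$phi_centers, each = nr)
  z <- rep(map$z_centers, times = nc)
  j <- as.numeric(map$map)
  keep <- if (drop_empty) j > 0 else rep(TRUE, length(j))
  tibble(x = map$center[1] + map$radius * cos(phi[keep]),
         y = map$center[2] + map$radius * sin(phi[keep]),
         z = z[keep],
         nx = cos(phi[keep]), ny = sin(phi[keep]), nz = 0,
         area = map$pixel_area, j_n = j[keep])
}

#' Normalized root-mean-square error
#'
#' `sqrt(mean((d1 - d2)^2))` after normalizing each input by its own maximum
#' (default; the convention used for "normalized flux density" curves), its
#' sum, or not at all.
#'
#' @param d1,d2 Numeric vectors of equal length.
#' @param normalize `"max"`, `"sum"` or `"none"`.
#' @return The NRMSE (dimensionless).
#' @examples
#' nrmse(c(1, 0), c(0, 1))  # 1
#' @export
nrmse <- function(d1, d2, normalize = c("max", "sum", "none")) {
  normalize <- match.arg(normalize)
  if (length(d1) != length(d2)) abort("d1 and d2 must have equal length")
  if (!length(d1)) abort("empty input")
  norm1 <- switch(normalize, max = max(d1), sum = sum(d1), none = 1)
  norm2 <- switch(normalize, max = max(d2), sum = sum(d2), none = 1)
  if (normalize != "none" && (norm1 == 0 || norm2 == 0))
    abort("cannot normalize an all-zero vector")
  sqrt(mean((d1 / norm1 - d2 / norm2)^2))
}
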