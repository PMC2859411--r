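# Analytic shapes, tissue regions and nested scenes.
#
# All lengths are millimetres; cylinder axes run along z; coordinates are
# right-handed.  A scene is a containment tree: one root region (the organism
# outline) whose descendants are internal inclusions.

#' Optical properties of a tissue
#'
#' @param mu_a Absorption coefficient (mm^-1), `>= 0`.
#' @param mu_s Scattering coefficient (mm^-1), `>= 0`; `mu_a + mu_s` must be
#'   positive for any region a photon packet can enter.
#' @param g Scattering anisotropy factor (mean cosine of the deflection
#'   angle), in (-1, 1); `g = 0` is isotropic scattering.
#' @param n Refractive index, `>= 1`.
#' @return A list of class `optical_properties`.
#' @examples
#' optical_properties(mu_a = 0.0138, mu_s = 9.1, g = 0.9, n = 1.37)
#' @export
optical_properties <- function(mu_a, mu_s, g = 0, n = 1) {
  stopifnot(is.numeric(mu_a), is.numeric(mu_s), is.numeric(g), is.numeric(n))
  if (mu_a < 0 || mu_s < 0) abort("mu_a and mu_s must be non-negative")
  if (mu_a + mu_s <= 0) abort("mu_a + mu_s must be positive")
  if (abs(g) >= 1) abort("anisotropy g must satisfy -1 < g < 1")
  if (n < 1) abort("refractive index n must be >= 1")
  structure(list(mu_a = mu_a, mu_s = mu_s, g = g, n = n),
            class = "optical_properties")
}

#' Analytic and mesh shape constructors
#'
#' Shapes are closed surfaces used both for tissue regions and for light
#' sources.  `shape_cylinder()` is axis-aligned along z; `shape_box()` takes
#' full edge lengths; `shape_mesh()` takes a closed, consistently outward
#' oriented triangle mesh (validated on construction).
#'
#' @param center Numeric length-3 centre (mm).
#' @param radius Radius (mm).
#' @param height Full height along z (mm).
#' @param radii Numeric length-3 semi-axes of an ellipsoid (mm).
#' @param size Numeric length-3 full edge lengths of a box (mm).
#' @param vertices Numeric matrix (n x 3) of mesh vertices (mm).
#' @param faces Integer matrix (m x 3) of 1-based triangle vertex indices.
#' @return A list of class `photon_shape`.
#' @name shapes
NULL

new_shape <- function(x) structure(x, class = "photon_shape")

#' @rdname shapes
#' @export
shape_cylinder <- function(center = c(0, 0, 0), radius, height) {
  stopifnot(length(center) == 3, radius > 0, height > 0)
  new_shape(list(type = "cylinder", center = as.numeric(center),
                 radius = radius, height = height))
}

#' @rdname shapes
#' @export
shape_sphere <- function(center = c(0, 0, 0), radius) {
  stopifnot(length(center) == 3, radius > 0)
  new_shape(list(type = "sphere", center = as.numeric(center), radius = radius))
}

#' @rdname shapes
#' @export
shape_ellipsoid <- function(center = c(0, 0, 0), radii) {
  stopifnot(length(center) == 3, length(radii) == 3, all(radii > 0))
  new_shape(list(type = "ellipsoid", center = as.numeric(center),
                 radii = as.numeric(radii)))
}

#' @rdname shapes
#' @export
shape_box <- function(center = c(0, 0, 0), size) {
  stopifnot(length(center) == 3, length(size) == 3, all(size > 0))
  new_shape(list(type = "box", center = as.numeric(center),
                 size = as.numeric(size)))
}

#' @rdname shapes
#' @export
shape_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  storage.mode(vertices) <- "double"
  storage.mode(faces) <- "integer"
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3)
  if (any(faces < 1L) || any(faces > nrow(vertices)))
    abort("mesh faces index vertices out of range")
  validate_closed_mesh(vertices, faces)
  new_shape(list(type = "mesh", center = colMeans(vertices),
                 vertices = vertices, faces = faces))
}

# closed 2-manifold check: every undirected edge is shared by exactly two
# faces, traversed once in each direction (consistent outward orientation).
# Degenerate faces are invisible to ray tests, so they are excluded from the
# census too.
validate_closed_mesh <- function(vertices, faces) {
  areas <- triangle_areas(vertices, faces)
  degen <- areas < 1e-12
  if (any(degen)) {
    warn(sprintf("mesh contains %d degenerate (zero-area) triangle(s); they are ignored by ray tests",
                 sum(degen)))
    faces <- faces[!degen, , drop = FALSE]
  }
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key)
  if (any(cnt != 2L))
    abort("mesh is not closed: some edges are not shared by exactly two faces")
  dir_key <- paste(e[, 1], e[, 2])
  if (anyDuplicated(dir_key))
    abort("mesh is not consistently oriented: a directed edge appears twice")
  invisible(TRUE)
}

triangle_areas <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  cc <- vertices[faces[, 3], , drop = FALSE]
  e1 <- b - a
  e2 <- cc - a
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  0.5 * sqrt(rowSums(cr^2))
}

#' Tissue region
#'
#' @param id Positive integer region identifier, unique within a scene.
#' @param shape A [shapes] object.
#' @param props An [optical_properties()] object.
#' @param parent Id of the enclosing region, or `0` for the root region
#'   (whose outside is the ambient medium).
#' @param label Optional human-readable name.
#' @return A list of class `photon_region`.
#' @export
region <- function(id, shape, props, parent = 0, label = NULL) {
  stopifnot(inherits(shape, "photon_shape"), inherits(props, "optical_properties"))
  id <- as.integer(id)
  parent <- as.integer(parent)
  if (id < 1) abort("region id must be a positive integer")
  structure(list(id = id, shape = shape, parent = parent, label = label,
                 mu_a = props$mu_a, mu_s = props$mu_s, g = props$g, n = props$n),
            class = "photon_region")
}

#' Build and validate a nested-region scene
#'
#' Regions form a containment tree rooted at one outermost region.  Validation
#' draws points inside every child shape and checks that they fall inside the
#' parent and outside every sibling.  Under `containment = "strict"` any
#' violation is an error; under `"clip"` violations are recorded (see
#' `attr(scene, "containment_report")`) and membership is resolved by
#' clipping: a point belongs to a child only where it is also inside all
#' ancestors, and the first-listed sibling wins where siblings overlap.
#'
#' @param ... [region()] objects.
#' @param ambient_n Refractive index of the medium outside the root region.
#' @param containment `"strict"` or `"clip"`.
#' @param n_check Points sampled per containment check.
#' @return A list of class `photon_scene` with elements `regions` and
#'   `ambient_n`.
#' @examples
#' sc <- scene(region(1, shape_cylinder(radius = 15, height = 30),
#'                    optical_properties(0.0138, 9.1, g = 0.9)))
#' @export
scene <- function(..., ambient_n = 1.0, containment = c("strict", "clip"),
                  n_check = 200) {
  containment <- match.arg(containment)
  regions <- list(...)
  if (length(regions) == 1 && !inherits(regions[[1]], "photon_region"))
    regions <- regions[[1]]
  if (!length(regions)) abort("a scene needs at least one region")
  for (r in regions)
    if (!inherits(r, "photon_region")) abort("scene() accepts region() objects")

  ids <- vapply(regions, function(r) r$id, integer(1))
  if (anyDuplicated(ids)) abort("region ids must be unique")
  parents <- vapply(regions, function(r) r$parent, integer(1))
  if (sum(parents == 0L) != 1L) abort("exactly one region must have parent = 0")
  if (!all(parents %in% c(0L, ids))) abort("unknown parent id in scene")

  # acyclicity: every region must reach the root
  for (i in seq_along(regions)) {
    seen <- integer(0)
    p <- parents[i]
    while (p != 0L) {
      if (p %in% seen) abort("containment tree has a cycle")
      seen <- c(seen, p)
      p <- parents[match(p, ids)]
    }
  }

  sc <- structure(list(regions = regions, ambient_n = ambient_n),
                  class = "photon_scene")
  report <- check_containment(sc, n_check = n_check)
  if (nrow(report) > 0) {
    msg <- paste(sprintf("region %d vs %d: %s (%.0f%% of sampled points)",
                         report$region, report$other, report$problem,
                         100 * report$fraction), collapse = "; ")
    if (containment == "strict")
      abort(paste0("scene containment validation failed: ", msg))
    warn(paste0("scene uses clipped containment: ", msg))
  }
  attr(sc, "containment_report") <- report
  sc
}

# sampled containment / overlap audit
check_containment <- function(sc, n_check = 200) {
  regions <- sc$regions
  ids <- vapply(regions, function(r) r$id, integer(1))
  parents <- vapply(regions, function(r) r$parent, integer(1))
  stream <- rcpp_make_stream(912873465, 0L)
  out <- list()
  for (i in seq_along(regions)) {
    if (parents[i] == 0L) next
    pts <- rcpp_sample_in_shape(unclass(regions[[i]]$shape), stream,
                                as.integer(n_check))
    parent <- regions[[match(parents[i], ids)]]
    inside <- rcpp_points_in_shape(unclass(parent$shape), pts)
    if (!all(inside))
      out[[length(out) + 1]] <- tibble(
        region = ids[i], other = parents[i],
        problem = "extends beyond parent", fraction = mean(!inside))
    sibs <- which(parents == parents[i] & ids != ids[i])
    for (j in sibs) {
      if (ids[j] > ids[i]) next  # report each pair once
      ov <- rcpp_points_in_shape(unclass(regions[[j]]$shape), pts)
      if (any(ov))
        out[[length(out) + 1]] <- tibble(
          region = ids[i], other = ids[j],
          problem = "overlaps sibling", fraction = mean(ov))
    }
  }
  if (!length(out))
    return(tibble(region = integer(), other = integer(),
                  problem = character(), fraction = double()))
  bind_rows(out)
}

scene_root <- function(sc) {
  parents <- vapply(sc$regions, function(r) r$parent, integer(1))
  sc$regions[[which(parents == 0L)]]
}

scene_region <- function(sc, id) {
  ids <- vapply(sc$regions, function(r) r$id, integer(1))
  sc$regions[[match(id, ids)]]
}

# plain-list form handed to the C++ core
scene_as_list <- function(sc) {
  list(ambient_n = sc$ambient_n,
       regions = lapply(sc$regions, function(r)
         list(id = r$id, parent = r$parent, shape = unclass(r$shape),
              mu_a = r$mu_a, mu_s = r$mu_s, g = r$g, n = r$n)))
}

#' @export
print.photon_scene <- function(x, ...) {
  cat(sprintf("<photon_scene> %d region(s), ambient n = %g\n",
              length(x$regions), x$ambient_n))
  for (r in x$regions)
    cat(sprintf("  region %d%s: %s, parent %s, mu_a=%g mu_s=%g g=%g n=%g\n",
                r$id, if (is.null(r$label)) "" else paste0(" (", r$label, ")"),
                r$shape$type, if (r$parent == 0) "ambient" else r$parent,
                r$mu_a, r$mu_s, r$g, r$n))
  invisible(x)
}

#' Point-membership test
#'
#' Strict interior test against a region's shape; points within about 1e-9 mm
#' of the surface may fall on either side.
#'
#' @param p Numeric length-3 point, or an n x 3 matrix of points (mm).
#' @param region A [region()] or [shapes] object.
#' @return Logical vector.
#' @export
point_in_region <- function(p, region) {
  shape <- if (inherits(region, "photon_region")) region$shape else region
  stopifnot(inherits(shape, "photon_shape"))
  p <- rbind_points(p)
  as.logical(rcpp_points_in_shape(unclass(shape), p))
}

#' Nearest boundary along a ray
#'
#' Finds the closest surface ahead of a point travelling through the region
#' tree: the current region's own surface, any direct child, and any ancestor
#' surface (ancestors clip children that extend beyond them).  The reported
#' normal is the outward normal of the hit shape; `next_region` is the region
#' on the far side (`0` = ambient).
#'
#' @param scene A [scene()].
#' @param p Numeric length-3 ray origin, strictly inside region `current`.
#' @param d Numeric length-3 unit direction.
#' @param current Id of the region containing `p`.
#' @return A list: `distance`, `point`, `normal`, `surface_region`,
#'   `next_region`, `element`; or `NULL` if no surface lies ahead.
#' @export
nearest_boundary_hit <- function(scene, p, d, current) {
  stopifnot(inherits(scene, "photon_scene"), length(p) == 3, length(d) == 3)
  d <- as.numeric(d)
  nd <- sqrt(sum(d^2))
  if (abs(nd - 1) > 1e-9) abort("direction d must be unit-norm")
  h <- rcpp_nearest_hit(scene_as_list(scene), as.integer(current),
                        as.numeric(p), d)
  if (!isTRUE(h$hit)) return(NULL)
  h$hit <- NULL
  h
}

#' Ray-triangle intersection
#'
#' Moller-Trumbore test with a 1e-12 barycentric tolerance; degenerate
#' (zero-area) triangles always miss.
#'
#' @param p,d Ray origin and unit direction (length-3 numeric).
#' @param tri 3 x 3 matrix, one vertex per row.
#' @return Positive hit distance (mm), or `NA` on a miss.
#' @export
ray_triangle_intersect <- function(p, d, tri) {
  tri <- as.matrix(tri)
  stopifnot(length(p) == 3, length(d) == 3, all(dim(tri) == c(3, 3)))
  t <- rcpp_ray_triangle(as.numeric(p), as.numeric(d), tri)
  if (t < 0) NA_real_ else t
}

rbind_points <- function(p) {
  if (is.null(dim(p))) {
    stopifnot(length(p) == 3)
    p <- matrix(as.numeric(p), 1, 3)
  }
  p <- as.matrix(p)
  storage.mode(p) <- "double"
  stopifnot(ncol(p) == 3)
  p
}

shape_bbox <- function(shape) {
  shape <- if (inherits(shape, "photon_region")) shape$shape else shape
  b <- rcpp_shape_bbox(unclass(shape))
  dimnames(b) <- list(c("lo", "hi"), c("x", "y", "z"))
  b
}
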