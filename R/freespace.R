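# Hybrid radiosity-radiance free-space model.
#
# Each outer-surface element with flux density J_n is a Lambertian source of
# radiance L = J_n / pi.  A detector pixel of area dA at r_d receives, from a
# surface element of area dS at r,
#
#   dP = (1/pi) J_n cos(theta_s) cos(theta_d) dS dA / |r_d - r|^2
#
# (cosine law at the source, detector foreshortening, inverse-square law).
# SIMPLE mode sums this directly; LENS mode additionally applies a
# visibility factor relative to the lens centre, the squared magnification
# t^2 = (v/u)^2, and a lens-modified distance term (see render_detector).

#' Lambertian radiance from surface flux density
#'
#' @param j_n Surface flux density (W/mm^2), `>= 0`.
#' @return Radiance `j_n / pi` (W/mm^2/sr).
#' @export
radiance_from_flux <- function(j_n) {
  stopifnot(all(j_n >= 0))
  j_n / pi
}

#' Planar detector description
#'
#' The detector plane is spanned by `up` (projected perpendicular to
#' `normal`; image rows) and `normal x up` (image columns); pixel power is
#' evaluated at pixel centres (midpoint rule).
#'
#' @param center Length-3 centre (mm).
#' @param normal Length-3 outward normal (towards the scene).
#' @param width,height Physical extent (mm); columns span `width`, rows span
#'   `height`.
#' @param rows,cols Pixel counts.
#' @param up In-plane "up" direction (default +z).
#' @return A list of class `detector_spec`; `dA = (width/cols)*(height/rows)`.
#' @export
detector_spec <- function(center, normal, width, height, rows, cols,
                          up = c(0, 0, 1)) {
  stopifnot(length(center) == 3, length(normal) == 3, width > 0, height > 0,
            rows >= 1, cols >= 1)
  normal <- as.numeric(normal) / sqrt(sum(normal^2))
  up <- as.numeric(up)
  up <- up - sum(up * normal) * normal
  if (sqrt(sum(up^2)) < 1e-12) abort("`up` is parallel to the detector normal")
  up <- up / sqrt(sum(up^2))
  right <- pracma_cross(up, normal)
  structure(list(center = as.numeric(center), normal = normal, up = up,
                 right = right, width = width, height = height,
                 rows = as.integer(rows), cols = as.integer(cols),
                 dA = (width / cols) * (height / rows)),
            class = "detector_spec")
}

#' Thin-lens system description
#'
#' In LENS mode the lens law `1/f = 1/u + 1/v` must hold within 1e-9 (given
#' `f` and the in-focus object distance `u`, the image distance `v` and
#' magnification `t = v/u` are derived when omitted).
#'
#' @param f Focal length (mm).
#' @param u Object distance to the in-focus plane (mm), `> f`.
#' @param center Lens centre (mm).
#' @param axis Optical axis unit vector (sign irrelevant).
#' @param v Image distance (mm); derived from the lens law when `NULL`.
#' @return A list of class `lens_spec` with `f`, `u`, `v`, `t`, `center`,
#'   `axis`.
#' @export
lens_spec <- function(f, u, center, axis, v = NULL) {
  stopifnot(f > 0, u > f, length(center) == 3, length(axis) == 3)
  if (is.null(v)) v <- 1 / (1 / f - 1 / u)
  if (abs(1 / f - 1 / u - 1 / v) > 1e-9)
    abort("lens parameters violate the thin-lens law 1/f = 1/u + 1/v")
  axis <- as.numeric(axis) / sqrt(sum(axis^2))
  structure(list(f = f, u = u, v = v, t = v / u, center = as.numeric(center),
                 axis = axis),
            class = "lens_spec")
}

as_elements <- function(surface) {
  surface <- as_tibble(surface)
  need <- c("x", "y", "z", "nx", "ny", "nz", "area", "j_n")
  if (!all(need %in% names(surface)))
    abort(paste("surface elements need columns:", paste(need, collapse = ", ")))
  surface
}

#' Differential received power from surface elements
#'
#' Power received by one detector pixel (centre `r_d`, normal `n_d`, area
#' `dA`) from each surface element, by the Lambertian cosine law and the
#' inverse-square law.  Elements facing away from the pixel (or pixels facing
#' away from the element) contribute zero.
#'
#' @param surface Tibble of surface elements: columns `x`, `y`, `z`
#'   (centroid, mm), `nx`, `ny`, `nz` (outward unit normal), `area` (mm^2),
#'   `j_n` (W/mm^2).
#' @param r_d Pixel centre (length 3, mm).
#' @param n_d Pixel normal (length 3, unit).
#' @param dA Pixel area (mm^2).
#' @return Numeric vector of received powers (W), one per element.
#' @export
differential_power <- function(surface, r_d, n_d, dA) {
  s <- as_elements(surface)
  vx <- r_d[1] - s$x; vy <- r_d[2] - s$y; vz <- r_d[3] - s$z
  d2 <- vx^2 + vy^2 + vz^2
  if (any(d2 == 0)) abort("detector pixel coincides with a surface element")
  d1 <- sqrt(d2)
  cos_s <- (vx * s$nx + vy * s$ny + vz * s$nz) / d1
  cos_d <- -(vx * n_d[1] + vy * n_d[2] + vz * n_d[3]) / d1
  dp <- (1 / pi) * s$j_n * pmax(cos_s, 0) * pmax(cos_d, 0) * s$area * dA / d2
  dp
}

#' Visibility of surface elements from a viewpoint
#'
#' An element is visible iff its outward normal makes a strictly positive
#' cosine with the direction to the viewpoint (a zero-radiance limb counts as
#' invisible) and, when a scene is supplied, the segment from the element to
#' the viewpoint is not occluded by the scene's root surface.
#'
#' @param surface Tibble of surface elements (see [differential_power()]).
#' @param r_d Viewpoint, e.g. the lens centre (length 3, mm).
#' @param scene Optional [scene()] whose root surface occludes.
#' @return Integer vector of 0/1 factors.
#' @export
visibility_factor <- function(surface, r_d, scene = NULL) {
  s <- as_elements(surface)
  vx <- r_d[1] - s$x; vy <- r_d[2] - s$y; vz <- r_d[3] - s$z
  d1 <- sqrt(vx^2 + vy^2 + vz^2)
  cos_s <- (vx * s$nx + vy * s$ny + vz * s$nz) / d1
  vis <- cos_s > 0
  if (!is.null(scene) && any(vis)) {
    root <- scene_root(scene)
    idx <- which(vis)
    eps <- 1e-6
    orig <- cbind(s$x[idx] + eps * s$nx[idx], s$y[idx] + eps * s$ny[idx],
                  s$z[idx] + eps * s$nz[idx])
    dirs <- cbind(vx[idx], vy[idx], vz[idx])
    t_hit <- rcpp_shape_ray_distance(unclass(root$shape), orig, dirs)
    occluded <- t_hit > 0 & t_hit < d1[idx] - eps
    vis[idx][occluded] <- FALSE
  }
  as.integer(vis)
}

#' Render surface flux onto a detector
#'
#' Integrates the Lambertian differential power of every surface element over
#' the detector pixel grid.
#'
#' `mode = "simple"` is the direct radiosity sum: visibility by cosine sign
#' only, inverse-square distance - the well-defined contact/ideal-aperture
#' model.  `mode = "lens"` adds the thin-lens system: a visibility factor
#' relative to the lens centre (strictly positive source cosine, root-surface
#' occlusion), the squared magnification `t^2`, and the lens-modified
#' distance `|r_d - r - (t u2 / (f cos theta)) s|^2` in place of
#' `|r_d - r|^2`, where `s` is the unit line of sight from the element to the
#' pixel, `theta` its angle to the optical axis, and `u2` the defocus: the
#' element's axial distance from the lens minus the in-focus object distance
#' `u`, so elements on the in-focus plane are imaged by the pure
#' inverse-square term scaled by `t^2`, and off-plane elements blur - a
#' depth-of-field effect.  This reading of the lens term (its source
#' derivation is not self-contained here) is documented in the methods
#' vignette; treat SIMPLE mode as the reference model and do not read LENS
#' magnitudes as externally validated.
#'
#' @param surface Tibble of surface elements (see [differential_power()]),
#'   e.g. from [surface_elements()] after a Monte Carlo run.
#' @param detector A [detector_spec()].
#' @param mode `"simple"` or `"lens"`.
#' @param lens A [lens_spec()] (required in LENS mode).
#' @param scene Optional [scene()] for the occlusion test.
#' @return A `detector_image`: list with `image` (rows x cols matrix, W per
#'   pixel, row 1 at the lowest `up` coordinate), `row_centers`,
#'   `col_centers` (mm in the detector plane), `detector`, `lens`, `mode`.
#' @export
render_detector <- function(surface, detector, mode = c("simple", "lens"),
                            lens = NULL, scene = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(detector, "detector_spec"))
  s <- as_elements(surface)
  img <- matrix(0, detector$rows, detector$cols)
  row_c <- (seq_len(detector$rows) - (detector$rows + 1) / 2) *
    (detector$height / detector$rows)
  col_c <- (seq_len(detector$cols) - (detector$cols + 1) / 2) *
    (detector$width / detector$cols)
  if (nrow(s) == 0) {
    warn("empty surface: returning a zero detector image")
  } else if (mode == "simple") {
    for (i in seq_len(detector$rows)) {
      for (j in seq_len(detector$cols)) {
        rd <- detector$center + row_c[i] * detector$up + col_c[j] * detector$right
        img[i, j] <- sum(differential_power(s, rd, detector$normal,
                                            detector$dA))
      }
    }
  } else {
    if (is.null(lens) || !inherits(lens, "lens_spec"))
      abort("LENS mode needs a lens_spec()")
    vis <- visibility_factor(s, lens$center, scene)
    sv <- s[vis == 1L, , drop = FALSE]
    if (nrow(sv) > 0) {
      for (i in seq_len(detector$rows)) {
        for (j in seq_len(detector$cols)) {
          rd <- detector$center + row_c[i] * detector$up +
            col_c[j] * detector$right
          vx <- rd[1] - sv$x; vy <- rd[2] - sv$y; vz <- rd[3] - sv$z
          d1 <- sqrt(vx^2 + vy^2 + vz^2)
          sx <- vx / d1; sy <- vy / d1; sz <- vz / d1
          cos_s <- pmax(sx * sv$nx + sy * sv$ny + sz * sv$nz, 0)
          cos_d <- pmax(-(sx * detector$normal[1] + sy * detector$normal[2] +
                            sz * detector$normal[3]), 0)
          cos_th <- pmax(abs(sx * lens$axis[1] + sy * lens$axis[2] +
                               sz * lens$axis[3]), 1e-9)
          # defocus term: axial offset of the element from the in-focus
          # object plane, magnified and normalized by the focal length
          d_ax <- abs((sv$x - lens$center[1]) * lens$axis[1] +
                        (sv$y - lens$center[2]) * lens$axis[2] +
                        (sv$z - lens$center[3]) * lens$axis[3])
          shift <- lens$t * (d_ax - lens$u) / (lens$f * cos_th)
          ddx <- vx - shift * sx; ddy <- vy - shift * sy; ddz <- vz - shift * sz
          dd2 <- ddx^2 + ddy^2 + ddz^2
          img[i, j] <- sum((1 / pi) * sv$j_n * cos_s * cos_d * detector$dA *
                             lens$t^2 * sv$area / dd2)
        }
      }
    }
  }
  structure(list(image = img, row_centers = row_c, col_centers = col_c,
                 detector = detector, lens = lens, mode = mode),
            class = "detector_image")
}

#' @export
print.detector_image <- function(x, ...) {
  cat(sprintf("<detector_image> %d x %d pixels, mode %s, total %.4g W\n",
              nrow(x$image), ncol(x$image), x$mode, sum(x$image)))
  invisible(x)
}

#' @export
as_tibble.detector_image <- function(x, ...) {
  tibble(row = rep(seq_along(x$row_centers), times = length(x$col_centers)),
         col = rep(seq_along(x$col_centers), each = length(x$row_centers)),
         v = rep(x$row_centers, times = length(x$col_centers)),
         u = rep(x$col_centers, each = length(x$row_centers)),
         power = as.numeric(x$image))
}

#' Extract a constant-z profile
#'
#' Takes the nearest row of a surface map or detector image to the requested
#' z (rows are floor-binned to the pixel grid; the row whose centre is
#' closest is returned, ties resolved towards the lower row).
#'
#' @param x A `cylinder_surface_map` or `detector_image`.
#' @param z Height (mm); for a detector image, position along the `up` axis.
#' @return Tibble with `position` (arc length or in-plane coordinate, mm),
#'   `value`, and the attributes `z_requested`/`z_actual` in columns.
#' @export
extract_profile <- function(x, z = 0) UseMethod("extract_profile")

#' @export
extract_profile.cylinder_surface_map <- function(x, z = 0) {
  if (z < min(x$z_edges) || z > max(x$z_edges))
    abort(sprintf("z = %g outside the map extent [%g, %g]", z,
                  min(x$z_edges), max(x$z_edges)))
  i <- which.min(abs(x$z_centers - z))  # which.min takes the first (lower) tie
  tibble(position = x$arc_centers, value = x$map[i, ],
         z_requested = z, z_actual = x$z_centers[i])
}

#' @export
extract_profile.detector_image <- function(x, z = 0) {
  if (z < -x$detector$height / 2 || z > x$detector$height / 2)
    abort(sprintf("z = %g outside the detector extent [%g, %g]", z,
                  -x$detector$height / 2, x$detector$height / 2))
  i <- which.min(abs(x$row_centers - z))
  tibble(position = x$col_centers, value = x$image[i, ],
         z_requested = z, z_actual = x$row_centers[i])
}
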