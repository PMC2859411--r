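# Run-configuration files (YAML) and tabular/array output writers.
#
# A config file describes a full run:
#
#   scene:
#     ambient_n: 1.0
#     regions:
#     - id: 1
#       parent: 0            # 0 = root (ambient outside)
#       label: phantom
#       shape: {type: cylinder, center: [0, 0, 0], radius: 15, height: 30}
#       mu_a: 0.0138
#       mu_s: 9.1
#       g: 0.9
#       n: 1.0
#   source:
#     shape: {type: cylinder, center: [8, 0, 0], radius: 1, height: 2}
#     power: 1.0e-9
#   controls: {packets: 100000, seed: 1, workers: 1, voxel_pitch: 0.5,
#              roulette_threshold: 1.0e-4, roulette_m: 10, max_events: 1000000}
#   detector: {center: [256, 0, 0], normal: [-1, 0, 0], width: 16, height: 16,
#              rows: 64, cols: 64}
#   lens: {f: 55, u: 200, center: [200, 0, 0], axis: [1, 0, 0]}
#
# Shapes: cylinder (center, radius, height; axis along z), sphere (center,
# radius), ellipsoid (center, radii[3]), box (center, size[3]), mesh (file:
# OFF/PLY/STL path relative to the config file, or inline vertices/faces).
# detector/lens blocks are optional (only needed for free-space rendering).

#' Read and write run configuration files
#'
#' @param path Config file path (YAML).
#' @param config For `write_run_config()`: a list with elements `scene`
#'   ([scene()]), `source` ([source_spec()]), and optional `controls` (list),
#'   `detector` ([detector_spec()]), `lens` ([lens_spec()]).
#' @param containment Containment policy used when rebuilding the scene.
#' @return `read_run_config()`: a list with `scene`, `source`, `controls`,
#'   `detector`, `lens` (missing blocks are `NULL`).
#' @export
read_run_config <- function(path, containment = c("strict", "clip")) {
  containment <- match.arg(containment)
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  if (is.null(cfg$scene) || is.null(cfg$source))
    abort("config must contain `scene` and `source` blocks")
  regions <- lapply(cfg$scene$regions, function(r) {
    region(r$id, shape_from_config(r$shape, base),
           optical_properties(r$mu_a, r$mu_s, g = r$g %||% 0, n = r$n %||% 1),
           parent = r$parent %||% 0, label = r$label)
  })
  sc <- scene(regions, ambient_n = cfg$scene$ambient_n %||% 1.0,
              containment = containment)
  src <- source_spec(shape_from_config(cfg$source$shape, base),
                     power = cfg$source$power)
  det <- if (!is.null(cfg$detector))
    detector_spec(unlist(cfg$detector$center), unlist(cfg$detector$normal),
                  cfg$detector$width, cfg$detector$height,
                  cfg$detector$rows, cfg$detector$cols,
                  up = unlist(cfg$detector$up %||% c(0, 0, 1)))
  lens <- if (!is.null(cfg$lens))
    lens_spec(cfg$lens$f, cfg$lens$u, unlist(cfg$lens$center),
              unlist(cfg$lens$axis), v = cfg$lens$v)
  list(scene = sc, source = src, controls = cfg$controls,
       detector = det, lens = lens)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

shape_from_config <- function(s, base) {
  switch(s$type,
    cylinder = shape_cylinder(unlist(s$center), s$radius, s$height),
    sphere = shape_sphere(unlist(s$center), s$radius),
    ellipsoid = shape_ellipsoid(unlist(s$center), unlist(s$radii)),
    box = shape_box(unlist(s$center), unlist(s$size)),
    mesh = {
      if (!is.null(s$file)) read_mesh(file.path(base, s$file))
      else shape_mesh(matrix(unlist(s$vertices), ncol = 3, byrow = TRUE),
                      matrix(as.integer(unlist(s$faces)), ncol = 3,
                             byrow = TRUE))
    },
    abort(sprintf("unknown shape type '%s' in config", s$type)))
}

shape_to_config <- function(shape, path = NULL, name = "mesh") {
  s <- unclass(shape)
  switch(s$type,
    cylinder = list(type = "cylinder", center = s$center, radius = s$radius,
                    height = s$height),
    sphere = list(type = "sphere", center = s$center, radius = s$radius),
    ellipsoid = list(type = "ellipsoid", center = s$center, radii = s$radii),
    box = list(type = "box", center = s$center, size = s$size),
    mesh = {
      if (is.null(path)) abort("mesh shapes need a config path to write next to")
      file <- paste0(name, ".off")
      write_mesh(s, file.path(dirname(path), file), format = "off")
      list(type = "mesh", file = file)
    })
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  sc <- config$scene
  stopifnot(inherits(sc, "photon_scene"))
  regions <- lapply(sc$regions, function(r) {
    out <- list(id = r$id, parent = r$parent,
                shape = shape_to_config(r$shape, path,
                                        name = paste0("region", r$id)),
                mu_a = r$mu_a, mu_s = r$mu_s, g = r$g, n = r$n)
    if (!is.null(r$label)) out$label <- r$label
    out
  })
  cfg <- list(scene = list(ambient_n = sc$ambient_n, regions = regions),
              source = list(shape = shape_to_config(config$source$shape, path,
                                                    name = "source"),
                            power = config$source$power))
  if (!is.null(config$controls)) cfg$controls <- config$controls
  if (!is.null(config$detector)) {
    d <- config$detector
    cfg$detector <- list(center = d$center, normal = d$normal, width = d$width,
                         height = d$height, rows = d$rows, cols = d$cols,
                         up = d$up)
  }
  if (!is.null(config$lens)) {
    l <- config$lens
    cfg$lens <- list(f = l$f, u = l$u, v = l$v, center = l$center,
                     axis = l$axis)
  }
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' Write the transmission tally as a per-element table
#'
#' One row per surface element of an unwrapped map (element id, centroid,
#' area, accumulated power, flux density J_n), tab-separated.
#'
#' @param map A `cylinder_surface_map` (or a surface-element tibble).
#' @param path Output TSV path.
#' @export
write_transmission_table <- function(map, path) {
  s <- if (inherits(map, "cylinder_surface_map"))
    surface_elements(map, drop_empty = FALSE) else as_elements(map)
  s <- mutate(s, element = dplyr::row_number(), power = .data$j_n * .data$area)
  s <- select(s, "element", "x", "y", "z", "area", "power", "j_n")
  utils::write.table(s, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a surface map or detector image as a text grid
#'
#' Plain whitespace-separated matrix (one map row per line) preceded by `#`
#' comment lines recording the geometry, so the file is self-describing.
#'
#' @param x A `cylinder_surface_map` or `detector_image`.
#' @param path Output path.
#' @export
write_map <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(x, "cylinder_surface_map")) {
    writeLines(c("# photonmc cylinder surface flux map (W/mm^2)",
                 sprintf("# radius_mm %g height_mm %g rows %d cols %d pixel_area_mm2 %.10g",
                         x$radius, x$height, nrow(x$map), ncol(x$map),
                         x$pixel_area),
                 "# rows: z ascending; cols: arc length R*phi from +x, counterclockwise"),
               con)
    m <- x$map
  } else if (inherits(x, "detector_image")) {
    d <- x$detector
    writeLines(c("# photonmc detector image (W/pixel)",
                 sprintf("# center %g %g %g normal %g %g %g width_mm %g height_mm %g rows %d cols %d mode %s",
                         d$center[1], d$center[2], d$center[3], d$normal[1],
                         d$normal[2], d$normal[3], d$width, d$height, d$rows,
                         d$cols, x$mode)), con)
    m <- x$image
  } else abort("write_map() handles cylinder_surface_map or detector_image")
  utils::write.table(m, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write the absorption grid as flat binary plus a JSON header
#'
#' The voxel grid is stored as little-endian doubles in Fortran (column-major
#' x-fastest) order; the sidecar `<path>.json` records the grid origin,
#' pitch, dimensions and units, making the pair self-describing.
#'
#' @param sim A `photon_sim`.
#' @param path Output path for the binary block (sidecar is `<path>.json`).
#' @export
write_absorption_grid <- function(sim, path) {
  stopifnot(inherits(sim, "photon_sim"))
  con <- file(path, "wb")
  writeBin(as.numeric(sim$absorption), con, size = 8, endian = "little")
  close(con)
  jsonlite::write_json(
    list(format = "photonmc absorption grid v1",
         dtype = "float64_le", order = "column_major_x_fastest",
         origin_mm = sim$grid$lo, pitch_mm = sim$grid$pitch,
         dim = sim$grid$dim, units = "W"),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read back an absorption grid written by [write_absorption_grid()]
#'
#' @param path Path given to [write_absorption_grid()].
#' @return List with `absorption` (3D array) and `grid` metadata.
#' @export
read_absorption_grid <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- prod(hdr$dim)
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, "double", n, size = 8, endian = "little")
  list(absorption = array(v, dim = hdr$dim),
       grid = list(lo = hdr$origin_mm, pitch = hdr$pitch_mm, dim = hdr$dim))
}

#' Write a profile as a two-column TSV
#'
#' @param profile Tibble from [extract_profile()].
#' @param path Output path.
#' @export
write_profile <- function(profile, path) {
  utils::write.table(profile[, c("position", "value")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
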