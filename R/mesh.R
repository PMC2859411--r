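# Triangle-mesh input/output: OFF (ASCII), PLY (ASCII + binary little/big
# endian), STL (ASCII + binary), plus a tessellated-cylinder generator used in
# tests and examples.  Readers return a shape_mesh(), so closedness and
# orientation are validated on load.

#' Read a triangle mesh
#'
#' Supports OFF (ASCII), PLY (ASCII, binary little- and big-endian) and STL
#' (ASCII and binary).  Quads are fan-triangulated; STL facets with identical
#' coordinates are welded into shared vertices so the surface connectivity can
#' be validated.
#'
#' @param path File path.
#' @param format `"auto"` (by extension) or one of `"off"`, `"ply"`, `"stl"`.
#' @return A `shape_mesh()`.
#' @export
read_mesh <- function(path, format = c("auto", "off", "ply", "stl")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("off", "ply", "stl"))
      abort(sprintf("cannot infer mesh format from extension '.%s'", ext))
    format <- ext
  }
  switch(format,
         off = read_off(path),
         ply = read_ply(path),
         stl = read_stl(path))
}

#' Write a triangle mesh
#'
#' @param mesh A `shape_mesh()` (or any list with `vertices` and `faces`).
#' @param path Output path; format from `format` or the extension.
#' @param format `"auto"`, `"off"`, `"ply"` (ASCII) or `"stl"` (ASCII).
#' @export
write_mesh <- function(mesh, path, format = c("auto", "off", "ply", "stl")) {
  format <- match.arg(format)
  if (format == "auto") format <- tolower(tools::file_ext(path))
  v <- mesh$vertices
  f <- mesh$faces
  switch(format,
    off = {
      con <- file(path, "w")
      on.exit(close(con))
      writeLines("OFF", con)
      writeLines(sprintf("%d %d 0", nrow(v), nrow(f)), con)
      writeLines(sprintf("%.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]), con)
      writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L),
                 con)
    },
    ply = {
      con <- file(path, "w")
      on.exit(close(con))
      writeLines(c("ply", "format ascii 1.0",
                   sprintf("element vertex %d", nrow(v)),
                   "property double x", "property double y", "property double z",
                   sprintf("element face %d", nrow(f)),
                   "property list uchar int vertex_indices", "end_header"), con)
      writeLines(sprintf("%.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]), con)
      writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L),
                 con)
    },
    stl = {
      con <- file(path, "w")
      on.exit(close(con))
      writeLines("solid photonmc", con)
      for (i in seq_len(nrow(f))) {
        a <- v[f[i, 1], ]; b <- v[f[i, 2], ]; cc <- v[f[i, 3], ]
        nrm <- pracma_cross(b - a, cc - a)
        nl <- sqrt(sum(nrm^2))
        if (nl > 0) nrm <- nrm / nl
        writeLines(c(sprintf("  facet normal %g %g %g", nrm[1], nrm[2], nrm[3]),
                     "    outer loop",
                     sprintf("      vertex %.9g %.9g %.9g", a[1], a[2], a[3]),
                     sprintf("      vertex %.9g %.9g %.9g", b[1], b[2], b[3]),
                     sprintf("      vertex %.9g %.9g %.9g", cc[1], cc[2], cc[3]),
                     "    endloop", "  endfacet"), con)
      }
      writeLines("endsolid photonmc", con)
    },
    abort(sprintf("unsupported mesh format '%s'", format)))
  invisible(path)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

read_off <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (toupper(toks[1]) != "OFF") abort("not an OFF file")
  nv <- as.integer(toks[2]); nf <- as.integer(toks[3])
  i <- 5L
  v <- matrix(as.numeric(toks[i:(i + 3L * nv - 1L)]), nv, 3, byrow = TRUE)
  i <- i + 3L * nv
  faces <- list()
  for (k in seq_len(nf)) {
    m <- as.integer(toks[i]); idx <- as.integer(toks[(i + 1L):(i + m)]) + 1L
    faces[[k]] <- fan_triangulate(idx)
    i <- i + m + 1L
  }
  f <- do.call(rbind, faces)
  shape_mesh(v, f)
}

fan_triangulate <- function(idx) {
  if (length(idx) < 3) abort("mesh face with fewer than 3 vertices")
  if (length(idx) == 3) return(matrix(idx, 1, 3))
  cbind(idx[1], idx[2:(length(idx) - 1)], idx[3:length(idx)])
}

ply_type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                   short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                   int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

ply_read_scalar <- function(con, type, endian) {
  sz <- ply_type_size[[type]]
  if (type %in% c("float", "float32", "double", "float64"))
    readBin(con, "double", 1, size = sz, endian = endian)
  else
    readBin(con, "integer", 1, size = sz,
            signed = !(type %in% c("uchar", "uint8", "ushort", "uint16")),
            endian = endian)
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  # header is always ASCII lines
  header <- character()
  repeat {
    line <- readLines(con, 1)
    if (!length(line)) abort("truncated PLY header")
    header <- c(header, line)
    if (trimws(line) == "end_header") break
  }
  if (trimws(header[1]) != "ply") abort("not a PLY file")
  fmt_line <- grep("^format", trimws(header), value = TRUE)[1]
  fmt <- strsplit(trimws(fmt_line), "\\s+")[[1]][2]

  elements <- list()  # name -> list(count, props)
  cur <- NULL
  for (line in trimws(header)) {
    t <- strsplit(line, "\\s+")[[1]]
    if (t[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = t[2], count = as.integer(t[3]), props = list())
    } else if (t[1] == "property" && !is.null(cur)) {
      cur$props[[length(cur$props) + 1]] <-
        if (t[2] == "list") list(list = TRUE, count_type = t[3],
                                 type = t[4], name = t[5])
        else list(list = FALSE, type = t[2], name = t[3])
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  if (is.null(elements$vertex) || is.null(elements$face))
    abort("PLY file lacks vertex or face elements")

  if (fmt == "ascii") {
    toks <- scan(con, what = character(), quiet = TRUE)
    pos <- 1L
    nv <- elements$vertex$count
    np <- length(elements$vertex$props)
    vm <- matrix(as.numeric(toks[pos:(pos + nv * np - 1L)]), nv, np,
                 byrow = TRUE)
    pos <- pos + nv * np
    pnames <- vapply(elements$vertex$props, `[[`, "", "name")
    v <- vm[, match(c("x", "y", "z"), pnames), drop = FALSE]
    faces <- vector("list", elements$face$count)
    for (k in seq_len(elements$face$count)) {
      m <- as.integer(toks[pos])
      idx <- as.integer(toks[(pos + 1L):(pos + m)]) + 1L
      faces[[k]] <- fan_triangulate(idx)
      pos <- pos + m + 1L
    }
  } else {
    endian <- if (fmt == "binary_little_endian") "little" else "big"
    nv <- elements$vertex$count
    props <- elements$vertex$props
    v <- matrix(NA_real_, nv, 3)
    pnames <- vapply(props, `[[`, "", "name")
    for (i in seq_len(nv)) {
      for (j in seq_along(props)) {
        val <- ply_read_scalar(con, props[[j]]$type, endian)
        k <- match(pnames[j], c("x", "y", "z"))
        if (!is.na(k)) v[i, k] <- val
      }
    }
    fprop <- elements$face$props[[1]]
    if (!isTRUE(fprop$list)) abort("unsupported PLY face encoding")
    faces <- vector("list", elements$face$count)
    for (k in seq_len(elements$face$count)) {
      m <- ply_read_scalar(con, fprop$count_type, endian)
      idx <- integer(m)
      for (j in seq_len(m)) idx[j] <- ply_read_scalar(con, fprop$type, endian)
      faces[[k]] <- fan_triangulate(idx + 1L)
    }
  }
  shape_mesh(v, do.call(rbind, faces))
}

read_stl <- function(path) {
  # binary STL: 80-byte header, uint32 facet count, 50 bytes per facet
  sz <- file.size(path)
  con <- file(path, "rb")
  on.exit(close(con))
  head80 <- readBin(con, "raw", 80)
  is_binary <- FALSE
  if (sz >= 84) {
    n <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (!is.na(n) && sz == 84 + 50 * as.double(n)) is_binary <- TRUE
  }
  if (is_binary) {
    raw <- readBin(con, "raw", sz - 84)
    vals <- matrix(NA_real_, n, 12)
    for (i in seq_len(n)) {
      off <- (i - 1L) * 50L
      vals[i, ] <- readBin(raw[(off + 1):(off + 48)], "double", 12, size = 4,
                           endian = "little")
    }
    tri <- vals[, 4:12, drop = FALSE]  # drop facet normals, keep 3 vertices
  } else {
    close(con)
    on.exit()
    lines <- readLines(path, warn = FALSE)
    vlines <- grep("^\\s*vertex", lines, value = TRUE)
    nums <- do.call(rbind, lapply(strsplit(trimws(vlines), "\\s+"),
                                  function(t) as.numeric(t[2:4])))
    if (nrow(nums) %% 3 != 0) abort("malformed ASCII STL")
    tri <- matrix(t(nums), ncol = 9, byrow = TRUE)
  }
  weld_triangle_soup(tri)
}

# merge per-facet vertices that share exact printed coordinates
weld_triangle_soup <- function(tri) {
  pts <- rbind(tri[, 1:3], tri[, 4:6], tri[, 7:9])
  key <- paste(pts[, 1], pts[, 2], pts[, 3])
  uid <- !duplicated(key)
  v <- pts[uid, , drop = FALSE]
  idx <- match(key, key[uid])
  nf <- nrow(tri)
  f <- cbind(idx[seq_len(nf)], idx[nf + seq_len(nf)], idx[2 * nf + seq_len(nf)])
  shape_mesh(v, f)
}

#' Tessellated cylinder mesh
#'
#' Closed, outward-oriented triangle mesh of an axis-aligned (z) cylinder:
#' `n_theta` segments around the circumference, triangulated side wall and
#' fan-capped ends.  Used to cross-check mesh transport against the analytic
#' cylinder.
#'
#' @param radius,height Cylinder dimensions (mm).
#' @param center Length-3 centre (mm).
#' @param n_theta Number of circumferential segments (>= 3).
#' @return A `shape_mesh()`.
#' @export
mesh_cylinder <- function(radius, height, center = c(0, 0, 0), n_theta = 64) {
  stopifnot(n_theta >= 3)
  th <- 2 * pi * (seq_len(n_theta) - 1) / n_theta
  z0 <- center[3] - height / 2
  z1 <- center[3] + height / 2
  ring <- cbind(center[1] + radius * cos(th), center[2] + radius * sin(th))
  v <- rbind(cbind(ring, z0), cbind(ring, z1),
             c(center[1], center[2], z0), c(center[1], center[2], z1))
  cb <- 2L * n_theta + 1L  # bottom centre
  ct <- 2L * n_theta + 2L  # top centre
  k <- seq_len(n_theta)
  k2 <- c(seq_len(n_theta)[-1], 1L)
  f <- rbind(cbind(k, k2, n_theta + k2),            # side, lower triangles
             cbind(k, n_theta + k2, n_theta + k),   # side, upper triangles
             cbind(cb, k2, k),                      # bottom cap (normal -z)
             cbind(ct, n_theta + k, n_theta + k2))  # top cap (normal +z)
  shape_mesh(v, f)
}
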