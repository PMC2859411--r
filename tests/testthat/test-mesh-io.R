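# Mesh format round-trips, run-config round-trips and array/table writers.

test_that("mesh validation rejects holes and inconsistent winding", {
  m <- mesh_cylinder(3, 5, n_theta = 12)
  expect_s3_class(m, "photon_shape")
  # removing a face opens the surface
  expect_error(shape_mesh(m$vertices, m$faces[-1, ]), "not closed")
  # flipping one face breaks the consistent orientation
  flipped <- m$faces
  flipped[1, ] <- flipped[1, c(2, 1, 3)]
  expect_error(shape_mesh(m$vertices, flipped), "orient")
  # a zero-area triangle warns once at load (pad with its reverse to keep
  # the edge balance intact)
  v2 <- rbind(m$vertices, m$vertices[1, ] + c(0, 0, 1e-15))
  degen <- rbind(m$faces,
                 c(1L, 2L, nrow(v2)),
                 c(2L, 1L, nrow(v2)))
  expect_warning(shape_mesh(v2, degen), "degenerate")
})

test_that("OFF, PLY and STL ASCII files round-trip through read/write", {
  m <- mesh_cylinder(4, 7, n_theta = 16)
  for (fmt in c("off", "ply", "stl")) {
    path <- file.path(tempdir(), paste0("rt.", fmt))
    write_mesh(m, path)
    m2 <- read_mesh(path)
    if (fmt == "stl") {
      # STL stores a triangle soup; welding recovers the same surface
      expect_equal(nrow(m2$faces), nrow(m$faces))
      expect_equal(sum(photonmc:::triangle_areas(m2$vertices, m2$faces)),
                   sum(photonmc:::triangle_areas(m$vertices, m$faces)),
                   tolerance = 1e-6)
    } else {
      expect_equal(m2$vertices, m$vertices, ignore_attr = TRUE)
      expect_equal(m2$faces, m$faces, ignore_attr = TRUE)
    }
  }
})

test_that("binary PLY and binary STL are read correctly", {
  m <- mesh_cylinder(3, 4, n_theta = 10)
  # binary little-endian PLY written directly in the test
  ply <- file.path(tempdir(), "bin.ply")
  con <- file(ply, "wb")
  writeLines(c("ply", "format binary_little_endian 1.0",
               sprintf("element vertex %d", nrow(m$vertices)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(m$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  for (i in seq_len(nrow(m$vertices)))
    writeBin(as.numeric(m$vertices[i, ]), con, size = 4, endian = "little")
  for (i in seq_len(nrow(m$faces))) {
    writeBin(as.raw(3), con)
    writeBin(as.integer(m$faces[i, ] - 1L), con, size = 4, endian = "little")
  }
  close(con)
  m2 <- read_mesh(ply)
  expect_equal(m2$faces, m$faces, ignore_attr = TRUE)
  expect_equal(m2$vertices, m$vertices, tolerance = 1e-6, ignore_attr = TRUE)
  # binary STL written directly in the test
  stl <- file.path(tempdir(), "bin.stl")
  con <- file(stl, "wb")
  writeBin(raw(80), con)
  writeBin(as.integer(nrow(m$faces)), con, size = 4, endian = "little")
  for (i in seq_len(nrow(m$faces))) {
    writeBin(numeric(3), con, size = 4, endian = "little")  # facet normal
    for (j in 1:3)
      writeBin(as.numeric(m$vertices[m$faces[i, j], ]), con, size = 4,
               endian = "little")
    writeBin(as.raw(c(0, 0)), con)
  }
  close(con)
  m3 <- read_mesh(stl)
  expect_equal(nrow(m3$faces), nrow(m$faces))
  expect_equal(sum(photonmc:::triangle_areas(m3$vertices, m3$faces)),
               sum(photonmc:::triangle_areas(m$vertices, m$faces)), tolerance = 1e-5)
})

test_that("run configs round-trip scenes, sources, detector and lens", {
  fx <- homogeneous_cylinder_phantom(n = 1.37)
  cfg <- list(scene = fx$scene, source = fx$source,
              controls = list(packets = 1000L, seed = 1L, workers = 2L,
                              voxel_pitch = 0.5),
              detector = detector_spec(c(256, 0, 0), c(-1, 0, 0), 16, 16,
                                       32, 32),
              lens = lens_spec(55, 200, c(200, 0, 0), c(1, 0, 0)))
  path <- file.path(tempdir(), "run.yaml")
  write_run_config(cfg, path)
  back <- read_run_config(path)
  r0 <- fx$scene$regions[[1]]
  r1 <- back$scene$regions[[1]]
  for (f in c("id", "parent", "mu_a", "mu_s", "g", "n"))
    expect_equal(r1[[f]], r0[[f]])
  expect_equal(unclass(r1$shape), unclass(r0$shape))
  expect_equal(unclass(back$source$shape), unclass(fx$source$shape))
  expect_equal(back$source$power, 1e-9)
  expect_equal(back$controls$packets, 1000L)
  expect_equal(back$detector$center, c(256, 0, 0))
  expect_equal(back$detector$dA, cfg$detector$dA)
  expect_equal(back$lens$t, cfg$lens$t)
  # mesh regions round-trip through an OFF sidecar
  msc <- scene(region(1, mesh_cylinder(5, 8, n_theta = 12),
                      optical_properties(0.1, 1)))
  mpath <- file.path(tempdir(), "mesh_run.yaml")
  write_run_config(list(scene = msc,
                        source = source_spec(shape_sphere(radius = 0.5),
                                             1e-9)),
                   mpath)
  mback <- read_run_config(mpath)
  expect_equal(mback$scene$regions[[1]]$shape$vertices,
               msc$regions[[1]]$shape$vertices, ignore_attr = TRUE)
  expect_equal(mback$scene$regions[[1]]$shape$faces,
               msc$regions[[1]]$shape$faces, ignore_attr = TRUE)
})

test_that("absorption grids, maps, tables and profiles write and read back", {
  fx <- homogeneous_cylinder_phantom()
  sim <- simulate_photons(fx$scene, fx$source, n_packets = 2000, seed = 3)
  base <- tempdir()
  # flat binary + JSON header round-trip
  gpath <- file.path(base, "absorb.bin")
  write_absorption_grid(sim, gpath)
  back <- read_absorption_grid(gpath)
  expect_equal(back$absorption, sim$absorption, ignore_attr = TRUE)
  expect_equal(back$grid$pitch, sim$grid$pitch)
  # surface map text grid
  map <- rasterize_cylinder_surface(sim, rows = 10, cols = 30)
  mpath <- file.path(base, "map.tsv")
  write_map(map, mpath)
  vals <- as.matrix(utils::read.table(mpath, comment.char = "#"))
  expect_equal(unname(vals), unname(map$map), tolerance = 1e-12)
  # per-element transmission table
  tpath <- file.path(base, "trans.tsv")
  write_transmission_table(map, tpath)
  tab <- utils::read.table(tpath, header = TRUE)
  expect_equal(nrow(tab), 10 * 30)
  expect_equal(sum(tab$power), map$side_power, tolerance = 1e-9)
  # profile writer
  ppath <- file.path(base, "prof.tsv")
  write_profile(extract_profile(map, 0), ppath)
  prof <- utils::read.table(ppath, header = TRUE)
  expect_equal(prof$value, extract_profile(map, 0)$value, tolerance = 1e-12)
})

test_that("absorption_table returns voxel centres on the grid", {
  sc <- scene(region(1, shape_box(size = c(4, 4, 4)),
                     optical_properties(5, 0)))
  src <- source_spec(shape_sphere(radius = 0.05), 1e-9)
  sim <- simulate_photons(sc, src, n_packets = 500, seed = 1,
                          voxel_pitch = 1)
  ab <- absorption_table(sim)
  expect_true(all(ab$absorbed > 0))
  expect_true(all(ab$x %in% c(-1.5, -0.5, 0.5, 1.5)))
  expect_equal(sum(ab$absorbed), sim$summary$absorbed, tolerance = 1e-12)
})
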