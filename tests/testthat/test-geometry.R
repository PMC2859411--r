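# Region containment, boundary-hit queries and ray-triangle intersection.

props <- optical_properties(0.0138, 9.1, g = 0.9)

test_that("point membership matches the phantom geometry", {
  cyl <- shape_cylinder(c(0, 0, 0), radius = 15, height = 30)
  expect_true(point_in_region(c(0, 0, 0), cyl))
  expect_false(point_in_region(c(16, 0, 0), cyl))
  expect_false(point_in_region(c(0, 0, 15.001), cyl))
  src <- shape_cylinder(c(8, 0, 0), radius = 1, height = 2)
  expect_true(point_in_region(c(8, 0, 0), src))
  # vectorized over a matrix of points
  pts <- rbind(c(0, 0, 0), c(14.9, 0, 0), c(0, 15.1, 0))
  expect_equal(point_in_region(pts, cyl), c(TRUE, TRUE, FALSE))
})

test_that("membership works for sphere, ellipsoid and box", {
  expect_true(point_in_region(c(0.9, 0, 0), shape_sphere(radius = 1)))
  expect_false(point_in_region(c(1.1, 0, 0), shape_sphere(radius = 1)))
  ell <- shape_ellipsoid(radii = c(1, 2, 3))
  expect_true(point_in_region(c(0, 1.9, 0), ell))
  expect_false(point_in_region(c(0, 2.1, 0), ell))
  box <- shape_box(size = c(2, 4, 6))
  expect_true(point_in_region(c(0.9, 1.9, 2.9), box))
  expect_false(point_in_region(c(1.1, 0, 0), box))
})

test_that("nearest boundary hits the analytic cylinder where expected", {
  sc <- scene(region(1, shape_cylinder(c(0, 0, 0), radius = 15, height = 30),
                     props))
  h <- nearest_boundary_hit(sc, c(0, 0, 0), c(1, 0, 0), 1)
  expect_equal(h$distance, 15, tolerance = 1e-12)
  expect_equal(h$next_region, 0)           # ambient
  expect_equal(h$normal, c(1, 0, 0), tolerance = 1e-12)
  h2 <- nearest_boundary_hit(sc, c(0, 0, 0), c(0, 0, 1), 1)
  expect_equal(h2$distance, 15, tolerance = 1e-12)  # top cap
  expect_equal(h2$element, 3)
  h3 <- nearest_boundary_hit(sc, c(8, 0, 0), c(1, 0, 0), 1)
  expect_equal(h3$distance, 7, tolerance = 1e-12)   # 15 - 8
  expect_equal(h3$next_region, 0)
})

test_that("nearest boundary sees child surfaces and reports the far side", {
  sc <- scene(region(1, shape_cylinder(radius = 10, height = 20), props),
              region(2, shape_sphere(c(4, 0, 0), radius = 2), props,
                     parent = 1))
  h <- nearest_boundary_hit(sc, c(0, 0, 0), c(1, 0, 0), 1)
  expect_equal(h$distance, 2, tolerance = 1e-12)  # sphere near side at x = 2
  expect_equal(h$surface_region, 2)
  expect_equal(h$next_region, 2)
  # from inside the child: far side of the sphere, then back into region 1
  h2 <- nearest_boundary_hit(sc, c(4, 0, 0), c(1, 0, 0), 2)
  expect_equal(h2$distance, 2, tolerance = 1e-12)
  expect_equal(h2$next_region, 1)
  # a query from a point outside the stated region is a geometry error
  expect_error(nearest_boundary_hit(sc, c(20, 0, 0), c(1, 0, 0), 1),
               "inconsistency")
})

test_that("ray-triangle intersection matches forced cases and the R oracle", {
  tri <- rbind(c(-1, -1, 0), c(2, -1, 0), c(-1, 2, 0))
  expect_equal(ray_triangle_intersect(c(0, 0, -1), c(0, 0, 1), tri), 1)
  tri10 <- tri
  tri10[, 3] <- 10
  expect_equal(ray_triangle_intersect(c(0, 0, -1), c(0, 0, 1), tri10), 11)
  # parallel to the plane -> miss
  expect_true(is.na(ray_triangle_intersect(c(0, 0, 1), c(1, 0, 0), tri)))
  # degenerate (zero-area) triangle -> miss
  degen <- rbind(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2))
  expect_true(is.na(ray_triangle_intersect(c(0, 0, -1), c(0, 0, 1), degen)))
  # random rays against a random triangle vs the pure-R implementation
  set.seed(42)
  for (k in 1:50) {
    t3 <- matrix(rnorm(9), 3, 3)
    p <- rnorm(3)
    d <- unit(rnorm(3))
    got <- ray_triangle_intersect(p, d, t3)
    want <- r_ray_triangle(p, d, t3[1, ], t3[2, ], t3[3, ])
    if (is.na(want)) expect_true(is.na(got))
    else expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("scene validation enforces tree structure and containment", {
  # two roots
  expect_error(scene(region(1, shape_sphere(radius = 5), props),
                     region(2, shape_sphere(radius = 1), props)),
               "exactly one region")
  # unknown parent
  expect_error(scene(region(1, shape_sphere(radius = 5), props),
                     region(2, shape_sphere(radius = 1), props, parent = 9)),
               "unknown parent")
  # child sticking out of its parent is rejected under strict containment
  expect_error(scene(region(1, shape_sphere(radius = 5), props),
                     region(2, shape_sphere(c(4.5, 0, 0), radius = 2), props,
                            parent = 1)),
               "containment")
  # ... and recorded under clip
  expect_warning(
    sc <- scene(region(1, shape_sphere(radius = 5), props),
                region(2, shape_sphere(c(4.5, 0, 0), radius = 2), props,
                       parent = 1),
                containment = "clip"),
    "clip")
  expect_gt(nrow(attr(sc, "containment_report")), 0)
  # overlapping siblings are rejected
  expect_error(scene(region(1, shape_sphere(radius = 10), props),
                     region(2, shape_sphere(c(1, 0, 0), radius = 2), props,
                            parent = 1),
                     region(3, shape_sphere(c(-1, 0, 0), radius = 2), props,
                            parent = 1)),
               "overlap")
})

test_that("closed meshes always return a boundary hit from inside", {
  m <- mesh_cylinder(5, 8, n_theta = 24)
  sc <- scene(region(1, m, props))
  stream <- substreams(7, 1)[[1]]
  pts <- sample_source_position(source_spec(shape_cylinder(radius = 4.5,
                                                           height = 7),
                                            1e-9), stream, 300)
  dirs <- sample_isotropic_direction(stream, 300)
  for (i in seq_len(300)) {
    h <- nearest_boundary_hit(sc, as.numeric(pts[i, ]), as.numeric(dirs[i, ]),
                              1)
    expect_false(is.null(h))
    expect_gt(h$distance, 0)
  }
})

test_that("meshed and analytic cylinders agree within tessellation error", {
  n_theta <- 128
  sag <- 15 * (1 - cos(pi / n_theta))  # chord sagitta of the side wall
  m <- mesh_cylinder(15, 30, n_theta = n_theta)
  sc_m <- scene(region(1, m, props))
  sc_a <- scene(region(1, shape_cylinder(radius = 15, height = 30), props))
  set.seed(3)
  for (k in 1:100) {
    p <- c(runif(2, -8, 8), runif(1, -10, 10))
    d <- unit(rnorm(3))
    ha <- nearest_boundary_hit(sc_a, p, d, 1)
    hm <- nearest_boundary_hit(sc_m, p, d, 1)
    # the inscribed mesh can only shorten the hit; grazing rays amplify the
    # sagitta, hence the slack factor
    expect_lt(abs(hm$distance - ha$distance), 4 * sag)
  }
})

test_that("mesh membership agrees with the R crossing-parity oracle", {
  m <- mesh_cylinder(4, 6, n_theta = 16)
  set.seed(9)
  pts <- cbind(runif(120, -5, 5), runif(120, -5, 5), runif(120, -4, 4))
  got <- point_in_region(pts, m)
  want <- vapply(seq_len(nrow(pts)), function(i)
    r_point_in_mesh(pts[i, ], m$vertices, m$faces), logical(1))
  expect_equal(got, want)
})
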