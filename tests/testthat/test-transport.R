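# Sampling primitives, boundary physics and the full packet life cycle.

props_41 <- optical_properties(0.0138, 9.1, g = 0.9)

test_that("source sampling stays inside the shape and fills the bbox rule", {
  stream <- substreams(11, 1)[[1]]
  # box source equals its own bounding box: every candidate accepted
  p <- sample_source_position(source_spec(shape_box(size = c(2, 3, 4)), 1),
                              stream, 2000)
  expect_true(all(abs(p$x) < 1 & abs(p$y) < 1.5 & abs(p$z) < 2))
  # source cylinder r=1 h=2 at (8,0,0): all samples satisfy the cylinder
  src <- source_spec(shape_cylinder(c(8, 0, 0), radius = 1, height = 2), 1e-9)
  q <- sample_source_position(src, stream, 1e4)
  expect_true(all((q$x - 8)^2 + q$y^2 <= 1 + 1e-12))
  expect_true(all(abs(q$z) <= 1 + 1e-12))
})

test_that("sphere rejection rate matches the sphere/box volume ratio", {
  stream <- substreams(5, 1)[[1]]
  n <- 2e4
  m <- rcpp_sample_in_shape(unclass(shape_sphere(radius = 1)), stream$ptr,
                            as.integer(n))
  rate <- n / attr(m, "attempts")
  p0 <- pi / 6
  expect_lt(abs(rate - p0), 3 * sqrt(p0 * (1 - p0) / n))
})

test_that("isotropic directions follow the azimuth/inclination map", {
  d <- isotropic_direction(0.5, 0.5)
  expect_equal(as.numeric(d), c(-1, 0, 0), tolerance = 1e-12)
  expect_equal(as.numeric(isotropic_direction(0, 1)), c(0, 0, 1),
               tolerance = 1e-12)
  expect_equal(as.numeric(isotropic_direction(0, 0)), c(0, 0, -1),
               tolerance = 1e-7)
  s <- substreams(3, 1)[[1]]
  m <- sample_isotropic_direction(s, 1e5)
  expect_unit_norm(m)
  for (comp in list(m$dx, m$dy, m$dz))
    expect_lt(abs(mean(comp)), 3 * sqrt(1 / 3) / sqrt(1e5))
})

test_that("free paths follow the exponential inverse-CDF", {
  expect_equal(free_path(exp(-1), optical_properties(0.5, 0.5)), 1)
  expect_equal(free_path(1, props_41), 0)
  expect_error(free_path(0, props_41), "xi")
  s <- substreams(8, 1)[[1]]
  x <- sample_free_path(props_41, s, 1e5)
  mu_t <- 0.0138 + 9.1
  expect_lt(abs(mean(x) - 1 / mu_t), 3 * (1 / mu_t) / sqrt(1e5))
})

test_that("absorption deposits follow the single-interaction albedo", {
  d <- deposit_absorption(1, optical_properties(1, 3))
  expect_equal(d$delta_w, 0.25)
  expect_equal(d$w_after, 0.75)
  expect_equal(deposit_absorption(2, optical_properties(0, 5))$delta_w, 0)
  # k interactions leave W = albedo^k exactly
  pr <- optical_properties(0.2, 0.8)
  w <- 1
  for (k in 1:20) w <- deposit_absorption(w, pr)$w_after
  expect_equal(w, 0.8^20, tolerance = 1e-14)
})

test_that("Henyey-Greenstein sampling has the right support and mean", {
  expect_equal(hg_cos_theta(1, 0.7), 1)
  expect_equal(hg_cos_theta(0, 0.7), -1)
  expect_error(hg_cos_theta(0.5, 1), "anisotropy")
  s <- substreams(12, 1)[[1]]
  u <- stream_uniform(s, 1e5)
  # g = 0 branch is uniform on [-1, 1]
  ct0 <- hg_cos_theta(u, 0)
  expect_equal(ct0, 2 * u - 1)
  expect_gt(suppressWarnings(
    stats::ks.test(ct0, "punif", min = -1, max = 1)$p.value), 0.001)
  # E[cos theta] = g
  for (g in c(0.5, 0.9)) {
    ct <- hg_cos_theta(stream_uniform(s, 1e5), g)
    expect_lt(abs(mean(ct) - g), 3 * sd(ct) / sqrt(1e5))
  }
  # deflected directions are unit and their dot with old_dir has mean g
  old <- unit(c(1, -2, 0.5))
  m <- sample_scatter_direction(old, 0.9, s, 2e4)
  expect_unit_norm(m)
  dots <- as.matrix(m) %*% old
  expect_lt(abs(mean(dots) - 0.9), 3 * sd(dots) / sqrt(2e4))
})

test_that("critical angle follows the rarer-medium convention", {
  expect_equal(critical_angle(1.5, 1.0), asin(2 / 3))
  expect_equal(critical_angle(1.0, 1.0), pi / 2)
  expect_equal(critical_angle(1.0, 1.5), pi / 2)
})

test_that("Fresnel reflectance matches the closed form and is reciprocal", {
  expect_equal(fresnel_reflectance(0, 1, 1.5), 0.04)
  expect_equal(fresnel_reflectance(0.3, 1.2, 1.2), 0)
  expect_equal(fresnel_reflectance(60 * pi / 180, 1.5, 1), 1)  # beyond theta_c
  th <- seq(0, 89, by = 1) * pi / 180
  for (pair in list(c(1, 1.5), c(1.37, 1), c(1, 1.33), c(1.6, 1.2))) {
    expect_equal(fresnel_reflectance(th, pair[1], pair[2]),
                 r_fresnel(th, pair[1], pair[2]), tolerance = 1e-9)
  }
  # reciprocity on sub-critical angles
  for (ti in c(0.1, 0.4, 0.6)) {
    tt <- asin(1.0 * sin(ti) / 1.5)
    expect_equal(fresnel_reflectance(ti, 1.0, 1.5),
                 fresnel_reflectance(tt, 1.5, 1.0), tolerance = 1e-12)
  }
})

test_that("reflection and refraction directions follow the vector forms", {
  expect_equal(reflect_direction(c(0, 0, -1), c(0, 0, 1)), c(0, 0, 1))
  # matched indices: direction unchanged
  I <- unit(c(0.3, -0.2, -1))
  expect_equal(refract_direction(I, c(0, 0, 1), 1.4, 1.4), I,
               tolerance = 1e-12)
  # Snell: 30 degrees into n = 1.5 bends to asin(1/3)
  I30 <- c(sin(pi / 6), 0, -cos(pi / 6))
  Tv <- refract_direction(I30, c(0, 0, 1), 1, 1.5)
  expect_equal(acos(abs(Tv[3])), asin(1 / 3), tolerance = 1e-12)
  expect_equal(sqrt(sum(Tv^2)), 1, tolerance = 1e-12)
  # the transmitted ray keeps the tangential orientation and the normal sign
  expect_gt(Tv[1], 0)
  expect_lt(Tv[3], 0)
  # random-case unit-norm preservation
  set.seed(4)
  for (k in 1:50) {
    I <- unit(rnorm(3))
    N <- unit(rnorm(3))
    expect_equal(sqrt(sum(reflect_direction(I, N)^2)), 1, tolerance = 1e-9)
    expect_equal(sqrt(sum(refract_direction(I, N, 1.2, 1.4)^2)), 1,
                 tolerance = 1e-9)
  }
  expect_error(reflect_direction(c(0, 0, 2), c(0, 0, 1)), "unit")
})

test_that("roulette outcomes are mW or 0 and unbiased in expectation", {
  s <- substreams(21, 1)[[1]]
  w <- roulette(rep(1e-5, 2e4), s, m = 10)
  expect_true(all(w %in% c(0, 1e-4)))
  expect_lt(abs(mean(w) - 1e-5), 3 * sd(w) / sqrt(2e4))
  expect_error(roulette(1, s, m = 1), "m must exceed")
})

test_that("a pure absorber in a huge region absorbs everything", {
  sc <- scene(region(1, shape_sphere(radius = 2000),
                     optical_properties(0.01, 0)))
  src <- source_spec(shape_sphere(radius = 0.1), 1e-9)
  sim <- simulate_photons(sc, src, n_packets = 2000, seed = 2,
                          voxel_pitch = 50)
  g <- glance(sim)
  expect_equal(g$absorbed, g$launched, tolerance = 1e-3)
  expect_equal(g$transmitted, 0)
})

test_that("energy is conserved on both phantom fixtures", {
  for (fx in list(homogeneous_cylinder_phantom(),
                  suppressWarnings(heterogeneous_phantom()))) {
    sim <- simulate_photons(fx$scene, fx$source, n_packets = 1e4, seed = 6)
    g <- glance(sim)
    # roulette is the only non-conserving step; 5 pooled sigma of its noise
    # is far below 1% at this scale
    expect_lt(abs(g$absorbed + g$transmitted + g$lost - g$launched) /
                g$launched, 0.01)
    expect_equal(g$packet_power * g$n_packets, g$launched)
  }
})

test_that("exit events lie on the root surface", {
  fx <- homogeneous_cylinder_phantom()
  sim <- simulate_photons(fx$scene, fx$source, n_packets = 3000, seed = 13)
  ex <- tidy(sim)
  expect_gt(nrow(ex), 0)
  rho <- sqrt(ex$x^2 + ex$y^2)
  on_side <- abs(rho - 15) < 1e-6
  on_cap <- abs(abs(ex$z) - 15) < 1e-6
  expect_true(all(on_side | on_cap))
  expect_true(all(ex$element[on_side & !on_cap] == 1))
  expect_true(all(ex$weight > 0))
})

test_that("runs are bit-identical for a fixed seed and worker count", {
  fx <- homogeneous_cylinder_phantom()
  a <- simulate_photons(fx$scene, fx$source, n_packets = 5000, seed = 9,
                        workers = 3)
  b <- simulate_photons(fx$scene, fx$source, n_packets = 5000, seed = 9,
                        workers = 3)
  expect_identical(a$absorption, b$absorption)
  expect_identical(a$exits, b$exits)
  expect_identical(glance(a), glance(b))
})

test_that("a mismatched-index boundary reflects part of the light back", {
  fx_matched <- homogeneous_cylinder_phantom(n = 1.0)
  fx_mism <- homogeneous_cylinder_phantom(n = 1.37)
  a <- simulate_photons(fx_matched$scene, fx_matched$source,
                        n_packets = 5000, seed = 31)
  b <- simulate_photons(fx_mism$scene, fx_mism$source,
                        n_packets = 5000, seed = 31)
  # internal reflection keeps packets inside longer: more absorption
  expect_gt(glance(b)$absorbed, glance(a)$absorbed)
  expect_lt(abs(glance(b)$energy_closure - 1), 0.01)
})

test_that("transport through a meshed cylinder matches the analytic one", {
  fx <- homogeneous_cylinder_phantom()
  m <- mesh_cylinder(15, 30, n_theta = 96)
  sc_m <- scene(region(1, m, optical_properties(0.0138, 9.1, g = 0.9)))
  a <- simulate_photons(fx$scene, fx$source, n_packets = 1e4, seed = 17)
  b <- simulate_photons(sc_m, fx$source, n_packets = 1e4, seed = 18)
  ga <- glance(a)
  gb <- glance(b)
  # absorbed fractions agree within Monte Carlo noise (binomial 5 sigma)
  pa <- ga$absorbed / ga$launched
  pb <- gb$absorbed / gb$launched
  se <- sqrt(pa * (1 - pa) / 1e4 + pb * (1 - pb) / 1e4)
  expect_lt(abs(pa - pb), 5 * se + 0.01)
})
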