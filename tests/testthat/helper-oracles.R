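# Independent pure-R oracles used to cross-check the compiled engine.

# Moller-Trumbore in plain R (independent of the compiled implementation)
r_ray_triangle <- function(p, d, a, b, cc) {
  cross <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                            u[3] * v[1] - u[1] * v[3],
                            u[1] * v[2] - u[2] * v[1])
  e1 <- b - a
  e2 <- cc - a
  h <- cross(d, e2)
  det <- sum(e1 * h)
  if (abs(det) < 1e-12) return(NA_real_)
  s <- p - a
  u <- sum(s * h) / det
  if (u < -1e-12 || u > 1 + 1e-12) return(NA_real_)
  q <- cross(s, e1)
  v <- sum(d * q) / det
  if (v < -1e-12 || u + v > 1 + 1e-12) return(NA_real_)
  t <- sum(e2 * q) / det
  if (t > 1e-9) t else NA_real_
}

# crossing-parity point-in-mesh test, entirely in R
r_point_in_mesh <- function(p, vertices, faces,
                            dir = c(1, 2, 3) / sqrt(14)) {
  hits <- 0L
  for (i in seq_len(nrow(faces))) {
    t <- r_ray_triangle(p, dir, vertices[faces[i, 1], ],
                        vertices[faces[i, 2], ], vertices[faces[i, 3], ])
    if (!is.na(t)) hits <- hits + 1L
  }
  (hits %% 2L) == 1L
}

# unpolarized Fresnel average written directly from the closed form
r_fresnel <- function(theta_i, n_i, n_t) {
  vapply(theta_i, function(ti) {
    if (ti == 0) return(((n_i - n_t) / (n_i + n_t))^2)
    st <- n_i * sin(ti) / n_t
    if (st >= 1) return(1)
    tt <- asin(st)
    0.5 * (sin(ti - tt)^2 / sin(ti + tt)^2 + tan(ti - tt)^2 / tan(ti + tt)^2)
  }, numeric(1))
}

# small helpers shared across test files
unit <- function(v) v / sqrt(sum(v^2))

expect_unit_norm <- function(m, tol = 1e-9) {
  n <- sqrt(rowSums(as.matrix(m)^2))
  expect_true(all(abs(n - 1) < tol))
}
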