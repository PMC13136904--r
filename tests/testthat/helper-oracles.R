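# Independent geometric oracles and shared fixtures for the test suite.

# uniform points inside a posed cylinder (world frame)
oracle_points_in_cyl <- function(n, center, axis, radius, height) {
  th <- runif(n, 0, 2 * pi)
  r <- radius * sqrt(runif(n))
  z <- runif(n, -height / 2, height / 2)
  ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * axis) * axis
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  x <- r * cos(th); y <- r * sin(th)
  t(center + t(outer(x, e1) + outer(y, e2) + outer(z, axis)))
}

# membership test for points vs a posed cylinder
oracle_in_cyl <- function(pts, center, axis, radius, height) {
  d <- sweep(pts, 2, center)
  z <- d %*% axis
  rad2 <- rowSums(d^2) - z^2
  abs(z) <= height / 2 & rad2 <= radius^2
}

rand_unit_vec <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

# random rotation matrix (uniform, quaternion method)
rand_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = FALSE)
}

# one desk-scale synthetic SAXS dataset reused across files (cached)
shared_saxs <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- gen_saxs(p_st_true = 0.5, seed = 2024L)
    cache
  }
})

# single-cylinder Debye estimate vs the quadrature form factor (cached);
# problem size chosen so the Monte-Carlo error at the deepest form-factor
# minimum below Q = 3 nm^-1 is a few parts in a thousand
shared_cylinder_debye <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      geom <- cylinder_geometry()
      q <- default_q_grid(120)
      pts <- single_cylinder_points(1e5, geom, points_per_cylinder = 100,
                                    seed = 31)
      I <- debye_intensity(pts, q, bin_width = 0.002,
                           self_term = FALSE)$intensity
      cache <<- list(q = q, I = I,
                     P = cylinder_form_factor(q, geom)$intensity)
    }
    cache
  }
})
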