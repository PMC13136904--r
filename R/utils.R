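# shared numerical helpers (internal)

# sin(x)/x with the analytic limit at x = 0; preserves dim attributes
sinc <- function(x) {
  out <- x
  big <- abs(x) >= 1e-8
  out[big] <- sin(x[big]) / x[big]
  out[!big] <- 1 - x[!big]^2 / 6
  out
}

logspace <- function(from, to, n) exp(seq(log(from), log(to), length.out = n))

vnorm <- function(v) sqrt(sum(v^2))

unitize <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("zero-length vector cannot be normalized")
  v / n
}

# Deterministic orthonormal frame perpendicular to a unit axis.  The first
# basis vector is the projection of x-hat (or y-hat when the axis is nearly
# x-hat) onto the plane normal to the axis; azimuth 0 therefore points along
# x-hat for a z-aligned cylinder.
perp_frame <- function(axis) {
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unitize(ref - sum(ref * axis) * axis)
  e2 <- c(
    axis[2] * e1[3] - axis[3] * e1[2],
    axis[3] * e1[1] - axis[1] * e1[3],
    axis[1] * e1[2] - axis[2] * e1[1]
  )
  list(e1 = e1, e2 = e2)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

# n uniform random rotations (quaternion method); returns list of two
# n x 3 matrices: the images of x-hat and z-hat under each rotation.
random_rotation_images <- function(n) {
  q <- matrix(rnorm(4 * n), n, 4)
  q <- q / sqrt(rowSums(q^2))
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  ex <- cbind(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y))
  ez <- cbind(2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2))
  list(ex = ex, ez = ez)
}

is_number <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
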