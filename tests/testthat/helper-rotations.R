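# Independent rotation oracles for the tests. These deliberately avoid the
# package's rot_*/compose_zxy functions: matrices are built from closed-form
# trigonometric entries or quaternions, so decomposition tests have an
# external reference.

# closed-form Rz(a) %*% Rx(b) %*% Ry(c), angles in degrees (hand-expanded)
oracle_zxy <- function(a, b, c) {
  z <- a * pi / 180; x <- b * pi / 180; y <- c * pi / 180
  cz <- cos(z); sz <- sin(z); cx <- cos(x); sx <- sin(x)
  cy <- cos(y); sy <- sin(y)
  matrix(c(cz * cy - sz * sx * sy, sz * cy + cz * sx * sy, -cx * sy,
           -sz * cx, cz * cx, sx,
           cz * sy + sz * sx * cy, sz * sy - cz * sx * cy, cx * cy),
         3, 3)
}

# vectorized: 3 x 3 x n array of oracle_zxy over angle vectors
oracle_zxy_array <- function(a, b, c) {
  z <- a * pi / 180; x <- b * pi / 180; y <- c * pi / 180
  cz <- cos(z); sz <- sin(z); cx <- cos(x); sx <- sin(x)
  cy <- cos(y); sy <- sin(y)
  n <- length(z)
  R <- array(0, c(3, 3, n))
  R[1, 1, ] <- cz * cy - sz * sx * sy
  R[2, 1, ] <- sz * cy + cz * sx * sy
  R[3, 1, ] <- -cx * sy
  R[1, 2, ] <- -sz * cx
  R[2, 2, ] <- cz * cx
  R[3, 2, ] <- sx
  R[1, 3, ] <- cz * sy + sz * sx * cy
  R[2, 3, ] <- sz * sy - cz * sx * cy
  R[3, 3, ] <- cx * cy
  R
}

# uniform random rotation matrix from a normalized Gaussian quaternion
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

max_matdiff <- function(A, B) max(abs(A - B))
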