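#' Elementary rotation matrices
#'
#' Right-handed rotation matrices about the lab X, Y and Z axes, using the
#' column-vector convention (`R %*% v` rotates `v`).
#'
#' @param theta_deg Rotation angle in degrees.
#' @return A 3x3 rotation matrix.
#' @name elementary-rotations
NULL

#' @rdname elementary-rotations
#' @export
rot_x <- function(theta_deg) {
  a <- theta_deg * pi / 180
  matrix(c(1, 0, 0,
           0, cos(a), sin(a),
           0, -sin(a), cos(a)), 3, 3)
}

#' @rdname elementary-rotations
#' @export
rot_y <- function(theta_deg) {
  a <- theta_deg * pi / 180
  matrix(c(cos(a), 0, -sin(a),
           0, 1, 0,
           sin(a), 0, cos(a)), 3, 3)
}

#' @rdname elementary-rotations
#' @export
rot_z <- function(theta_deg) {
  a <- theta_deg * pi / 180
  matrix(c(cos(a), sin(a), 0,
           -sin(a), cos(a), 0,
           0, 0, 1), 3, 3)
}

#' Rotation about an arbitrary axis
#'
#' @param theta_deg Angle in degrees.
#' @param axis Length-3 axis vector (normalized internally).
#' @return A 3x3 rotation matrix (Rodrigues formula).
#' @export
rot_axis <- function(theta_deg, axis) {
  stopifnot(length(axis) == 3, all(is.finite(axis)))
  n <- sqrt(sum(axis^2))
  if (n < .Machine$double.eps) stop("rotation axis must be non-zero")
  u <- axis / n
  a <- theta_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

# rows of the cross product of two n x 3 matrices
cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# normalize rows of an n x 3 matrix; returns list(unit, norm)
unit_rows <- function(m) {
  n <- sqrt(rowSums(m^2))
  list(unit = m / n, norm = n)
}

as_rotation_array <- function(R) {
  if (is.matrix(R)) {
    stopifnot(all(dim(R) == c(3, 3)))
    R <- array(R, c(3, 3, 1))
  }
  stopifnot(is.array(R), length(dim(R)) == 3, all(dim(R)[1:2] == c(3, 3)))
  R
}

# max |R'R - I| and |det - 1| over an array of matrices
rotation_defect <- function(R) {
  R <- as_rotation_array(R)
  worst <- 0
  for (i in seq_len(dim(R)[3])) {
    Ri <- R[, , i]
    worst <- max(worst,
                 max(abs(crossprod(Ri) - diag(3))),
                 abs(det(Ri) - 1))
  }
  worst
}

#' Z-X-Y Cardan angle decomposition
#'
#' Decomposes rotation matrices into the intrinsic z-x'-y'' Cardan sequence
#' used for joint angles: `R = Rz(dfpf) %*% Rx(evinv) %*% Ry(abdadd)`. The
#' first angle (about Z) is dorsi-/plantarflexion, the second (about X)
#' eversion/inversion, the third (about Y) abduction/adduction.
#'
#' When the middle angle is within `gimbal_tol` degrees of +/-90 the first
#' and third angles are not separable (gimbal lock); the third angle is then
#' fixed to 0, the coupled rotation is absorbed into the first angle, and the
#' frame is flagged.
#'
#' @param R A 3x3 rotation matrix or a 3x3xn array of them.
#' @param convention `"zxy"` (intrinsic z-x'-y'', default) or
#'   `"zxy_extrinsic"` (fixed-axis Z then X then Y, i.e.
#'   `R = Ry %*% Rx %*% Rz`).
#' @param gimbal_tol Degrees from +/-90 of the middle angle below which a
#'   frame is flagged as gimbal-locked.
#' @param ortho_tol Maximum allowed orthonormality defect of the input.
#' @return An n x 3 matrix with columns `dfpf`, `evinv`, `abdadd` (degrees),
#'   with a logical attribute `"gimbal"` of length n. For a single matrix a
#'   named length-3 vector is returned (same attribute).
#' @examples
#' euler_zxy(rot_z(30) %*% rot_x(20) %*% rot_y(10))
#' @export
euler_zxy <- function(R, convention = c("zxy", "zxy_extrinsic"),
                      gimbal_tol = 1e-6, ortho_tol = 1e-6) {
  convention <- match.arg(convention)
  single <- is.matrix(R)
  R <- as_rotation_array(R)
  if (rotation_defect(R) > ortho_tol) {
    stop("input is not orthonormal within tolerance ", ortho_tol)
  }
  if (convention == "zxy_extrinsic") {
    # extrinsic Z-X-Y of R equals the negated intrinsic z-x'-y'' of t(R)
    Rt <- R
    for (i in seq_len(dim(R)[3])) Rt[, , i] <- t(R[, , i])
    out <- euler_zxy(if (single) Rt[, , 1] else Rt,
                     convention = "zxy",
                     gimbal_tol = gimbal_tol, ortho_tol = ortho_tol)
    g <- attr(out, "gimbal")
    out <- -out
    attr(out, "gimbal") <- g
    return(out)
  }
  r32 <- pmin(1, pmax(-1, R[3, 2, ]))
  x <- asin(r32)
  gimbal <- (90 - abs(x) * 180 / pi) < gimbal_tol
  z <- atan2(-R[1, 2, ], R[2, 2, ])
  y <- atan2(-R[3, 1, ], R[3, 3, ])
  if (any(gimbal)) {
    # at |evinv| = 90 only (dfpf -/+ abdadd) is defined: absorb it into dfpf
    s <- sign(r32[gimbal])
    z[gimbal] <- atan2(s * R[2, 1, gimbal], R[1, 1, gimbal]) * s
    y[gimbal] <- 0
  }
  out <- cbind(dfpf = z, evinv = x, abdadd = y) * 180 / pi
  if (single) {
    out <- c(dfpf = out[1, 1], evinv = out[1, 2], abdadd = out[1, 3])
  }
  attr(out, "gimbal") <- gimbal
  out
}

#' Compose a rotation from Z-X-Y Cardan angles
#'
#' Inverse of [euler_zxy()]: `rot_z(dfpf) %*% rot_x(evinv) %*% rot_y(abdadd)`.
#'
#' @param dfpf,evinv,abdadd Angles in degrees.
#' @return A 3x3 rotation matrix.
#' @export
compose_zxy <- function(dfpf, evinv, abdadd) {
  rot_z(dfpf) %*% rot_x(evinv) %*% rot_y(abdadd)
}
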