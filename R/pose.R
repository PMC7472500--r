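#' Per-frame rigid segment pose
#'
#' Container for one segment's orientation (3x3 rotation, columns = segment
#' X, Y, Z expressed in the lab frame) and origin (mm) per frame.
#'
#' @param segment Segment name.
#' @param R 3x3xn array of orientation matrices.
#' @param origin n x 3 matrix of origins (mm).
#' @param rate Sampling rate (Hz).
#' @param ortho_tol Maximum allowed orthonormality defect.
#' @return An object of class `pose_series`.
#' @export
pose_series <- function(segment, R, origin, rate, ortho_tol = 1e-9) {
  R <- as_rotation_array(R)
  origin <- as.matrix(origin)
  stopifnot(ncol(origin) == 3, nrow(origin) == dim(R)[3])
  defect <- rotation_defect(R)
  if (defect > ortho_tol) {
    stop("pose matrices not orthonormal: defect ", format(defect))
  }
  structure(list(segment = segment, R = R, origin = origin, rate = rate),
            class = "pose_series")
}

#' @export
print.pose_series <- function(x, ...) {
  cat("<pose_series> ", x$segment, ", ", dim(x$R)[3], " frames @ ",
      x$rate, " Hz\n", sep = "")
  invisible(x)
}

#' Build a segment-fixed orthonormal frame from markers
#'
#' Constructs the per-frame segment pose from a [segment_definition()]:
#' the long-axis unit vector is kept exact as the primary axis; the plane
#' triple's unit normal (oriented by the definition's `normal_sign`) is
#' re-orthogonalized against it (`u x (n x u)`, i.e. the normal's component
#' orthogonal to the primary axis); the third axis completes a right-handed
#' triad. Axes are then mapped to anatomical X (anterior), Y (superior),
#' Z (right-lateral) according to the plane label. The origin is the
#' long-axis `from` marker.
#'
#' @param traj A [trajectory_set()] containing the segment's markers (after
#'   [derive_virtual_markers()] if the definition uses virtual landmarks).
#' @param segdef A [segment_definition()].
#' @param collinear_tol Degeneracy threshold: frames where the plane
#'   triangle's area is below `collinear_tol` x (longest side)^2 are
#'   rejected.
#' @return A [pose_series()].
#' @export
build_segment_pose <- function(traj, segdef, collinear_tol = 1e-6) {
  stopifnot(inherits(traj, "trajectory_set"),
            inherits(segdef, "segment_definition"))
  seg <- segdef$name
  from <- get_marker(traj, segdef$axis_from, seg)
  to <- get_marker(traj, segdef$axis_to, seg)
  p1 <- get_marker(traj, segdef$plane[1], seg)
  p2 <- get_marker(traj, segdef$plane[2], seg)
  p3 <- get_marker(traj, segdef$plane[3], seg)

  ax <- unit_rows(to - from)
  if (any(ax$norm < .Machine$double.eps)) {
    stop("degenerate long axis (coincident markers) in segment ", seg,
         " at frame ", which(ax$norm < .Machine$double.eps)[1])
  }
  u <- ax$unit

  v1 <- p2 - p1
  v2 <- p3 - p1
  cr <- cross3(v1, v2)
  area <- 0.5 * sqrt(rowSums(cr^2))
  longest <- pmax(sqrt(rowSums(v1^2)), sqrt(rowSums(v2^2)),
                  sqrt(rowSums((p3 - p2)^2)))
  degen <- area < collinear_tol * longest^2
  if (any(degen)) {
    stop("collinear plane markers (degenerate frame) in segment ", seg,
         " at frame ", which(degen)[1])
  }
  n0 <- segdef$normal_sign * unit_rows(cr)$unit
  # keep the primary axis exact; project the normal orthogonal to it
  n <- n0 - rowSums(n0 * u) * u
  nn <- unit_rows(n)
  if (any(nn$norm < 1e-9)) {
    stop("plane normal parallel to long axis in segment ", seg,
         " at frame ", which(nn$norm < 1e-9)[1])
  }
  n <- nn$unit

  w <- cross3(u, n)  # completes u, n to a right-handed triad
  nf <- nrow(u)
  R <- array(0, c(3, 3, nf))
  # anatomical mapping: primary axis and plane normal to X/Y/Z columns
  if (segdef$primary == "anterior" && segdef$plane_label == "transverse") {
    X <- u; Y <- n; Z <- w                     # w = X x Y
  } else if (segdef$primary == "anterior" && segdef$plane_label == "sagittal") {
    X <- u; Z <- n; Y <- cross3(n, u)          # Y = Z x X
  } else if (segdef$primary == "superior" && segdef$plane_label == "frontal") {
    Y <- u; X <- n; Z <- cross3(n, u)          # Z = X x Y
  } else {
    stop("unsupported primary/plane combination for segment ", seg, ": ",
         segdef$primary, "/", segdef$plane_label)
  }
  R[, 1, ] <- t(X)
  R[, 2, ] <- t(Y)
  R[, 3, ] <- t(Z)
  pose_series(seg, R, from, traj$rate)
}

#' Inter-segment rotation
#'
#' Expresses the distal (child) segment's orientation in the proximal
#' (parent) segment's frame: `R_rel = t(R_parent) %*% R_child` per frame.
#'
#' @param child,parent [pose_series()] objects (or 3x3xn arrays) with equal
#'   frame counts.
#' @return A 3x3xn array of relative rotation matrices.
#' @export
relative_rotation <- function(child, parent) {
  Rc <- if (inherits(child, "pose_series")) child$R else as_rotation_array(child)
  Rp <- if (inherits(parent, "pose_series")) parent$R else as_rotation_array(parent)
  if (dim(Rc)[3] != dim(Rp)[3]) {
    stop("frame count mismatch: child has ", dim(Rc)[3],
         ", parent has ", dim(Rp)[3])
  }
  out <- array(0, dim(Rc))
  for (i in seq_len(dim(Rc)[3])) {
    out[, , i] <- crossprod(Rp[, , i], Rc[, , i])
  }
  out
}
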