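#' Load the dummy-foot rig geometry
#'
#' Reads the rig description (three rigid box segments carrying the model
#' landmarks, three marker-bearing reference plates, rotation pivots) from a
#' YAML fixture. The shipped default uses nominal, synthetic landmark
#' placements on the box faces; edit a copy to explore other placements.
#'
#' @param path YAML file; default the fixture shipped with the package.
#' @return An object of class `dummy_geometry` with elements `boxes`,
#'   `markers` (data.frame `name`, `box`, `x`, `y`, `z`, `label` --
#'   duplicated landmarks get box-qualified labels), `plates`, `pivots`.
#' @export
dummy_geometry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "dummy_geometry.yaml", package = "footkin",
                        mustWork = TRUE)
  }
  g <- yaml::read_yaml(path)
  mk <- do.call(rbind, lapply(g$markers, function(m) {
    data.frame(name = m$name, box = m$box, x = m$pos[[1]], y = m$pos[[2]],
               z = m$pos[[3]], stringsAsFactors = FALSE)
  }))
  dup <- names(which(table(mk$name) > 1))
  mk$label <- ifelse(mk$name %in% dup, paste0(mk$name, ":", mk$box), mk$name)
  if (anyDuplicated(mk$label)) stop("duplicated marker label within one box")
  # landmarks must sit on or inside their box volume (small tolerance for
  # marker radius)
  for (i in seq_len(nrow(mk))) {
    b <- g$boxes[[mk$box[i]]]
    if (is.null(b)) stop("marker ", mk$label[i], " references unknown box")
    tol <- 10
    if (mk$x[i] < b$x_min - tol || mk$x[i] > b$x_max + tol ||
        mk$y[i] < b$y_min - tol || mk$y[i] > b$y_max + tol ||
        mk$z[i] < b$z_min - tol || mk$z[i] > b$z_max + tol) {
      stop("marker ", mk$label[i], " lies outside box ", mk$box[i])
    }
  }
  plates <- lapply(g$plates, function(p) {
    list(box = p$box, o = as.numeric(unlist(p$o)),
         x = as.numeric(unlist(p$x)), z = as.numeric(unlist(p$z)))
  })
  pivots <- lapply(g$pivots, function(p) as.numeric(unlist(p)))
  structure(list(boxes = g$boxes, markers = mk, plates = plates,
                 pivots = pivots, units = g$units),
            class = "dummy_geometry")
}

#' @export
print.dummy_geometry <- function(x, ...) {
  cat("<dummy_geometry> ", nrow(x$markers), " physical markers on ",
      length(x$boxes), " boxes, plates ",
      paste(names(x$plates), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# model segment -> rig box carrying its tracking markers
rig_segment_boxes <- function() {
  c(Hallux = "toe", Forefoot = "forefoot", Rearfoot = "rearfoot",
    Rearfoot_2 = "rearfoot", Metatarsus = "forefoot", Calcaneus = "rearfoot")
}

#' Reference-plate pose from its three markers
#'
#' Builds the plate coordinate system: X from point `o` to point `x`; the
#' plate normal `Y = unit((z - o) x X)` (chosen to point up at the neutral
#' position); `Z = X x Y`, so the measured `o -> z` direction is only trusted
#' for the plane it spans, keeping X exact.
#'
#' @param o,x,z Plate marker positions: length-3 vectors or n x 3 matrices.
#' @return A [pose_series()] named after the plate (origin `o`). For vector
#'   input, a single-frame series.
#' @param rate Sampling rate recorded on the result (Hz).
#' @param plate Plate label.
#' @export
plate_pose <- function(o, x, z, rate = 100, plate = "plate") {
  tomat <- function(p) if (is.matrix(p)) p else matrix(p, 1, 3, byrow = TRUE)
  o <- tomat(o); x <- tomat(x); z <- tomat(z)
  stopifnot(nrow(o) == nrow(x), nrow(o) == nrow(z))
  ux <- unit_rows(x - o)
  if (any(ux$norm < .Machine$double.eps)) {
    stop("degenerate plate: o and x coincide at frame ",
         which(ux$norm < .Machine$double.eps)[1])
  }
  X <- ux$unit
  yv <- cross3(z - o, X)
  uy <- unit_rows(yv)
  if (any(uy$norm < 1e-9 * ux$norm)) {
    stop("collinear plate markers at frame ", which(uy$norm < 1e-9)[1])
  }
  Y <- uy$unit
  Z <- cross3(X, Y)
  R <- array(0, c(3, 3, nrow(o)))
  R[, 1, ] <- t(X); R[, 2, ] <- t(Y); R[, 3, ] <- t(Z)
  pose_series(plate, R, o, rate)
}

sweep_axis <- function(plane = c("frontal", "transverse", "sagittal")) {
  plane <- match.arg(plane)
  switch(plane,
         frontal = c(1, 0, 0),
         transverse = c(0, 1, 0),
         sagittal = c(0, 0, 1))
}

#' Simulate a dummy-foot plate sweep
#'
#' Reproduces the plate-sweep validation protocol: one end of the dummy foot
#' (the toe on plate A, or the rearfoot on plate C) is rotated together with
#' its plate through a grid of known angles about one anatomical plane's
#' axis, while the other segments stay fixed. One simulated frame is emitted
#' per grid position (quasi-static). The imposed plate-relative rotation is
#' the ground truth: plate A relative to plate B corresponds to `Met_Hal`,
#' plate B relative to plate C to `Cal_Met`. Noise (if any) perturbs markers
#' only; the truth is exact by construction.
#'
#' `placement_offset_deg` mounts the moving *segment* (not its plate)
#' rotated about the sweep axis, emulating a rigid misalignment between
#' segment markers and plate: downstream this shows up as a constant offset
#' between measured and true angles (a fixed bias).
#'
#' @param geom A [dummy_geometry()].
#' @param moving_end `"toe"` (sweeps `Met_Hal`) or `"rearfoot"` (`Cal_Met`).
#' @param plane Rotation plane: `"frontal"` (about X), `"transverse"`
#'   (about Y) or `"sagittal"` (about Z).
#' @param grid Angle grid in degrees, within \[-90, 90\].
#' @param noise_sd Marker Gaussian noise SD (mm) added to every marker.
#' @param placement_offset_deg Rigid mounting offset of the moving segment
#'   about the sweep axis (degrees).
#' @param seed Optional RNG seed for the noise.
#' @param rate Nominal sampling rate recorded on the trajectories (Hz).
#' @return List with `traj` (a [trajectory_set()] including plate markers
#'   `o:A`, ..., `z:C`), `truth` (data.frame `plane`, `grid_deg`, `joint`,
#'   `dfpf`, `evinv`, `abdadd` -- the Z-X-Y decomposition of the imposed
#'   plate-relative rotation) and `protocol` (the echoed parameters).
#' @export
simulate_sweep <- function(geom, moving_end = c("toe", "rearfoot"),
                           plane = c("frontal", "transverse", "sagittal"),
                           grid = seq(-90, 90, by = 5),
                           noise_sd = 0, placement_offset_deg = 0,
                           seed = NULL, rate = 100) {
  stopifnot(inherits(geom, "dummy_geometry"))
  moving_end <- match.arg(moving_end)
  plane <- match.arg(plane)
  if (any(grid < -90 | grid > 90)) {
    stop("angle grid must lie within [-90, 90] degrees")
  }
  axis <- sweep_axis(plane)
  pivot <- geom$pivots[[moving_end]]
  moving_plate <- if (moving_end == "toe") "A" else "C"
  # truth convention: the imposed angle theta is the angle of the distal
  # plate relative to the proximal one (A rel B, or B rel C), so the
  # rearfoot plate itself turns by -theta
  plate_sign <- if (moving_end == "toe") 1 else -1

  mk <- geom$markers
  pts <- as.matrix(mk[, c("x", "y", "z")])
  moving_mk <- mk$box == geom$plates[[moving_plate]]$box
  if (placement_offset_deg != 0) {
    Ro <- rot_axis(placement_offset_deg * plate_sign, axis)
    pts[moving_mk, ] <- sweep(
      (sweep(pts[moving_mk, , drop = FALSE], 2, pivot) %*% t(Ro)),
      2, pivot, "+")
  }
  plate_pts <- do.call(rbind, lapply(names(geom$plates), function(p) {
    pl <- geom$plates[[p]]
    cbind(data.frame(label = paste0(c("o", "x", "z"), ":", p),
                     moving = (p == moving_plate), stringsAsFactors = FALSE),
          rbind(pl$o, pl$x, pl$z))
  }))
  names(plate_pts)[3:5] <- c("x", "y", "z")

  nfr <- length(grid)
  labels <- c(mk$label, plate_pts$label)
  series <- lapply(labels, function(l) matrix(NA_real_, nfr, 3))
  names(series) <- labels
  truth <- matrix(0, nfr, 3)
  for (i in seq_len(nfr)) {
    R <- rot_axis(grid[i] * plate_sign, axis)
    move <- function(p) pivot + as.vector(R %*% (p - pivot))
    for (j in seq_len(nrow(mk))) {
      p <- pts[j, ]
      series[[mk$label[j]]][i, ] <- if (moving_mk[j]) move(p) else p
    }
    for (j in seq_len(nrow(plate_pts))) {
      p <- unlist(plate_pts[j, c("x", "y", "z")], use.names = FALSE)
      series[[plate_pts$label[j]]][i, ] <-
        if (plate_pts$moving[j]) move(p) else p
    }
    truth[i, ] <- euler_zxy(rot_axis(grid[i], axis))
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    series <- lapply(series, function(m) {
      m + matrix(stats::rnorm(length(m), sd = noise_sd), nrow(m), 3)
    })
  }
  traj <- trajectory_set(series, rate, segment_boxes = rig_segment_boxes())
  truth_df <- data.frame(
    plane = plane, grid_deg = grid,
    joint = if (moving_end == "toe") "Met_Hal" else "Cal_Met",
    dfpf = truth[, 1], evinv = truth[, 2], abdadd = truth[, 3],
    stringsAsFactors = FALSE)
  list(traj = traj, truth = truth_df,
       protocol = list(moving_end = moving_end, plane = plane, grid = grid,
                       noise_sd = noise_sd,
                       placement_offset_deg = placement_offset_deg,
                       seed = seed, rate = rate))
}

#' Plate-derived relative angles from a sweep trajectory
#'
#' Reconstructs the true-value angles the way the physical protocol defines
#' them: build each plate's frame from its `o`, `x`, `z` markers and
#' decompose the distal-relative-to-proximal plate rotation. On noiseless
#' trajectories this reproduces the imposed grid exactly.
#'
#' @param traj A sweep [trajectory_set()] containing the plate markers.
#' @param pair `"A_rel_B"` (truth for `Met_Hal`) or `"B_rel_C"`
#'   (truth for `Cal_Met`).
#' @return n x 3 matrix of Z-X-Y angles (degrees) with `gimbal` attribute.
#' @export
plate_angles <- function(traj, pair = c("A_rel_B", "B_rel_C")) {
  pair <- match.arg(pair)
  plates <- if (pair == "A_rel_B") c("A", "B") else c("B", "C")
  pose <- lapply(plates, function(p) {
    plate_pose(get_marker(traj, paste0("o:", p)),
               get_marker(traj, paste0("x:", p)),
               get_marker(traj, paste0("z:", p)),
               rate = traj$rate, plate = p)
  })
  euler_zxy(relative_rotation(pose[[1]], pose[[2]]))
}

#' Simulate a static rig recording
#'
#' Stationary markers at the neutral position, optionally with seeded
#' Gaussian noise -- the rig analogue of a static standing trial.
#'
#' @param geom A [dummy_geometry()].
#' @param duration_s Duration (s).
#' @param rate_hz Sampling rate (Hz).
#' @param noise_sd Marker noise SD (mm).
#' @param seed Optional RNG seed.
#' @return A [trajectory_set()] (including plate markers).
#' @export
simulate_static <- function(geom, duration_s = 15, rate_hz = 100,
                            noise_sd = 0, seed = NULL) {
  stopifnot(inherits(geom, "dummy_geometry"),
            duration_s > 0, rate_hz > 0)
  nfr <- max(1L, as.integer(round(duration_s * rate_hz)))
  mk <- geom$markers
  series <- lapply(seq_len(nrow(mk)), function(j) {
    matrix(unlist(mk[j, c("x", "y", "z")], use.names = FALSE), nfr, 3,
           byrow = TRUE)
  })
  names(series) <- mk$label
  for (p in names(geom$plates)) {
    pl <- geom$plates[[p]]
    for (nm in c("o", "x", "z")) {
      series[[paste0(nm, ":", p)]] <- matrix(pl[[nm]], nfr, 3, byrow = TRUE)
    }
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    series <- lapply(series, function(m) {
      m + matrix(stats::rnorm(length(m), sd = noise_sd), nfr, 3)
    })
  }
  trajectory_set(series, rate_hz, segment_boxes = rig_segment_boxes())
}
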