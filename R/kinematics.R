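#' Joint angle series
#'
#' Per-frame Z-X-Y Cardan angles of one joint, in degrees:
#' dorsi-/plantarflexion (`dfpf`, about Z), eversion/inversion (`evinv`,
#' about X) and abduction/adduction (`abdadd`, about Y).
#'
#' @param joint Joint name (e.g. `"Met_Hal"`).
#' @param angles n x 3 numeric matrix, columns `dfpf`, `evinv`, `abdadd`
#'   (degrees).
#' @param rate Sampling rate (Hz).
#' @param gimbal Logical vector flagging frames where the decomposition is
#'   gimbal-locked.
#' @param baseline_subtracted Has a static baseline been removed? (Raw
#'   decompositions satisfy `dfpf, abdadd` in (-180, 180] and `evinv` in
#'   [-90, 90]; baseline-subtracted values may exceed those ranges.)
#' @return An object of class `joint_angle_series`.
#' @export
joint_angle_series <- function(joint, angles, rate,
                               gimbal = rep(FALSE, nrow(angles)),
                               baseline_subtracted = FALSE) {
  angles <- as.matrix(angles)
  stopifnot(ncol(angles) == 3, length(gimbal) == nrow(angles))
  colnames(angles) <- c("dfpf", "evinv", "abdadd")
  if (!all(is.finite(angles))) stop("non-finite joint angles")
  if (!baseline_subtracted) {
    tol <- 1e-9
    if (any(angles[, c(1, 3)] <= -180 - tol | angles[, c(1, 3)] > 180 + tol) ||
        any(abs(angles[, 2]) > 90 + tol)) {
      stop("raw angles out of range: dfpf/abdadd must lie in (-180, 180], ",
           "evinv in [-90, 90]")
    }
  }
  structure(list(joint = joint, angles = angles, rate = rate,
                 gimbal = as.logical(gimbal),
                 baseline_subtracted = baseline_subtracted),
            class = "joint_angle_series")
}

#' @export
print.joint_angle_series <- function(x, ...) {
  cat("<joint_angle_series> ", x$joint, ", ", nrow(x$angles), " frames @ ",
      x$rate, " Hz", if (x$baseline_subtracted) ", baseline-subtracted",
      if (any(x$gimbal)) paste0(", ", sum(x$gimbal), " gimbal frame(s)"),
      "\n", sep = "")
  invisible(x)
}

#' Compute all joint angles of a foot model
#'
#' Runs the rigid-body pipeline for a trajectory set: derive virtual
#' markers, build each required segment frame, form distal-relative-to-
#' proximal rotations, and decompose them with the intrinsic Z-X-Y Cardan
#' sequence. Only the segments referenced by the requested joints are
#' built, so e.g. a missing `P1` marker only fails joints involving the
#' hallux.
#'
#' @param traj A [trajectory_set()].
#' @param model A foot model from [register_model()].
#' @param joints Joint names to compute (default: all of the model's).
#' @param convention Euler convention, see [euler_zxy()].
#' @param collinear_tol Passed to [build_segment_pose()].
#' @return Named list of [joint_angle_series()], one per joint.
#' @export
joint_angles <- function(traj, model, joints = NULL,
                         convention = c("zxy", "zxy_extrinsic"),
                         collinear_tol = 1e-6) {
  stopifnot(inherits(traj, "trajectory_set"), inherits(model, "foot_model"))
  convention <- match.arg(convention)
  jt <- model$joints
  if (!is.null(joints)) {
    unknown <- setdiff(joints, jt$joint)
    if (length(unknown)) {
      stop("unknown joint(s) for model ", model$model_id, ": ",
           paste(unknown, collapse = ", "))
    }
    jt <- jt[jt$joint %in% joints, , drop = FALSE]
  }
  traj <- derive_virtual_markers(traj, model, strict = FALSE)
  needed <- unique(c(jt$child, jt$parent))
  poses <- lapply(model$segments[needed], function(s) {
    build_segment_pose(traj, s, collinear_tol = collinear_tol)
  })
  out <- list()
  for (i in seq_len(nrow(jt))) {
    rel <- relative_rotation(poses[[jt$child[i]]], poses[[jt$parent[i]]])
    ang <- euler_zxy(rel, convention = convention)
    out[[jt$joint[i]]] <- joint_angle_series(jt$joint[i], ang, traj$rate,
                                             gimbal = attr(ang, "gimbal"))
  }
  out
}

#' Static baseline of joint angles
#'
#' Mean angle triple per joint over a static window, to be removed from
#' dynamic trials with [subtract_baseline()]. The default window is the
#' whole static trial.
#'
#' @param angles Named list of [joint_angle_series()] from a static trial.
#' @param window Optional integer frame range `c(first, last)`.
#' @return An object of class `static_baseline`: named list of length-3
#'   mean angle vectors (degrees).
#' @export
static_baseline <- function(angles, window = NULL) {
  stopifnot(is.list(angles), length(angles) >= 1)
  out <- lapply(angles, function(a) {
    stopifnot(inherits(a, "joint_angle_series"))
    idx <- seq_len(nrow(a$angles))
    if (!is.null(window)) {
      stopifnot(length(window) == 2, window[1] >= 1,
                window[2] <= nrow(a$angles), window[1] <= window[2])
      idx <- window[1]:window[2]
    }
    m <- colMeans(a$angles[idx, , drop = FALSE])
    if (!all(is.finite(m))) stop("non-finite baseline for joint ", a$joint)
    m
  })
  names(out) <- vapply(angles, `[[`, character(1), "joint")
  structure(out, class = "static_baseline")
}

wrap180 <- function(x) {
  w <- ((x + 180) %% 360) - 180
  w[w == -180] <- 180
  w
}

#' Subtract a static baseline from joint angles
#'
#' Component-wise subtraction of the static standing mean from a joint's
#' angle series; the first and third components are re-wrapped to
#' (-180, 180].
#'
#' @param angles A [joint_angle_series()].
#' @param baseline A [static_baseline()] containing the joint.
#' @return The baseline-subtracted [joint_angle_series()].
#' @export
subtract_baseline <- function(angles, baseline) {
  stopifnot(inherits(angles, "joint_angle_series"),
            inherits(baseline, "static_baseline"))
  if (!(angles$joint %in% names(baseline))) {
    stop("baseline does not contain joint ", angles$joint)
  }
  b <- baseline[[angles$joint]]
  a <- sweep(angles$angles, 2, b, "-")
  a[, 1] <- wrap180(a[, 1])
  a[, 3] <- wrap180(a[, 3])
  joint_angle_series(angles$joint, a, angles$rate, gimbal = angles$gimbal,
                     baseline_subtracted = TRUE)
}

#' Zero-lag Butterworth low-pass filtering of marker trajectories
#'
#' Filters every coordinate of every marker with a low-pass Butterworth
#' filter applied forward and backward (zero phase lag). Ends are extended
#' by odd reflection over `3 * order` samples before the two passes to
#' suppress edge transients. `order` is the order of the single-pass filter
#' (the two-pass magnitude response is effectively squared), the
#' conventional reading in movement analysis.
#'
#' @param traj A [trajectory_set()].
#' @param cutoff_hz Cutoff frequency (Hz); default 6.
#' @param order Single-pass filter order; default 4.
#' @return The filtered [trajectory_set()].
#' @export
filter_trajectories <- function(traj, cutoff_hz = 6, order = 4) {
  stopifnot(inherits(traj, "trajectory_set"))
  if (cutoff_hz <= 0 || cutoff_hz >= traj$rate / 2) {
    stop("cutoff (", cutoff_hz, " Hz) must lie strictly between 0 and the ",
         "Nyquist frequency (", traj$rate / 2, " Hz)")
  }
  nf <- n_frames(traj)
  pad <- 3L * as.integer(order)
  if (nf <= 3L * order) {
    stop("series too short to filter: ", nf, " frames <= 3 x order (",
         3L * order, ")")
  }
  bf <- signal::butter(order, cutoff_hz / (traj$rate / 2), type = "low")
  nb <- length(bf$b) - 1
  na <- length(bf$a) - 1
  run <- function(x) {
    # steady-state initial conditions at the first sample, so a constant
    # signal passes exactly (unit DC gain, no startup transient)
    as.numeric(signal::filter(bf$b, bf$a, x,
                              init.x = rep(x[1], nb),
                              init.y = rep(x[1], na)))
  }
  filt1 <- function(x) {
    # odd (point-mirrored) reflection about each endpoint
    head_pad <- 2 * x[1] - x[seq(pad + 1, 2)]
    tail_pad <- 2 * x[nf] - x[seq(nf - 1, nf - pad)]
    xp <- c(head_pad, x, tail_pad)
    y <- run(xp)
    y <- rev(run(rev(y)))
    y[(pad + 1):(pad + nf)]
  }
  out <- lapply(traj$markers, function(m) apply(m, 2, filt1))
  trajectory_set(out, traj$rate, segment_boxes = traj$segment_boxes)
}

#' Peak joint angles within a task window
#'
#' Maximum and minimum of each rotation component within a frame window,
#' the summary used for slow (calf raise) and fast (drop jump) tasks.
#'
#' @param angles A [joint_angle_series()] or named list of them.
#' @param window Integer frame range `c(first, last)`; default the whole
#'   series.
#' @param task Task label.
#' @return A data.frame of class `peak_summary`: `joint`, `task`,
#'   `component`, `max`, `min` (degrees).
#' @export
extract_peaks <- function(angles, window = NULL,
                          task = c("calf_raise", "gait", "drop_jump",
                                   "dummy_sweep", "static")) {
  task <- match.arg(task)
  if (inherits(angles, "joint_angle_series")) angles <- list(angles)
  rows <- lapply(angles, function(a) {
    stopifnot(inherits(a, "joint_angle_series"))
    nf <- nrow(a$angles)
    idx <- seq_len(nf)
    if (!is.null(window)) {
      if (length(window) != 2 || window[1] > window[2]) {
        stop("empty task window")
      }
      if (window[1] < 1 || window[2] > nf) {
        stop("task window [", window[1], ", ", window[2],
             "] outside series (", nf, " frames)")
      }
      idx <- window[1]:window[2]
    }
    sub <- a$angles[idx, , drop = FALSE]
    data.frame(joint = a$joint, task = task,
               component = colnames(sub),
               max = apply(sub, 2, max), min = apply(sub, 2, min),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  stopifnot(all(out$max >= out$min))
  class(out) <- c("peak_summary", class(out))
  out
}

#' Tidy export of joint angle series
#'
#' @param angles A [joint_angle_series()] or named list of them.
#' @param trial Trial label recorded in the output.
#' @return A long data.frame with columns `trial`, `joint`, `component`,
#'   `frame`, `time_s`, `angle_deg`, `gimbal_flag`.
#' @export
angles_to_df <- function(angles, trial = NA_character_) {
  if (inherits(angles, "joint_angle_series")) angles <- list(angles)
  rows <- lapply(angles, function(a) {
    nf <- nrow(a$angles)
    data.frame(
      trial = trial, joint = a$joint,
      component = rep(colnames(a$angles), each = nf),
      frame = rep(seq_len(nf), 3),
      time_s = rep((seq_len(nf) - 1) / a$rate, 3),
      angle_deg = as.vector(a$angles),
      gimbal_flag = rep(a$gimbal, 3),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}
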