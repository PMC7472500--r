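#' Labeled 3D marker trajectories
#'
#' A `trajectory_set` holds labeled 3D marker positions (mm, lab frame)
#' sampled at a fixed rate. All markers share the same frame count and must
#' be complete: gaps are not interpolated here, upstream I/O has to deliver
#' full series.
#'
#' Duplicate physical markers (a dummy rig carries shared landmarks once per
#' adjoining segment) are stored under qualified names `"<landmark>:<box>"`;
#' `segment_boxes` maps model segment names to the rig box whose copies they
#' track, and [get_marker()] resolves the qualified copy first, falling back
#' to the plain label.
#'
#' @param markers Named list of n x 3 numeric matrices (columns X, Y, Z).
#' @param rate Sampling rate in Hz (> 0).
#' @param segment_boxes Optional named character vector, model segment name
#'   -> rig box label.
#' @return An object of class `trajectory_set`.
#' @export
trajectory_set <- function(markers, rate, segment_boxes = NULL) {
  if (!is.list(markers) || length(markers) == 0) {
    stop("`markers` must be a non-empty named list of n x 3 matrices")
  }
  nm <- names(markers)
  if (is.null(nm) || anyNA(nm) || any(nm == "") || anyDuplicated(nm)) {
    stop("marker names must be unique and non-empty")
  }
  markers <- lapply(markers, function(m) {
    m <- as.matrix(m)
    if (ncol(m) != 3) stop("each marker series must have 3 columns (X, Y, Z)")
    storage.mode(m) <- "double"
    colnames(m) <- c("X", "Y", "Z")
    m
  })
  nf <- vapply(markers, nrow, integer(1))
  if (length(unique(nf)) != 1) {
    stop("all marker series must have the same number of frames")
  }
  bad <- nm[!vapply(markers, function(m) all(is.finite(m)), logical(1))]
  if (length(bad)) {
    stop("non-finite positions in marker(s): ", paste(bad, collapse = ", "))
  }
  if (!is.numeric(rate) || length(rate) != 1 || !is.finite(rate) || rate <= 0) {
    stop("`rate` must be a single positive number (Hz)")
  }
  structure(list(markers = markers, rate = rate,
                 segment_boxes = segment_boxes),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat("<trajectory_set> ", length(x$markers), " markers, ",
      n_frames(x), " frames @ ", x$rate, " Hz\n", sep = "")
  cat("  markers: ", paste(utils::head(names(x$markers), 12), collapse = ", "),
      if (length(x$markers) > 12) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Number of frames in a trajectory set
#' @param traj A [trajectory_set()].
#' @return Integer frame count.
#' @export
n_frames <- function(traj) {
  stopifnot(inherits(traj, "trajectory_set"))
  nrow(traj$markers[[1]])
}

#' Marker labels of a trajectory set
#' @param traj A [trajectory_set()].
#' @return Character vector of labels.
#' @export
marker_names <- function(traj) {
  stopifnot(inherits(traj, "trajectory_set"))
  names(traj$markers)
}

#' Look up a marker series, resolving duplicated copies
#'
#' If `segment` is given and the trajectory set carries a qualified copy of
#' the landmark for that segment's rig box (`"<name>:<box>"`), the copy is
#' returned; otherwise the plain label is used.
#'
#' @param traj A [trajectory_set()].
#' @param name Landmark code (e.g. `"H1"`).
#' @param segment Optional model segment name requesting the marker.
#' @return An n x 3 matrix of positions (mm).
#' @export
get_marker <- function(traj, name, segment = NULL) {
  stopifnot(inherits(traj, "trajectory_set"))
  if (!is.null(segment) && !is.null(traj$segment_boxes)) {
    box <- unname(traj$segment_boxes[segment])
    if (length(box) == 1 && !is.na(box)) {
      q <- paste0(name, ":", box)
      if (q %in% names(traj$markers)) return(traj$markers[[q]])
    }
  }
  if (name %in% names(traj$markers)) return(traj$markers[[name]])
  stop("marker ", name, " not found",
       if (!is.null(segment)) paste0(" (required by segment ", segment, ")"))
}

# does the set contain the landmark in any form usable by `segment`?
has_marker <- function(traj, name, segment = NULL) {
  if (name %in% names(traj$markers)) return(TRUE)
  if (!is.null(segment) && !is.null(traj$segment_boxes)) {
    box <- unname(traj$segment_boxes[segment])
    if (length(box) == 1 && !is.na(box) &&
        paste0(name, ":", box) %in% names(traj$markers)) {
      return(TRUE)
    }
  }
  FALSE
}

#' Append computed (virtual) markers
#'
#' Adds the model's virtual landmarks to a trajectory set. Both are frame-wise
#' midpoints, never measured: `MC` between `NV` and `B5`, and `IM` between
#' `MM` and `LM`. Where a parent landmark exists as duplicated per-box copies
#' (`"NV:forefoot"`, `"NV:rearfoot"`, ...), a qualified midpoint is produced
#' for every box carrying both parents.
#'
#' @param traj A [trajectory_set()].
#' @param model A foot model from [register_model()] (supplies the virtual
#'   marker definitions).
#' @param strict Error when a parent landmark is absent (default). With
#'   `strict = FALSE` underivable virtual markers are skipped, so a missing
#'   parent only surfaces if a requested segment actually needs the
#'   midpoint.
#' @return A new `trajectory_set` with the virtual markers appended.
#' @export
derive_virtual_markers <- function(traj, model, strict = TRUE) {
  stopifnot(inherits(traj, "trajectory_set"), inherits(model, "foot_model"))
  nm <- names(traj$markers)
  out <- traj$markers
  for (v in names(model$virtual)) {
    parents <- model$virtual[[v]]
    made <- FALSE
    if (all(parents %in% nm) && !(v %in% nm)) {
      out[[v]] <- (traj$markers[[parents[1]]] + traj$markers[[parents[2]]]) / 2
      made <- TRUE
    } else if (v %in% nm) {
      made <- TRUE
    }
    # qualified copies: one midpoint per box carrying both parents
    suff <- function(p) {
      hits <- grep(paste0("^", p, ":"), nm, value = TRUE)
      sub("^[^:]+:", "", hits)
    }
    boxes <- intersect(suff(parents[1]), suff(parents[2]))
    for (b in boxes) {
      tgt <- paste0(v, ":", b)
      if (!(tgt %in% nm)) {
        out[[tgt]] <- (traj$markers[[paste0(parents[1], ":", b)]] +
                         traj$markers[[paste0(parents[2], ":", b)]]) / 2
      }
      made <- TRUE
    }
    if (!made && strict) {
      missing <- parents[!vapply(parents, function(p) {
        p %in% nm || length(suff(p)) > 0
      }, logical(1))]
      stop(missing[1], " required for ", v)
    }
  }
  trajectory_set(out, traj$rate, segment_boxes = traj$segment_boxes)
}

# apply a rigid motion p -> R p + t to every marker (used by the rig and tests)
transform_trajectory <- function(traj, R = diag(3), t = c(0, 0, 0)) {
  stopifnot(inherits(traj, "trajectory_set"))
  out <- lapply(traj$markers, function(m) {
    sweep(m %*% t(R), 2, t, "+")
  })
  trajectory_set(out, traj$rate, segment_boxes = traj$segment_boxes)
}
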