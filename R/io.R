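#' Write trajectories as a TRC file
#'
#' OpenSim-dialect TRC: tab-separated text with the standard five header
#' lines, coordinates in mm.
#'
#' @param traj A [trajectory_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trc <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory_set"))
  nm <- marker_names(traj)
  nf <- n_frames(traj)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("PathFileType", "4", "(X/Y/Z)", basename(path),
                   sep = "\t"), con)
  writeLines(paste("DataRate", "CameraRate", "NumFrames", "NumMarkers",
                   "Units", "OrigDataRate", "OrigDataStartFrame",
                   "OrigNumFrames", sep = "\t"), con)
  writeLines(paste(traj$rate, traj$rate, nf, length(nm), "mm", traj$rate,
                   1, nf, sep = "\t"), con)
  writeLines(paste(c("Frame#", "Time",
                     as.vector(rbind(nm, "", ""))), collapse = "\t"), con)
  writeLines(paste(c("", "", paste0(rep(c("X", "Y", "Z"), length(nm)),
                                    rep(seq_along(nm), each = 3))),
                   collapse = "\t"), con)
  writeLines("", con)
  coords <- do.call(cbind, traj$markers)
  time <- (seq_len(nf) - 1) / traj$rate
  lines <- vapply(seq_len(nf), function(i) {
    paste(c(i, format(time[i], trim = TRUE),
            format(coords[i, ], trim = TRUE, digits = 15)), collapse = "\t")
  }, character(1))
  writeLines(lines, con)
  invisible(path)
}

#' Read a TRC trajectory file
#'
#' @param path TRC file (OpenSim dialect). Units `m` are converted to mm.
#' @return A [trajectory_set()].
#' @export
read_trc <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 6 || !startsWith(lines[1], "PathFileType")) {
    stop("not a TRC file (missing PathFileType header): ", path)
  }
  hdr_names <- strsplit(lines[2], "\t")[[1]]
  hdr_vals <- strsplit(lines[3], "\t")[[1]]
  hdr <- stats::setNames(as.list(hdr_vals), hdr_names)
  rate <- as.numeric(hdr$DataRate)
  if (!is.finite(rate) || rate <= 0) stop("invalid DataRate in TRC header")
  units <- if (!is.null(hdr$Units)) hdr$Units else "mm"
  scale <- switch(units, mm = 1, m = 1000,
                  stop("unsupported TRC units: ", units))
  labels_raw <- strsplit(lines[4], "\t")[[1]]
  nm <- labels_raw[-(1:2)]
  nm <- nm[nm != ""]
  data_start <- 7
  while (data_start <= length(lines) && !nzchar(trimws(lines[data_start]))) {
    data_start <- data_start + 1
  }
  body <- lines[data_start:length(lines)]
  body <- body[nzchar(trimws(body))]
  rows <- lapply(seq_along(body), function(i) {
    v <- suppressWarnings(as.numeric(strsplit(body[i], "\t")[[1]]))
    if (length(v) != 2 + 3 * length(nm) || anyNA(v)) {
      stop("corrupt TRC data at frame line ", i, " of ", path)
    }
    v
  })
  mat <- do.call(rbind, rows)
  markers <- lapply(seq_along(nm), function(j) {
    mat[, 2 + (3 * (j - 1) + 1):(3 * j), drop = FALSE] * scale
  })
  names(markers) <- nm
  trajectory_set(markers, rate)
}

#' Write trajectories as wide CSV
#'
#' Dialect: header `frame,time_s,<marker>_x,<marker>_y,<marker>_z,...`,
#' coordinates in mm, comma separator.
#'
#' @param traj A [trajectory_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_traj_csv <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory_set"))
  nf <- n_frames(traj)
  df <- data.frame(frame = seq_len(nf), time_s = (seq_len(nf) - 1) / traj$rate)
  for (nm in marker_names(traj)) {
    m <- traj$markers[[nm]]
    df[[paste0(nm, "_x")]] <- m[, 1]
    df[[paste0(nm, "_y")]] <- m[, 2]
    df[[paste0(nm, "_z")]] <- m[, 3]
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a wide-CSV trajectory file
#'
#' @param path CSV with columns `frame`, `time_s`, `<marker>_x/_y/_z` (mm).
#'   Frames must be complete and contiguous.
#' @return A [trajectory_set()].
#' @export
read_traj_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("frame", "time_s") %in% names(df))) {
    stop("CSV must have `frame` and `time_s` columns: ", path)
  }
  nf <- nrow(df)
  expected <- seq_len(nf)
  if (!isTRUE(all.equal(as.numeric(df$frame), as.numeric(expected)))) {
    gap <- setdiff(expected, df$frame)
    stop("missing or out-of-order frame row(s): ",
         paste(utils::head(if (length(gap)) gap else df$frame[
           df$frame != expected], 5), collapse = ", "))
  }
  coord_cols <- setdiff(names(df), c("frame", "time_s"))
  base <- unique(sub("_[xyz]$", "", coord_cols))
  markers <- lapply(base, function(nm) {
    cols <- paste0(nm, "_", c("x", "y", "z"))
    if (!all(cols %in% names(df))) {
      stop("incomplete coordinate triplet for marker ", nm)
    }
    m <- as.matrix(df[, cols])
    if (anyNA(m)) {
      stop("missing coordinate(s) for marker ", nm, " at frame ",
           which(rowSums(is.na(m)) > 0)[1])
    }
    m
  })
  names(markers) <- base
  rate <- if (nf > 1) 1 / stats::median(diff(df$time_s)) else 100
  trajectory_set(markers, round(rate, 6))
}

# rename mocap labels to canonical codes, preserving ":box" qualifiers
apply_label_aliases <- function(labels) {
  al <- marker_aliases()
  parts <- strsplit(labels, ":", fixed = TRUE)
  vapply(parts, function(p) {
    base <- if (p[1] %in% names(al)) al[[p[1]]] else p[1]
    paste(c(base, p[-1]), collapse = ":")
  }, character(1))
}

#' Read marker trajectories from a motion-capture file
#'
#' Reads TRC or wide-CSV trajectories, normalizes units to mm, and maps
#' marker labels onto the canonical landmark codes via the Rizzoli-style
#' alias table (so Vicon exports labeled either way load unchanged). C3D is
#' recognized but not parsed by this build; export TRC or CSV instead.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"trc"`, `"csv"` or `"c3d"`.
#' @param rename Apply the label alias table (default `TRUE`).
#' @param strict Error if any label (after renaming) is neither a canonical
#'   landmark code nor a plate marker.
#' @return A [trajectory_set()].
#' @export
read_trajectories <- function(path, format = c("auto", "trc", "csv", "c3d"),
                              rename = TRUE, strict = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     trc = "trc", csv = "csv", c3d = "c3d",
                     stop("cannot infer format from extension: ", path))
  }
  if (format == "c3d") {
    stop("C3D input is not supported by this build; export the trial as ",
         "TRC or CSV")
  }
  if (!file.exists(path)) stop("file not found: ", path)
  traj <- switch(format, trc = read_trc(path), csv = read_traj_csv(path))
  if (rename) {
    names(traj$markers) <- apply_label_aliases(names(traj$markers))
  }
  if (any(grepl(":", names(traj$markers), fixed = TRUE))) {
    # box-qualified duplicates come from the dummy rig: restore its
    # segment -> box lookup so frame construction resolves the right copy
    traj$segment_boxes <- rig_segment_boxes()
  }
  if (strict) {
    known <- c(foot_landmarks()$name, "o", "x", "z")
    base <- sub(":.*$", "", names(traj$markers))
    unmapped <- sort(unique(names(traj$markers)[!(base %in% known)]))
    if (length(unmapped)) {
      stop("unmapped marker label(s): ", paste(unmapped, collapse = ", "))
    }
  }
  traj
}

#' Write sweep ground truth as CSV
#'
#' @param truth The `truth` data.frame from [simulate_sweep()] (or several
#'   row-bound together).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth_csv <- function(truth, path) {
  stopifnot(is.data.frame(truth),
            all(c("plane", "grid_deg", "dfpf", "evinv", "abdadd") %in%
                  names(truth)))
  utils::write.csv(truth, path, row.names = FALSE)
  invisible(path)
}
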