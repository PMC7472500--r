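#' Pipeline run configuration
#'
#' Validates all analysis parameters up front, before any file is read.
#'
#' @param model Model id (see [register_model()]).
#' @param joints Joint names to compute (default all of the model's; use a
#'   subset for trials that do not carry every segment's markers, e.g.
#'   dummy-rig recordings without a shank).
#' @param convention Euler convention (see [euler_zxy()]).
#' @param cutoff_hz,filter_order Butterworth parameters (defaults 6 Hz,
#'   4th order single-pass).
#' @param filter_stage Filter marker trajectories (`"markers"`, default) or
#'   the computed angle series (`"angles"`), or `"none"`.
#' @param rate_hz Expected sampling rate (Hz), used to validate the cutoff
#'   against Nyquist; re-checked against each file's actual rate.
#' @param baseline_window Optional frame range `c(first, last)` of the
#'   static trial used for the baseline.
#' @param noise_sd,seed Simulation noise parameters (dummy trials only).
#' @param out_dir Output directory for artifacts.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(model = "new", joints = NULL,
                       convention = c("zxy", "zxy_extrinsic"),
                       cutoff_hz = 6, filter_order = 4,
                       filter_stage = c("markers", "angles", "none"),
                       rate_hz = 100, baseline_window = NULL,
                       noise_sd = 0, seed = 1, out_dir = tempdir()) {
  convention <- match.arg(convention)
  filter_stage <- match.arg(filter_stage)
  spec <- register_model(model)  # errors on unknown id
  if (!is.null(joints)) {
    unknown <- setdiff(joints, spec$joints$joint)
    if (length(unknown)) {
      stop("unknown joint(s) for model ", model, ": ",
           paste(unknown, collapse = ", "))
    }
  }
  if (!is.numeric(rate_hz) || rate_hz <= 0) stop("rate_hz must be positive")
  if (!is.numeric(cutoff_hz) || cutoff_hz <= 0 || cutoff_hz >= rate_hz / 2) {
    stop("invalid cutoff: ", cutoff_hz, " Hz must lie strictly below the ",
         "Nyquist frequency (", rate_hz / 2, " Hz)")
  }
  if (!is.numeric(filter_order) || filter_order < 1) {
    stop("filter_order must be >= 1")
  }
  if (!is.null(baseline_window)) {
    stopifnot(length(baseline_window) == 2,
              baseline_window[1] >= 1,
              baseline_window[1] <= baseline_window[2])
  }
  structure(list(model = model, joints = joints, convention = convention,
                 cutoff_hz = cutoff_hz, filter_order = filter_order,
                 filter_stage = filter_stage, rate_hz = rate_hz,
                 baseline_window = baseline_window, noise_sd = noise_sd,
                 seed = seed, out_dir = out_dir),
            class = "run_config")
}

#' Bundle one trial for the pipeline
#'
#' @param source A trajectory file path or an in-memory [trajectory_set()].
#' @param type Trial type.
#' @param window Optional event window `c(first, last)` (frames).
#' @param id Trial identifier used in output file names.
#' @return A list of class `trial_bundle`.
#' @export
trial_bundle <- function(source,
                         type = c("static", "calf_raise", "gait",
                                  "drop_jump", "dummy_sweep"),
                         window = NULL, id = NULL) {
  type <- match.arg(type)
  if (!is.null(window)) {
    stopifnot(length(window) == 2, window[1] >= 1, window[1] <= window[2])
  }
  if (is.null(id)) {
    id <- if (is.character(source)) {
      tools::file_path_sans_ext(basename(source))
    } else type
  }
  structure(list(source = source, type = type, window = window, id = id),
            class = "trial_bundle")
}

load_trial <- function(trial, config) {
  traj <- if (inherits(trial$source, "trajectory_set")) trial$source else
    read_trajectories(trial$source)
  if (!is.null(trial$window) && trial$window[2] > n_frames(traj)) {
    stop("[", trial$id, "] event window exceeds trial length (",
         n_frames(traj), " frames)")
  }
  if (config$filter_stage == "markers" && trial$type != "dummy_sweep" &&
      n_frames(traj) > 3 * config$filter_order) {
    traj <- filter_trajectories(traj, config$cutoff_hz, config$filter_order)
  }
  traj
}

#' Run the full analysis pipeline
#'
#' Orchestrates filter -> segment frames -> joint angles -> static baseline
#' subtraction -> task peaks (and the agreement battery for dummy-sweep
#' trials), writing CSV artifacts and a YAML log of every parameter.
#' Deterministic given (config, seed, inputs).
#'
#' @param config A [run_config()].
#' @param trials List of [trial_bundle()]s. If a `static` trial is present
#'   its mean angles are subtracted from all dynamic trials.
#' @return Invisibly, a list with the per-trial angle tables, peak
#'   summaries, and the paths of all written artifacts.
#' @export
run_pipeline <- function(config, trials) {
  stopifnot(inherits(config, "run_config"))
  if (inherits(trials, "trial_bundle")) trials <- list(trials)
  stopifnot(length(trials) >= 1,
            all(vapply(trials, inherits, logical(1), "trial_bundle")))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  model <- register_model(config$model)
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop("[", what, "] ", conditionMessage(e), call. = FALSE)
    })
  }

  baseline <- NULL
  statics <- which(vapply(trials, function(t) t$type == "static", logical(1)))
  if (length(statics)) {
    tr <- trials[[statics[1]]]
    traj <- stage(paste0("read:", tr$id), load_trial(tr, config))
    ang <- stage(paste0("angles:", tr$id),
                 joint_angles(traj, model, joints = config$joints, convention = config$convention))
    baseline <- static_baseline(ang, window = config$baseline_window)
  }

  artifacts <- list()
  results <- list(angles = list(), peaks = list())
  for (tr in trials) {
    traj <- stage(paste0("read:", tr$id), load_trial(tr, config))
    ang <- stage(paste0("angles:", tr$id),
                 joint_angles(traj, model, joints = config$joints, convention = config$convention))
    if (!is.null(baseline) && tr$type != "static") {
      ang <- stage(paste0("baseline:", tr$id),
                   lapply(ang, subtract_baseline, baseline = baseline))
    }
    df <- angles_to_df(ang, trial = tr$id)
    angle_path <- file.path(config$out_dir,
                            paste0("angles_", tr$id, ".csv"))
    utils::write.csv(df, angle_path, row.names = FALSE)
    artifacts <- c(artifacts, angle_path)
    results$angles[[tr$id]] <- df
    if (tr$type %in% c("calf_raise", "drop_jump", "gait")) {
      pk <- stage(paste0("peaks:", tr$id),
                  extract_peaks(ang, window = tr$window, task = tr$type))
      peak_path <- file.path(config$out_dir, paste0("peaks_", tr$id, ".csv"))
      utils::write.csv(pk, peak_path, row.names = FALSE)
      artifacts <- c(artifacts, peak_path)
      results$peaks[[tr$id]] <- pk
    }
  }

  log_path <- file.path(config$out_dir, "run_log.yaml")
  yaml::write_yaml(list(
    model = config$model, euler_convention = config$convention,
    filter = list(cutoff_hz = config$cutoff_hz,
                  order = config$filter_order,
                  stage = config$filter_stage),
    baseline_window = config$baseline_window,
    noise_sd = config$noise_sd, seed = config$seed,
    trials = lapply(trials, function(t) {
      list(id = t$id, type = t$type,
           source = if (is.character(t$source)) t$source else "<in-memory>")
    })), log_path)
  artifacts <- c(artifacts, log_path)
  invisible(c(results, list(artifacts = unlist(artifacts),
                            baseline = baseline)))
}
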