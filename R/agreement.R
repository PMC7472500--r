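#' Standard-related validity (Pearson correlation)
#'
#' Pearson correlation between a measured angle series and its ground
#' truth, with the two-sided p-value from the t distribution on n - 2
#' degrees of freedom.
#'
#' @param measured,truth Equal-length numeric vectors (degrees), n >= 3.
#' @param label Optional angle/plane label carried on the result.
#' @return An object of class `correlation_result`: `r`, `p`, `n`, `label`.
#' @export
pearson_validity <- function(measured, truth, label = NULL) {
  stopifnot(is.numeric(measured), is.numeric(truth))
  if (length(measured) != length(truth)) stop("length mismatch")
  if (length(measured) < 3) stop("need at least 3 paired observations")
  if (!all(is.finite(measured)) || !all(is.finite(truth))) {
    stop("non-finite values")
  }
  if (stats::sd(measured) == 0 || stats::sd(truth) == 0) {
    stop("undefined correlation: zero variance in input")
  }
  ct <- stats::cor.test(measured, truth, method = "pearson",
                        alternative = "two.sided")
  structure(list(r = unname(ct$estimate), p = ct$p.value,
                 n = length(measured), label = label),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat("<correlation_result>", if (!is.null(x$label)) x$label,
      sprintf(" r = %.3f, p = %.3g, n = %d\n", x$r, x$p, x$n))
  invisible(x)
}

#' Bland-Altman agreement analysis
#'
#' Differences `d = measured - truth`; bias = mean(d); limits of agreement
#' (LoA) = bias +/- 1.96 SD(d) (classical multiplier, not a t quantile).
#' A *fixed* bias is declared when the 95% confidence interval of the mean
#' difference excludes zero; a *proportional* bias when the ordinary
#' least-squares slope of d on the pairwise means is significant at 5%.
#'
#' @param measured,truth Equal-length numeric vectors (degrees), n >= 3.
#' @param label Optional label.
#' @param tol Numerical resolution (degrees): a mean difference or
#'   difference SD below `tol` is treated as exactly zero when setting the
#'   bias flags, so floating-point residue never registers as bias.
#' @return An object of class `bland_altman`: `bias`, `sd_diff`,
#'   `loa_lower`, `loa_upper`, `fixed_bias`, `proportional_bias`, `slope`,
#'   `slope_p`, `inside_loa` (fraction of points inside the LoA), `n`,
#'   `means`, `diffs`.
#' @export
bland_altman <- function(measured, truth, label = NULL, tol = 1e-9) {
  stopifnot(is.numeric(measured), is.numeric(truth))
  if (length(measured) != length(truth)) stop("length mismatch")
  n <- length(measured)
  if (n < 3) stop("need at least 3 paired observations")
  if (!all(is.finite(measured)) || !all(is.finite(truth))) {
    stop("non-finite values")
  }
  d <- measured - truth
  m <- (measured + truth) / 2
  bias <- mean(d)
  sd_d <- stats::sd(d)
  loa <- bias + c(-1, 1) * 1.96 * sd_d
  se <- sd_d / sqrt(n)
  ci <- bias + c(-1, 1) * stats::qt(0.975, n - 1) * se
  fixed <- (ci[1] > 0 || ci[2] < 0) && abs(bias) > tol
  slope <- 0
  slope_p <- NA_real_
  proportional <- FALSE
  if (sd_d > tol && stats::sd(m) > 0) {
    fit <- stats::lm(d ~ m)
    sm <- summary(fit)$coefficients
    if (nrow(sm) == 2 && is.finite(sm[2, 4])) {
      slope <- unname(sm[2, 1])
      slope_p <- unname(sm[2, 4])
      proportional <- slope_p < 0.05
    }
  }
  structure(list(bias = bias, sd_diff = sd_d,
                 loa_lower = loa[1], loa_upper = loa[2],
                 fixed_bias = fixed, proportional_bias = proportional,
                 slope = slope, slope_p = slope_p,
                 inside_loa = mean(d >= loa[1] & d <= loa[2]),
                 n = n, label = label, means = m, diffs = d),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat("<bland_altman>", if (!is.null(x$label)) x$label, "\n")
  cat(sprintf("  bias %.3f deg, LoA [%.3f, %.3f], n = %d\n",
              x$bias, x$loa_lower, x$loa_upper, x$n))
  cat("  bias class:", classify_bias(x), "\n")
  invisible(x)
}

#' Classify the systematic-bias pattern
#'
#' Deterministic mapping of the Bland-Altman flags to a label.
#'
#' @param result A [bland_altman()] result.
#' @return `"none"`, `"fixed"`, `"proportional"` or `"fixed+proportional"`.
#' @export
classify_bias <- function(result) {
  stopifnot(inherits(result, "bland_altman"))
  f <- isTRUE(result$fixed_bias)
  p <- isTRUE(result$proportional_bias)
  if (f && p) "fixed+proportional" else if (f) "fixed" else if (p)
    "proportional" else "none"
}

#' Unpaired comparison of peak angles
#'
#' Two-sample t-test (pooled variance by default) between peak angle
#' groups, two-sided, significance at 5%. If the pooled variance is zero
#' and the means are equal, p = 1 by convention; a zero-variance difference
#' in means is flagged degenerate.
#'
#' @param group_a,group_b Numeric vectors, n >= 2 each.
#' @param var_equal Pooled-variance (Student) test if `TRUE` (default),
#'   Welch otherwise.
#' @return An object of class `t_test_result`: group means/SDs/sizes, `t`,
#'   `df`, `p`, `significant`, `degenerate`.
#' @export
compare_peaks <- function(group_a, group_b, var_equal = TRUE) {
  stopifnot(is.numeric(group_a), is.numeric(group_b))
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("need at least 2 observations per group")
  }
  na <- length(group_a); nb <- length(group_b)
  degenerate <- FALSE
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0) {
    if (mean(group_a) == mean(group_b)) {
      t <- 0; p <- 1; df <- na + nb - 2
    } else {
      t <- Inf * sign(mean(group_a) - mean(group_b)); p <- 0
      df <- na + nb - 2; degenerate <- TRUE
    }
  } else {
    tt <- stats::t.test(group_a, group_b, var.equal = var_equal)
    t <- unname(tt$statistic); df <- unname(tt$parameter); p <- tt$p.value
  }
  structure(list(mean_a = mean(group_a), mean_b = mean(group_b),
                 sd_a = stats::sd(group_a), sd_b = stats::sd(group_b),
                 n_a = na, n_b = nb, t = t, df = df, p = p,
                 significant = p < 0.05, degenerate = degenerate),
            class = "t_test_result")
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("<t_test_result> t = %.3f (df = %.1f), p = %.4g%s\n",
              x$t, x$df, x$p, if (x$significant) " *" else ""))
  invisible(x)
}

plane_component <- function(plane) {
  switch(plane, frontal = "evinv", transverse = "abdadd", sagittal = "dfpf",
         stop("unknown plane: ", plane))
}

#' Assemble a validity report from sweep cells
#'
#' Tabulates, per model x joint x plane cell, the standard-related validity
#' (Pearson r, p) and the Bland-Altman bias, limits of agreement and bias
#' class of measured against true angles.
#'
#' @param cells List of cells, each a list with `model`, `joint`, `plane`,
#'   `measured`, `truth` (equal-length numeric vectors, degrees).
#' @return A data.frame of class `agreement_report` with columns `model`,
#'   `joint`, `plane`, `n`, `r`, `p`, `bias`, `sd_diff`, `loa_lower`,
#'   `loa_upper`, `bias_class`.
#' @export
validity_report <- function(cells) {
  if (!is.list(cells) || length(cells) == 0) {
    stop("empty input: need at least one sweep cell")
  }
  rows <- lapply(cells, function(cl) {
    lab <- paste(cl$model, cl$joint, cl$plane)
    pr <- pearson_validity(cl$measured, cl$truth, label = lab)
    ba <- bland_altman(cl$measured, cl$truth, label = lab)
    data.frame(model = cl$model, joint = cl$joint, plane = cl$plane,
               n = pr$n, r = pr$r, p = pr$p, bias = ba$bias,
               sd_diff = ba$sd_diff, loa_lower = ba$loa_lower,
               loa_upper = ba$loa_upper, bias_class = classify_bias(ba),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  class(out) <- c("agreement_report", class(out))
  out
}

#' End-to-end dummy-foot validity study
#'
#' Runs the full validation protocol in simulation: for each requested
#' model, sweep the toe plate (validating `Met_Hal`) and the rearfoot plate
#' (validating `Cal_Met` / `Cal_Met_2`) through the angle grid in each
#' plane, compute the model's joint angles through the rigid-body pipeline,
#' and compare the plane's rotation component against the imposed plate
#' angles.
#'
#' @param models Model ids (see [register_model()]).
#' @param planes Planes to sweep.
#' @param geom A [dummy_geometry()] (default: the shipped fixture).
#' @param grid Angle grid (degrees).
#' @param noise_sd Marker noise SD (mm).
#' @param placement_offset_deg Mounting offset of the moving segments, see
#'   [simulate_sweep()].
#' @param seed RNG seed used (only) when `noise_sd > 0`.
#' @param cells_only Return the raw cells (measured/truth vectors) instead
#'   of the tabulated report.
#' @return An `agreement_report` data.frame (or the cell list).
#' @export
dummy_foot_validity <- function(models = c("new", "new_2", "rizzoli"),
                                planes = c("frontal", "transverse",
                                           "sagittal"),
                                geom = dummy_geometry(),
                                grid = seq(-90, 90, by = 5),
                                noise_sd = 0, placement_offset_deg = 0,
                                seed = NULL, cells_only = FALSE) {
  cells <- list()
  for (model_id in models) {
    model <- register_model(model_id)
    ends <- c(Met_Hal = "toe",
              stats::setNames("rearfoot",
                              grep("^Cal_Met", model$joints$joint,
                                   value = TRUE)))
    for (k in seq_along(ends)) {
      joint <- names(ends)[k]
      for (plane in planes) {
        sw <- simulate_sweep(geom, moving_end = ends[[k]], plane = plane,
                             grid = grid, noise_sd = noise_sd,
                             placement_offset_deg = placement_offset_deg,
                             seed = if (is.null(seed)) NULL else
                               seed + 7L * k + match(plane, planes))
        ang <- joint_angles(sw$traj, model, joints = joint)[[joint]]
        comp <- plane_component(plane)
        cells[[length(cells) + 1L]] <- list(
          model = model_id, joint = joint, plane = plane,
          measured = ang$angles[, comp], truth = sw$truth[[comp]])
      }
    }
  }
  if (cells_only) cells else validity_report(cells)
}
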