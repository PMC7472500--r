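#' Validity scatter plot
#'
#' Measured against true angles with the identity line, one panel per cell.
#'
#' @param cells Sweep cells as returned by
#'   `dummy_foot_validity(..., cells_only = TRUE)` (or a single cell list).
#' @return A ggplot object.
#' @export
plot_validity <- function(cells) {
  if (!is.null(cells$measured)) cells <- list(cells)
  df <- do.call(rbind, lapply(cells, function(cl) {
    data.frame(cell = paste(cl$model, cl$joint, cl$plane),
               truth = cl$truth, measured = cl$measured)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$truth, y = .data$measured)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~cell) +
    ggplot2::labs(x = "true angle (deg)", y = "measured angle (deg)") +
    ggplot2::theme_minimal()
}

#' Bland-Altman plot
#'
#' Differences against pairwise means, with the bias line and (when a bias
#' is present) the limits of agreement.
#'
#' @param ba A [bland_altman()] result.
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(ba) {
  stopifnot(inherits(ba, "bland_altman"))
  df <- data.frame(mean = ba$means, diff = ba$diffs)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = ba$bias, colour = "blue") +
    ggplot2::labs(x = "mean of measured and true (deg)",
                  y = "measured - true (deg)",
                  subtitle = paste("bias class:", classify_bias(ba))) +
    ggplot2::theme_minimal()
  if (classify_bias(ba) != "none") {
    p <- p +
      ggplot2::geom_hline(yintercept = c(ba$loa_lower, ba$loa_upper),
                          colour = "blue", linetype = 2)
  }
  p
}
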