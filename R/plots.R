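#' @import ggplot2
NULL

#' Plot spot-intensity traces
#'
#' @param trace Trace tibble (`cell`, `time_s`, `intensity`; a
#'   `true_signal` column is overlaid when present).
#' @param cells Optional subset of cell ids.
#' @param threshold Optional detection threshold drawn as a dashed line.
#' @export
plot_trace <- function(trace, cells = NULL, threshold = NULL) {
  if (!is.null(cells)) trace <- trace[trace$cell %in% cells, ]
  p <- ggplot(trace, aes(x = .data$time_s, y = .data$intensity)) +
    geom_line(colour = "grey30", linewidth = 0.3) +
    facet_wrap(~cell) +
    labs(x = "time (s)", y = "spot intensity (loop units)")
  if ("true_signal" %in% names(trace)) {
    p <- p + geom_line(aes(y = .data$true_signal), colour = "steelblue",
                       linewidth = 0.3)
  }
  if (!is.null(threshold)) {
    p <- p + geom_hline(yintercept = threshold, linetype = "dashed")
  }
  p
}

#' @exportS3Method ggplot2::autoplot
autoplot.trace_acf <- function(object, ...) {
  ggplot(object, aes(x = .data$lag_s, y = .data$G)) +
    geom_pointrange(aes(ymin = .data$G - .data$se,
                        ymax = .data$G + .data$se), size = 0.2) +
    labs(x = "lag (s)", y = expression(G(tau)))
}

#' @exportS3Method ggplot2::autoplot
autoplot.acf_decomposition <- function(object, ...) {
  ggplot(object$acf, aes(x = .data$lag_s, y = .data$G)) +
    geom_point(size = 0.8) +
    geom_line(aes(y = .data$slow_line), colour = "grey50",
              linetype = "dashed") +
    geom_vline(xintercept = object$dwell_s, colour = "firebrick",
               linetype = "dotted") +
    labs(x = "lag (s)", y = expression(G(tau)),
         subtitle = sprintf("dwell %.0f s, load %.1f polymerases",
                            object$dwell_s, object$polymerase_load))
}

#' @exportS3Method ggplot2::autoplot
autoplot.hmm_scan <- function(object, ...) {
  ggplot(object$table, aes(x = .data$K, y = .data$aic)) +
    geom_line() + geom_point() +
    geom_point(data = object$table[object$table$K == object$selected_K, ],
               colour = "firebrick", size = 2) +
    labs(x = "number of gene states K", y = "AIC")
}

#' @exportS3Method ggplot2::autoplot
autoplot.frap_groups <- function(object, ...) {
  ggplot(object$curves,
         aes(x = .data$time_s, y = .data$recovery, colour = .data$group)) +
    geom_ribbon(aes(ymin = .data$recovery - .data$se,
                    ymax = .data$recovery + .data$se,
                    fill = .data$group), alpha = 0.2, colour = NA) +
    geom_line() +
    labs(x = "time since bleach (s)", y = "normalized recovery",
         subtitle = sprintf("max group difference: %.1f pooled s.e.",
                            object$difference_statistic))
}

#' @exportS3Method ggplot2::autoplot
autoplot.rate_path <- function(object, ...) {
  ggplot(object$path, aes(x = .data$time_s, y = .data$rate)) +
    geom_step() +
    labs(x = "time (s)", y = "initiation rate (1/s)")
}

#' Plot a quantile calibration curve
#'
#' @param curve A [quantile_calibrate()] result.
#' @export
plot_calibration <- function(curve) {
  ggplot(curve$points, aes(x = .data$live, y = .data$loops,
                           colour = .data$percentile)) +
    geom_point() +
    labs(x = "live intensity (a.u.)", y = "smFISH loop count",
         colour = "percentile")
}
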