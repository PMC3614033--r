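#' Plot pool fractions of candidate mutations
#'
#' One point per candidate at its genomic position, coloured by
#' classification, with the causal threshold drawn as a dashed line.
#'
#' @param candidates Classified candidates (needs chrom, pos,
#'   pool_fraction, classification).
#' @param threshold Threshold line (default 0.9).
#' @return A ggplot object.
#' @export
plot_pool_fractions <- function(candidates, threshold = 0.9) {
  ggplot2::ggplot(
    candidates,
    ggplot2::aes(x = .data$pos, y = .data$pool_fraction,
                 colour = .data$classification)
  ) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom), scales = "free_x") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "genomic position (bp)",
                  y = "selected-pool allele fraction", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_pool_fractions
#' @param object A `clone_report`.
#' @param ... Passed on (unused).
#' @method autoplot clone_report
#' @export
autoplot.clone_report <- function(object, threshold = 0.9, ...) {
  plot_pool_fractions(object$candidates, threshold = threshold) +
    ggplot2::ggtitle(object$clone)
}

#' Plot an allele-frequency time course
#'
#' @param timecourse Output of [build_timecourse()].
#' @return A ggplot object.
#' @export
plot_timecourse <- function(timecourse) {
  ggplot2::ggplot(
    timecourse,
    ggplot2::aes(x = .data$time_point, y = .data$frequency,
                 colour = .data$allele)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "time point (generations)",
                  y = "mutant allele frequency", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a windowed depth-ratio track with optional CNV calls
#'
#' @param ratio_track Output of [depth_ratio()].
#' @param calls Optional calls from [segment_cnv()], shaded as rectangles.
#' @return A ggplot object.
#' @export
plot_depth_ratio <- function(ratio_track, calls = NULL) {
  p <- ggplot2::ggplot(
    ratio_track,
    ggplot2::aes(x = (.data$start + .data$end) / 2, y = .data$ratio)
  ) +
    ggplot2::geom_step(na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted") +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom), scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "normalized depth ratio") +
    ggplot2::theme_minimal()
  if (!is.null(calls) && nrow(calls) > 0) {
    p <- p + ggplot2::geom_rect(
      data = calls,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -Inf, ymax = Inf, fill = .data$call),
      alpha = 0.2, inherit.aes = FALSE
    )
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
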