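#' Plot delta-index tracks along the genome
#'
#' One panel per chromosome: per-marker delta-index points, the sliding-window
#' mean as a line, horizontal screening-threshold lines, and candidate
#' intervals as shaded spans.
#'
#' @param track An index track from [compute_index()].
#' @param windows Optional [window_track()] tibble.
#' @param intervals Optional [call_intervals()] tibble.
#' @param threshold Threshold drawn at +/- this value (default 0.5).
#' @param point_alpha Marker point transparency.
#' @return A ggplot object.
#' @export
plot_delta_track <- function(track, windows = NULL, intervals = NULL,
                             threshold = 0.5, point_alpha = 0.25) {
  p <- ggplot2::ggplot(
    track,
    ggplot2::aes(x = .data$pos / 1e6, y = .data$delta_index)
  )
  if (!is.null(intervals) && nrow(intervals) > 0) {
    p <- p + ggplot2::geom_rect(
      data = intervals,
      ggplot2::aes(
        xmin = .data$start / 1e6, xmax = .data$end / 1e6,
        ymin = -1, ymax = 1
      ),
      inherit.aes = FALSE, fill = "goldenrod", alpha = 0.3
    )
  }
  p <- p + ggplot2::geom_point(
    alpha = point_alpha, size = 0.4, colour = "grey30"
  )
  if (!is.null(windows)) {
    w <- windows[!windows$empty, ]
    if (nrow(w) > 0) {
      p <- p + ggplot2::geom_line(
        data = w,
        ggplot2::aes(
          x = (.data$start + .data$end) / 2 / 1e6,
          y = .data$mean_delta
        ),
        colour = "firebrick", linewidth = 0.5
      )
    }
  }
  p +
    ggplot2::geom_hline(
      yintercept = c(-threshold, threshold),
      linetype = "dashed", colour = "steelblue"
    ) +
    ggplot2::facet_wrap(~chrom, ncol = 3) +
    ggplot2::coord_cartesian(ylim = c(-1, 1)) +
    ggplot2::labs(
      x = "position (Mb)", y = expression(Delta * "-index"),
      title = "Delta-index along the genome"
    ) +
    ggplot2::theme_minimal(base_size = 9)
}

#' Plot a stage-pattern census as a bar chart
#'
#' @param census Output of [pattern_census()].
#' @return A ggplot object.
#' @export
plot_pattern_census <- function(census) {
  ggplot2::ggplot(census, ggplot2::aes(x = .data$pattern, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.4, size = 3) +
    ggplot2::labs(
      x = NULL, y = "genes",
      title = "Expression patterns across developmental stages"
    ) +
    ggplot2::theme_minimal(base_size = 10) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
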