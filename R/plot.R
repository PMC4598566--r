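# ggplot2 displays for the package's result objects.

#' Rose plot of normalized orientation angles
#'
#' Displays the pooled per-condition angle histograms of a polarity summary
#' as rose plots (polar sector charts). Because angles are normalized to a
#' 90° circular mean per cell or field, a tightly polarized condition shows
#' one narrow lobe at 90°, while polarity defects spread counts around the
#' circle.
#'
#' @param object A `polarity_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.polarity_summary <- function(object, ...) {
  h <- object$histograms
  ggplot2::ggplot(h, ggplot2::aes(
    x = (.data$bin_start_deg + .data$bin_end_deg) / 2,
    y = .data$count
  )) +
    ggplot2::geom_col(width = 360 / max(1, nrow(h) / max(1, length(unique(h$condition)))),
      fill = "steelblue", colour = "grey20", linewidth = 0.2) +
    ggplot2::coord_polar(start = -pi / 2, direction = -1) +
    ggplot2::scale_x_continuous(limits = c(0, 360),
      breaks = seq(0, 270, by = 90)) +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(
      x = NULL, y = "count",
      title = sprintf("%s polarity (angles normalized to 90°)", object$kind)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a cilia disassembly time course
#'
#' Mean percent-ciliated per condition over time with s.e.m. error bars,
#' the standard display for serum-induced cilia disassembly experiments.
#'
#' @param object A `cilia_timecourse`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cilia_timecourse <- function(object, ...) {
  p <- object$points
  ggplot2::ggplot(p, ggplot2::aes(.data$timepoint_h, .data$mean_percent_ciliated,
    colour = .data$condition, group = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$mean_percent_ciliated - .data$sem,
      ymax = .data$mean_percent_ciliated + .data$sem
    ), width = 0.15, na.rm = TRUE) +
    ggplot2::labs(x = "time after serum addition (h)", y = "ciliated cells (%)",
      colour = NULL) +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}

#' Plot per-condition flow statistics
#'
#' Velocity and tortuosity means with s.e.m. error bars per condition.
#'
#' @param object A `flow_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.flow_summary <- function(object, ...) {
  c_tbl <- object$conditions
  long <- dplyr::bind_rows(
    tibble::tibble(condition = c_tbl$condition, metric = "velocity (µm/s)",
      mean = c_tbl$mean_velocity_um_s, sem = c_tbl$sem_velocity),
    tibble::tibble(condition = c_tbl$condition, metric = "tortuosity",
      mean = c_tbl$mean_tortuosity, sem = c_tbl$sem_tortuosity)
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$condition, .data$mean)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem,
      ymax = .data$mean + .data$sem), width = 0.2, na.rm = TRUE) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
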