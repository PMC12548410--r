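#' Boxplot of D-ratios by group
#'
#' One panel per motif, groups on the x axis, the reference line at
#' D = 1 (no depletion or enrichment) drawn for orientation.
#'
#' @param tbl Output of [d_ratio_table()].
#' @param group Grouping column (default `"variant_class"`).
#' @return A ggplot object.
#' @export
plot_dratio <- function(tbl, group = "variant_class") {
  ggplot2::ggplot(
    filter(tbl, !.data$undefined),
    ggplot2::aes(x = .data[[group]], y = .data$d_ratio,
                 fill = .data[[group]])
  ) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_boxplot(outlier.size = 0.8, show.legend = FALSE) +
    ggplot2::facet_wrap(~motif, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "D-ratio (observed / expected)") +
    ggplot2::theme_minimal()
}

#' Sliding-window GC / CpG O/E profile plot
#'
#' @param x An `erv_window_profile` from [window_profile()].
#' @param ... Unused.
#' @return A ggplot object with GC% and CpG O/E panels and the island
#'   thresholds marked.
#' @export
autoplot.erv_window_profile <- function(x, ...) {
  long <- tibble(
    start = rep(x$start, 2),
    metric = rep(c("GC percent", "CpG O/E"), each = nrow(x)),
    value = c(x$gc_percent, x$cpg_oe)
  )
  thresholds <- tibble(metric = c("GC percent", "CpG O/E"),
                       cutoff = c(50, 0.6))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$start, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_hline(data = thresholds,
                        ggplot2::aes(yintercept = .data$cutoff),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::facet_wrap(~metric, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "window start (bp)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Methylation track plot
#'
#' Per-bin mean percent methylation across the provirus; bins without
#' data are left blank.
#'
#' @param x An `erv_meth_track` from [provirus_track()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.erv_meth_track <- function(x, ...) {
  ggplot2::ggplot(
    filter(x$track, !.data$no_data),
    ggplot2::aes(x = .data$bin_start, y = .data$mean_percent)
  ) +
    ggplot2::geom_col(width = x$bin_size * 0.9, fill = "steelblue") +
    ggplot2::geom_hline(yintercept = x$median_percent, linetype = "dashed") +
    ggplot2::ylim(0, 100) +
    ggplot2::labs(x = "position (bp)", y = "CpG methylation (%)",
                  title = x$seq_id) +
    ggplot2::theme_minimal()
}

#' Methylation vs CpG O/E scatter
#'
#' The per-virus summary view: median percent methylation against median
#' CpG D-ratio, with any excluded point highlighted.
#'
#' @param points Tibble with `label`, `median_meth`, `median_oe`.
#' @param exclude Optional label(s) drawn in red and excluded from the
#'   trend.
#' @return A ggplot object.
#' @export
plot_meth_vs_oe <- function(points, exclude = NULL) {
  points$excluded <- points$label %in% (exclude %||% character())
  ggplot2::ggplot(points,
                  ggplot2::aes(x = .data$median_meth, y = .data$median_oe)) +
    ggplot2::geom_smooth(data = filter(points, !.data$excluded),
                         method = "lm", formula = y ~ x, se = FALSE,
                         colour = "grey60", linewidth = 0.5) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$excluded), size = 2,
                        show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black",
                                            `TRUE` = "firebrick")) +
    ggplot2::geom_text(ggplot2::aes(label = .data$label),
                       vjust = -0.8, size = 3) +
    ggplot2::labs(x = "median CpG methylation (%)",
                  y = "median CpG D-ratio") +
    ggplot2::theme_minimal()
}
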