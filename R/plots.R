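#' Plot a probe track with optional call overlay
#'
#' Scatter of probe log2 ratios along the chromosome (faceted by
#' chromosome), with called segments drawn at their nominal state mean.
#'
#' @param track Probe tibble for one sample (`chrom`, `pos`, `log2ratio`).
#' @param calls Optional call tibble to overlay.
#' @param state_means Means used for segment overlay heights.
#' @return A ggplot object.
#' @export
plot_probe_track <- function(track, calls = NULL,
                             state_means = or_state_means()) {
  p <- ggplot2::ggplot(track, ggplot2::aes(.data$pos / 1e6,
                                           .data$log2ratio)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.4, colour = "grey40") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "log2 ratio") +
    ggplot2::theme_minimal()
  if (!is.null(calls) && nrow(calls) > 0) {
    calls <- dplyr::mutate(
      calls, y = state_means[as.character(.data$copy_state)])
    p <- p + ggplot2::geom_segment(
      data = calls,
      ggplot2::aes(x = .data$start / 1e6, xend = .data$end / 1e6,
                   y = .data$y, yend = .data$y, colour = .data$type),
      linewidth = 1.2) +
      ggplot2::scale_colour_manual(values = c(dup = "#c0392b",
                                              del = "#2980b9"))
  }
  p
}

#' @export
autoplot.or_repertoire_stats <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(object, "population", dplyr::starts_with("pct_")),
    -"population", names_to = "statistic", values_to = "percent")
  ggplot2::ggplot(long, ggplot2::aes(.data$population, .data$percent,
                                     fill = .data$population)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(~statistic) +
    ggplot2::labs(x = NULL, y = "percent") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.or_recurrence <- function(object, ...) {
  counts <- dplyr::count(object, .data$chrom, .data$class)
  ggplot2::ggplot(counts, ggplot2::aes(.data$chrom, .data$n,
                                       fill = .data$class)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::scale_fill_manual(values = c(hotspot = "#c0392b",
                                          intermediate = "#f39c12",
                                          rare = "#2980b9")) +
    ggplot2::labs(x = NULL, y = "events") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @export
autoplot.or_sharing <- function(object, ...) {
  long <- tidyr::unnest(
    dplyr::select(object, "cnp_id", "populations"), "populations")
  ggplot2::ggplot(long, ggplot2::aes(.data$populations, .data$cnp_id)) +
    ggplot2::geom_tile(fill = "#2c3e50") +
    ggplot2::labs(x = "population", y = "CNP") +
    ggplot2::theme_minimal()
}
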