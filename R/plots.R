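# ggplot2 views of the main result types.

#' Density plot of the two methylation axes
#'
#' The classic cohort view: average backbone methylation on x, average CGI
#' methylation on y, with the classification cutoffs drawn as dashed lines
#' so the NC-NB / HC-NB / HC-LB regimes are visible.
#'
#' @param summary A [summarize_samples()] tibble.
#' @param cgi_cut,backbone_cut Cutoffs to draw (defaults 0.24 / 0.78).
#' @param color Optional column name used to colour points (e.g.
#'   `"tumor_type"`).
#' @return A ggplot object.
#' @export
plot_methylation_density <- function(summary, cgi_cut = 0.24,
                                     backbone_cut = 0.78, color = NULL) {
  p <- ggplot2::ggplot(
    summary,
    ggplot2::aes(x = .data$avg_backbone, y = .data$avg_cgi)
  ) +
    ggplot2::geom_density_2d(colour = "grey60", na.rm = TRUE)
  if (!is.null(color)) {
    p <- p + ggplot2::geom_point(
      ggplot2::aes(colour = .data[[color]]),
      size = 0.8, alpha = 0.7, na.rm = TRUE
    )
  } else {
    p <- p + ggplot2::geom_point(size = 0.8, alpha = 0.5, na.rm = TRUE)
  }
  p +
    ggplot2::geom_hline(yintercept = cgi_cut, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = backbone_cut, linetype = "dashed") +
    ggplot2::labs(
      x = "average backbone methylation",
      y = "average CGI methylation"
    ) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.meth_summary <- function(object, ...) {
  plot_methylation_density(object, ...)
}

#' Plot a sliding-window methylation track
#'
#' @param track A [window_means()] tibble.
#' @param chrom Optional chromosome to restrict to.
#' @return A ggplot object (one panel per chromosome).
#' @export
plot_window_track <- function(track, chrom = NULL) {
  if (!is.null(chrom)) track <- track[track$chrom %in% chrom, ]
  ggplot2::ggplot(
    track[!is.na(track$mean_value), ],
    ggplot2::aes(x = (.data$start + .data$end) / 2e6, y = .data$mean_value)
  ) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "window mean") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.meth_window_track <- function(object, ...) {
  plot_window_track(object, ...)
}

#' Plot cross-tumor percentile curves along the genome
#'
#' @param percentiles A [cross_tumor_percentiles()] tibble.
#' @return A ggplot object of -log10 percentile p-values by position.
#' @export
plot_scna_percentiles <- function(percentiles) {
  pct_cols <- grep("^p\\d+$", names(percentiles), value = TRUE)
  long <- tidyr::pivot_longer(percentiles,
    cols = dplyr::all_of(pct_cols),
    names_to = "percentile", values_to = "p"
  )
  ggplot2::ggplot(
    long,
    ggplot2::aes(
      x = .data$start / 1e6, y = -log10(.data$p),
      colour = .data$percentile
    )
  ) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "-log10 corrected p") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
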