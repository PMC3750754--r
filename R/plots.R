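# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a binned homozygosity profile
#'
#' Raw and smoothed degree per bin, faceted by chromosome, with the calling
#' threshold and (optionally) the called ROHs shaded.
#'
#' @param object A [bin_profile()] result (smoothed or not).
#' @param rohs Optional ROH tibble to shade.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot roh_profile
#' @export
autoplot.roh_profile <- function(object, rohs = NULL, ...) {
  config <- attr(object, "config") %||% roh_config()
  p <- ggplot2::ggplot(object, ggplot2::aes(x = (start + end) / 2e6))
  if (!is.null(rohs) && nrow(rohs) > 0) {
    p <- p + ggplot2::geom_rect(
      data = rohs,
      ggplot2::aes(xmin = start / 1e6, xmax = end / 1e6, ymin = 0, ymax = 1),
      inherit.aes = FALSE, fill = "goldenrod", alpha = 0.25
    )
  }
  p <- p +
    ggplot2::geom_line(ggplot2::aes(y = degree, colour = "raw"),
                       na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = config$degree_threshold,
                        linetype = "dashed")
  if ("smoothed" %in% names(object)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(y = smoothed, colour = "smoothed"),
                                na.rm = TRUE)
  }
  p +
    ggplot2::facet_wrap(~chrom, ncol = 1) +
    ggplot2::scale_colour_manual(values = c(raw = "grey60",
                                            smoothed = "steelblue"),
                                 name = NULL) +
    ggplot2::labs(x = "Position (Mb)", y = "Degree of homozygosity") +
    ggplot2::theme_minimal()
}

#' Plot a concordance table as a heatmap
#'
#' @param object A `concordance_table`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot concordance_table
#' @export
autoplot.concordance_table <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$seq_call, y = .data$array_call,
                                   fill = n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = n), colour = "white") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "Sequencing call", y = "Array call",
                  fill = "Sites") +
    ggplot2::theme_minimal()
}

#' Plot ROH intervals per breed as a segment map
#'
#' @param rohs ROH tibble.
#' @return A ggplot.
#' @export
plot_roh_map <- function(rohs) {
  ggplot2::ggplot(rohs) +
    ggplot2::geom_segment(
      ggplot2::aes(x = start / 1e6, xend = end / 1e6,
                   y = breed, yend = breed, colour = breed),
      linewidth = 4
    ) +
    ggplot2::facet_wrap(~chrom, ncol = 1) +
    ggplot2::labs(x = "Position (Mb)", y = NULL) +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
}
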