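#' Plot LD decay bins
#'
#' @param object An `ld_bins` tibble from [ld_decay()].
#' @param ... Unused.
#' @return A ggplot: mean r-squared against bin midpoint (in kb), one line
#'   per chromosome when present.
#' @method autoplot ld_bins
#' @export
autoplot.ld_bins <- function(object, ...) {
  df <- as_tibble(object)
  df$mid_kb <- (df$distance_lo + df$distance_hi) / 2 / 1000
  df <- df[df$n_pairs > 0, ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$mid_kb, y = .data$mean_r2)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "distance (kb)", y = expression(mean ~ r^2),
                  title = "LD decay")
  if ("chrom" %in% names(df)) {
    p <- p + ggplot2::aes(colour = .data$chrom) + ggplot2::labs(colour = NULL)
  }
  p
}

#' Plot a divergence-rate histogram
#'
#' @param object A `divergence_histogram` from [divergence_histogram()].
#' @param ... Unused.
#' @return A ggplot bar chart with the modal bin highlighted.
#' @method autoplot divergence_histogram
#' @export
autoplot.divergence_histogram <- function(object, ...) {
  df <- as_tibble(object)
  df$modal <- df$bin_lo == attr(object, "modal_lo")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_lo, y = .data$count,
                                   fill = .data$modal)) +
    ggplot2::geom_col(width = df$bin_hi[1] - df$bin_lo[1], just = 0,
                      show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey40", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "divergence", y = "gene pairs",
                  title = "Divergence-rate distribution")
}

#' Plot recovered scaffold order against genetic position
#'
#' @param placements Ordered placements ([order_scaffolds()]).
#' @return A ggplot of cM key against order index, faceted by linkage
#'   group and coloured by evidence class.
#' @export
plot_placements <- function(placements) {
  ggplot2::ggplot(placements,
                  ggplot2::aes(x = .data$order_index, y = .data$cm_key,
                               colour = .data$evidence)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$linkage_group), scales = "free") +
    ggplot2::labs(x = "order on pseudomolecule", y = "cM key", colour = NULL)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
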