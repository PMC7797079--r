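#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an occupancy profile
#'
#' Mean normalized occupancy per codon with standard-error bars, codons
#' ordered by occupancy; codons of the highlighted amino acids are coloured.
#'
#' @param object an `occupancy_profile`.
#' @param highlight character vector of codons to emphasise.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.occupancy_profile <- function(object, highlight = "TGG", ...) {
  df <- dplyr::filter(object, !is.na(.data$mean_occupancy)) |>
    dplyr::mutate(
      codon = stats::reorder(.data$codon, .data$mean_occupancy),
      highlighted = .data$codon %in% highlight)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$codon,
                                   y = .data$mean_occupancy,
                                   colour = .data$highlighted)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_occupancy - .data$stderr,
      ymax = .data$mean_occupancy + .data$stderr), fatten = 1.5) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::labs(x = NULL, y = "normalized codon occupancy") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 6))
}

#' Plot a metagene profile
#'
#' Mean normalized RPF density against codon offset from the target codon;
#' called peaks (if supplied) are marked.
#'
#' @param object a `metagene_profile`.
#' @param peaks optional peak table from [detect_peaks()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.metagene_profile <- function(object, peaks = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$position,
                                            y = .data$mean_density)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::labs(
      x = sprintf("codon offset from %s", attr(object, "target_codon")),
      y = "mean normalized RPF density") +
    ggplot2::theme_bw()
  if (!is.null(peaks) && any(peaks$passes_threshold)) {
    called <- peaks[peaks$passes_threshold, ]
    p <- p + ggplot2::geom_vline(xintercept = called$position,
                                 linetype = "dotted", colour = "firebrick")
  }
  p
}

#' Scatter plot of codon occupancies in two conditions
#'
#' Log2 occupancy in the stress condition against control, one point per
#' codon, with the highlighted codons labelled — the standard two-condition
#' codon-occupancy comparison.
#'
#' @param ratio tibble from [occupancy_ratio()].
#' @param highlight codons to label.
#' @return a ggplot object.
#' @export
plot_occupancy_scatter <- function(ratio, highlight = "TGG") {
  df <- dplyr::filter(ratio, !is.na(.data$log2_ratio)) |>
    dplyr::mutate(highlighted = .data$codon %in% highlight)
  ggplot2::ggplot(df, ggplot2::aes(x = log2(.data$occupancy_control),
                                   y = log2(.data$occupancy_stress))) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$highlighted)) +
    ggplot2::geom_text(
      data = ~ dplyr::filter(.x, .data$highlighted),
      ggplot2::aes(label = .data$codon), vjust = -1) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "black"),
                                 guide = "none") +
    ggplot2::labs(x = "log2 occupancy (control)",
                  y = "log2 occupancy (stress)") +
    ggplot2::theme_bw()
}

#' Boxplots of TE change by codon-content bin
#'
#' @param x a `bin_trend` object.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.bin_trend <- function(x, ...) {
  ref <- x$summary$median[x$summary$bin_id == 1L]
  p <- ggplot2::ggplot(x$genes,
                       ggplot2::aes(x = factor(.data$bin_id),
                                    y = .data$log2_te_change)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(x = "codon-content bin (0 = no occurrence)",
                  y = "log2 TE change (median-centred)") +
    ggplot2::theme_bw()
  if (length(ref) == 1L) {
    p <- p + ggplot2::geom_hline(yintercept = ref, linetype = "dashed",
                                 colour = "firebrick")
  }
  p
}
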