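#' VAF histogram plot
#'
#' Histogram of variant allele fractions at fixed bin width (0.02), the
#' representation used to inspect the amplification-artifact VAF peak
#' (around 0.26 in MDA-amplified embryo biopsies) against the 0.5
#' heterozygote expectation.
#'
#' @param data Tibble with a `vaf` column (e.g. a screening table or gate
#'   output).
#' @param binwidth Bin width.
#' @return A ggplot object.
#' @export
plot_vaf_histogram <- function(data, binwidth = 0.02) {
  ggplot2::ggplot(filter(data, !is.na(.data$vaf)),
                  ggplot2::aes(x = .data$vaf)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "grey30") +
    ggplot2::geom_vline(xintercept = 0.35, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = "variant allele fraction", y = "sites",
                  title = "VAF distribution (dashed: de novo gate)") +
    ggplot2::theme_minimal()
}

#' Depth-bin copy-ratio plot
#'
#' Per-bin embryo/parent copy ratio along a chromosome with the duplication
#' and deletion thresholds, and CNV calls overlaid.
#'
#' @param scored Scored bin tibble ([score_bins()]).
#' @param calls Optional CNV call tibble to overlay.
#' @param chrom Optional single chromosome to show.
#' @return A ggplot object.
#' @export
plot_depth_bins <- function(scored, calls = NULL, chrom = NULL) {
  if (!is.null(chrom)) {
    scored <- filter(scored, .data$chrom == .env$chrom)
    if (!is.null(calls)) calls <- filter(calls, .data$chrom == .env$chrom)
  }
  p <- ggplot2::ggplot(scored, ggplot2::aes(x = .data$start / 1e6,
                                            y = .data$ratio)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.5) +
    ggplot2::geom_hline(yintercept = c(0.5, 2), linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "copy ratio") +
    ggplot2::theme_minimal()
  if (!is.null(calls) && nrow(calls) > 0) {
    p <- p + ggplot2::geom_segment(
      data = calls,
      ggplot2::aes(x = .data$start / 1e6, xend = .data$end / 1e6,
                   y = .data$mean_ratio, yend = .data$mean_ratio),
      colour = "dodgerblue", linewidth = 1.2
    )
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Filter-survivor bar chart for an embryo report
#'
#' Successive per-filter survivor counts for each inheritance mode
#' (each filter is added to the previous ones).
#'
#' @param object An `embryo_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.embryo_report <- function(object, ...) {
  sc <- object$survivor_counts |>
    group_by(.data$mode) |>
    mutate(step = factor(.data$step, levels = unique(.data$step))) |>
    ungroup()
  ggplot2::ggplot(sc, ggplot2::aes(x = .data$step, y = .data$remaining)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::facet_wrap(~mode, scales = "free") +
    ggplot2::labs(
      x = NULL, y = "variants remaining",
      title = paste0("Successive filter survivors — ", object$embryo_id)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
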