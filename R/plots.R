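#' Plot a genome track
#'
#' @param object A [genome_track()].
#' @param chrom Chromosome to draw (default: first).
#' @param xlim Optional bp range to zoom into.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.genome_track <- function(object, chrom = NULL, xlim = NULL, ...) {
  if (is.null(chrom)) chrom <- track_chroms(object)[1]
  d <- tidy(object)
  d <- d[d$chrom == chrom & !is.na(d$value), ]
  if (!is.null(xlim)) d <- d[d$start >= xlim[1] & d$end <= xlim[2], ]
  ggplot2::ggplot(d, ggplot2::aes(x = (.data$start + .data$end) / 2,
                                  y = .data$value)) +
    ggplot2::geom_step(linewidth = 0.3) +
    ggplot2::labs(x = paste0(chrom, " position (bp)"), y = object$semantics,
                  title = paste0("Track (smoothing: ",
                                 as.character(object$smoothing), ")")) +
    ggplot2::theme_minimal()
}

#' Plot distance profiles (observed vs random control)
#'
#' @param profiles One `distance_profile` tibble or a row-bound set of
#'   them (distinguished by the `label` column).
#' @return A ggplot bar chart of bin fractions.
#' @export
plot_distance_profile <- function(profiles) {
  d <- as_tibble(profiles)
  d$bin_label <- factor(
    ifelse(is.finite(d$upper),
           sprintf("%g-%g", d$lower / 1000, d$upper / 1000),
           sprintf(">%g", d$lower / 1000)),
    levels = unique(ifelse(is.finite(d$upper),
                           sprintf("%g-%g", d$lower / 1000, d$upper / 1000),
                           sprintf(">%g", d$lower / 1000))))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bin_label, y = .data$fraction,
                                  fill = .data$label)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "Distance to nearest HAS (kb)", y = "Fraction of sites",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a TSS repeat profile
#'
#' @param profile A `tss_profile` tibble from [tss_repeat_profile()].
#' @return A ggplot line chart with 95% CI ribbons per gene group.
#' @export
plot_tss_profile <- function(profile) {
  d <- as_tibble(profile)
  bin_bp <- attr(profile, "bin_bp") %||% 1000
  d$kb <- (d$bin - 0.5) * bin_bp / 1000
  ggplot2::ggplot(d, ggplot2::aes(x = .data$kb, y = .data$mean_pct,
                                  colour = .data$group, fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lower,
                                      ymax = .data$ci_upper),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Distance from TSS (kb)",
                  y = "Repeat-masked sequence (%)",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Scatter plot of repeat-class RPKM (ChIP vs input)
#'
#' @param enrichment A `class_enrichment` tibble.
#' @param label_threshold Label classes with ratio at or above this fold
#'   (default 2).
#' @return A ggplot scatter on log10 axes.
#' @export
plot_class_enrichment <- function(enrichment, label_threshold = 2) {
  d <- as_tibble(enrichment)
  lab <- d[!is.na(d$ratio) & d$ratio >= label_threshold, ]
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$input_rpkm,
                                       y = .data$chip_rpkm)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Input RPKM", y = "ChIP RPKM") +
    ggplot2::theme_minimal()
  if (nrow(lab) > 0) {
    p <- p + ggplot2::geom_text(data = lab,
                                ggplot2::aes(label = .data$class),
                                vjust = -0.6, size = 3)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

`%||%` <- function(a, b) if (is.null(a)) b else a
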