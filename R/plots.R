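# ggplot2 figures for the main result types.

#' Plot TSS metagene profiles
#'
#' One line per sample, faceted by mark; the vertical line marks the TSS.
#' @param profile tibble from [tss_metagene_profile()].
#' @return a ggplot object.
#' @export
plot_metagene <- function(profile) {
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = .data$offset, y = .data$nc,
                               colour = .data$condition,
                               group = .data$sample)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey40") +
    ggplot2::facet_wrap(~mark, scales = "free_y") +
    ggplot2::labs(x = "distance from TSS (bp)",
                  y = "mean enrichment over input") +
    ggplot2::theme_minimal()
}

#' Volcano plot of differential windows
#'
#' @param stats tibble from [diff_windows()].
#' @param q_max,delta_min thresholds to highlight (defaults 0.01 and 3).
#' @return a ggplot object.
#' @export
plot_volcano <- function(stats, q_max = 0.01, delta_min = 3) {
  d <- mutate(stats, called = .data$q <= q_max & abs(.data$delta) > delta_min)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$delta,
                                  y = -log10(pmax(.data$q, 1e-300)),
                                  colour = .data$called)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.5) +
    ggplot2::facet_wrap(~mark) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "enrichment difference (delta)",
                  y = "-log10 adjusted p") +
    ggplot2::theme_minimal()
}

#' Plot an MDS embedding of samples
#'
#' @param mds tibble from [mds_samples()].
#' @return a ggplot object.
#' @export
plot_mds <- function(mds) {
  ggplot2::ggplot(mds, ggplot2::aes(x = .data$dim1, y = .data$dim2,
                                    colour = .data$condition,
                                    label = .data$sample)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(x = "MDS dimension 1", y = "MDS dimension 2") +
    ggplot2::theme_minimal()
}

#' Plot a motif probability curve
#'
#' @param curve tibble from [motif_probability_curve()].
#' @return a ggplot object.
#' @export
plot_motif_curve <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$offset, y = .data$probability)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "offset from region center (bp)",
                  y = "motif probability") +
    ggplot2::theme_minimal()
}

#' Plot mean expression by distance from the nearest region
#'
#' @param profile tibble from [distance_expression_profile()].
#' @return a ggplot object.
#' @export
plot_distance_profile <- function(profile) {
  d <- mutate(profile,
              x = ifelse(is.infinite(.data$bin_end), .data$bin_start,
                         (.data$bin_start + .data$bin_end) / 2))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x / 1000, y = .data$mean_expr)) +
    ggplot2::geom_col(width = 8) +
    ggplot2::labs(x = "distance to nearest region (kbp)",
                  y = "mean log2 expression") +
    ggplot2::theme_minimal()
}
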