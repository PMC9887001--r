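#' Plot parental read counts with allelic calls
#'
#' Scatter of maternal vs paternal informative reads (log scale) coloured by
#' the allelic call.
#'
#' @param object An `allelic_calls` table.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.allelic_calls <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$maternal_reads + 1,
                               y = .data$paternal_reads + 1,
                               colour = .data$call)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "maternal reads + 1", y = "paternal reads + 1",
                  colour = "call") +
    ggplot2::theme_minimal()
}

#' MA-style plot of a differential-expression comparison
#'
#' Mean normalized signal against log2 fold change, DEGs highlighted.
#'
#' @param object A `deg_calls` table.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.deg_calls <- function(object, ...) {
  d <- tibble::as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(
    x = (.data$fpkm_a + .data$fpkm_b) / 2 + 0.1,
    y = .data$log2fc, colour = .data$is_deg)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "mean merged FPKM", y = "log2 fold change (A / B)",
                  colour = "DEG") +
    ggplot2::theme_minimal()
}

#' Methylation-difference plot with DMS calls
#'
#' Per-CpG methylation difference along the chromosome, DMSs highlighted.
#'
#' @param object A `dms_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dms_table <- function(object, ...) {
  d <- tibble::as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pos, y = .data$diff,
                                  colour = .data$is_dms)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.6) +
    ggplot2::geom_hline(yintercept = c(-0.2, 0.2), linetype = 3) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "darkorange")) +
    ggplot2::labs(x = "position (bp)", y = "methylation difference (A - B)",
                  colour = "DMS") +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom)) +
    ggplot2::theme_minimal()
}

#' Cross-sample DHS signal with allelic calls
#'
#' Scatter of scaled sample-B FPKM against sample-A FPKM (log scale),
#' coloured by allelic call, with the fold-change boundaries.
#'
#' @param object A `dhs_calls` table.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dhs_calls <- function(object, ...) {
  d <- tibble::as_tibble(object)
  samples <- attr(object, "samples") %||% c("A", "B")
  fa <- d[[paste0("fpkm_", samples[1])]]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$fpkm_b_scaled + 0.5,
                                  y = fa + 0.5, colour = .data$call)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = paste0(samples[2], " FPKM (scaled) + 0.5"),
                  y = paste0(samples[1], " FPKM + 0.5"), colour = "call") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
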