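#' @importFrom rlang .data
NULL

#' Forest plot of per-dataset burden odds ratios
#'
#' @param per_ds data.frame from \code{\link{perDatasetFits}}
#' @return a ggplot object
#' @export
plotForest <- function(per_ds) {
  df <- per_ds[!is.na(per_ds$beta), , drop = FALSE]
  df$or <- exp(0.01 * df$beta)
  df$lo <- exp(0.01 * (df$beta - 1.96 * df$se))
  df$hi <- exp(0.01 * (df$beta + 1.96 * df$se))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$or, y = .data$dataset)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                            height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio per 1% Froh", y = NULL) +
    ggplot2::theme_bw()
}

#' Burden slope across ROH SNP thresholds
#'
#' @param sweep data.frame from \code{\link{thresholdSweep}}
#' @return a ggplot object
#' @export
plotSweep <- function(sweep) {
  ggplot2::ggplot(sweep, ggplot2::aes(x = .data$min_snps, y = .data$beta)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lo,
                                      ymax = .data$ci_hi), alpha = 0.2) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "minimum homozygous SNPs per ROH",
                  y = "burden slope (log-odds per unit Froh)") +
    ggplot2::theme_bw()
}

#' Signed Manhattan-style plot and ROH frequency track for the mapping scan
#'
#' Risk bins (positive slope) plot upward, protective bins downward; the
#' lower track shows the per-bin ROH carriage frequency.
#'
#' @param x a \linkS4class{MappingResult}
#' @return a ggplot object
#' @export
plotMapping <- function(x) {
  df <- cbind(x@bins, x@results[, -1])
  df <- df[!df$skipped, , drop = FALSE]
  df$pos <- (df$bp_start + df$bp_end) / 2
  df$signed <- df$minus_log10_p * df$sign
  p1 <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pos / 1e6)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$signed,
                                     colour = factor(.data$sign)),
                        size = 0.8, show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c("-1" = "steelblue",
                                            "1" = "firebrick")) +
    ggplot2::facet_grid(. ~ chrom, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (Mb)",
                  y = "signed -log10 p (risk up, protective down)") +
    ggplot2::theme_bw()
  if (is.finite(x@suggestiveP))
    p1 <- p1 + ggplot2::geom_hline(
      yintercept = c(-1, 1) * -log10(x@suggestiveP),
      linetype = 3, colour = "grey40")
  p1
}
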