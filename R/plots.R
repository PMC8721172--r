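# Base-graphics views of the dosage statistics.

#' Boxplots of the binned bootstrap X:A ratio
#'
#' One box per expression bin, grouped by genotype, with a reference line
#' at 1 (dosage compensation).
#'
#' @param boot From [xa_bootstrap()].
#' @param ... Passed to [graphics::boxplot()].
#' @return Invisibly, the boxplot statistics.
#' @export
plot_xa_bootstrap <- function(boot, ...) {
  bp <- graphics::boxplot(ratio ~ genotype + bin, data = boot,
                          outline = FALSE, las = 2,
                          xlab = "expression bin x genotype",
                          ylab = "X:A ratio of medians", ...)
  graphics::abline(h = 1, lty = 2, col = "grey40")
  invisible(bp)
}

#' X-dosage ratio profile along the chromosome
#'
#' Per-gene XO/XY:XX expression ratios against chromosome position, with
#' the fitted geometric mean and its multiplicative SD band.
#'
#' @param fit From [ratio_fit()] (with annotation attached to the
#'   normalized matrix).
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the per-gene ratio table.
#' @export
plot_ratio_profile <- function(fit, ...) {
  rt <- fit$ratios
  if (is.null(rt$start_bp)) stop_arg("ratio table carries no positions")
  graphics::plot(rt$start_bp / 1e6, rt$ratio, pch = 16, cex = 0.6,
                 xlab = "position (Mb)", ylab = "ratio vs XX", log = "y", ...)
  graphics::abline(h = fit$geometric_mean, col = "red")
  graphics::abline(h = fit$mult_sd_interval, col = "red", lty = 2)
  invisible(rt)
}
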