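#' Scatter plot of a screening run
#'
#' Plots target synapse density (x) against target specificity ratio (y),
#' one point per candidate — the standard view for comparing candidates in a
#' screen.  Excluded candidates (when a verdict is supplied) are drawn as
#' open triangles; an optional vertical line marks the expected maximum
#' plausible density.
#'
#' @param reports List of `measurement_report`s.
#' @param verdict Optional `screening_verdict` from [rank_candidates()].
#' @param expected_max_density Optional density cutoff to draw.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the plotted data frame.
#' @export
plot_screen <- function(reports, verdict = NULL, expected_max_density = NULL,
                        ...) {
  tab <- report_table(reports)
  excluded <- rep(FALSE, nrow(tab))
  if (!is.null(verdict))
    excluded <- tab$channel_name %in%
      verdict$channel_name[verdict$excluded]
  graphics::plot(tab$target_synapse_density, tab$tsr,
                 pch = ifelse(excluded, 2L, 19L),
                 xlab = "target synapse density (per um^3)",
                 ylab = "target specificity ratio",
                 ylim = c(0, max(1, tab$tsr, na.rm = TRUE)), ...)
  graphics::text(tab$target_synapse_density, tab$tsr,
                 labels = tab$channel_name, pos = 3, cex = 0.7)
  if (!is.null(expected_max_density))
    graphics::abline(v = expected_max_density, lty = 2)
  invisible(tab)
}
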