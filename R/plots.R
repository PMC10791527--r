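#' Density plot of a group change distribution with the focal marked
#'
#' Plots the kernel density of per-individual change scores, a dashed
#' vertical line at the group mean and a solid red line at the focal's
#' value — the standard way to show where the provider falls in the group
#' change distribution.
#'
#' @param changes numeric vector of per-individual changes.
#' @param focal_change the focal's change.
#' @param main plot title.
#' @param xlab x-axis label.
#' @return Invisibly, the [stats::density()] object.
#' @export
plot_change_density <- function(changes, focal_change,
                                main = "change distribution",
                                xlab = "change (experimental - baseline)") {
  d <- stats::density(changes)
  xlim <- range(c(d$x, focal_change))
  graphics::plot(d, main = main, xlab = xlab, xlim = xlim)
  graphics::abline(v = mean(changes), lty = 2)
  graphics::abline(v = focal_change, col = "red", lwd = 2)
  invisible(d)
}
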