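## Minimal base-graphics summaries of the headline quantifications.

#' Plot an aggregate normalised-length curve
#'
#' Mean normalised embryo length with a +/- SD ribbon over normalised
#' developmental time.
#'
#' @param curve an [aggregateCurves()] result.
#' @param ... further arguments to [graphics::plot()].
#' @return Invisibly, `curve`.
#' @export
plotAggregateCurve <- function(curve, ...) {
  graphics::plot(curve$norm_time, curve$mean, type = "n",
                 xlab = "normalised developmental time",
                 ylab = "normalised embryo length", ...)
  graphics::polygon(c(curve$norm_time, rev(curve$norm_time)),
                    c(curve$mean + curve$sd, rev(curve$mean - curve$sd)),
                    col = "grey85", border = NA)
  graphics::lines(curve$norm_time, curve$mean, lwd = 2)
  invisible(curve)
}

#' Plot germband-tip kinematics
#'
#' Cumulative migration distance (left axis, solid) and per-interval
#' speed (right axis, dashed) of the posterior germband tip.
#'
#' @param kin a [tipKinematics()] result.
#' @param ... further arguments to [graphics::plot()].
#' @return Invisibly, `kin`.
#' @export
plotTipKinematics <- function(kin, ...) {
  op <- graphics::par(mar = c(5, 4, 2, 4))
  on.exit(graphics::par(op))
  graphics::plot(kin$time_h, kin$distance_um, type = "l", lwd = 2,
                 xlab = "time [h]", ylab = "migration distance [um]", ...)
  graphics::par(new = TRUE)
  graphics::plot(kin$time_h, kin$speed_um_h, type = "l", lty = 2,
                 axes = FALSE, xlab = "", ylab = "")
  graphics::axis(4)
  graphics::mtext("speed [um/h]", side = 4, line = 2.5)
  invisible(kin)
}
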