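# Out-of-plane projection error of the measured retardance.
#
# When the spindle long axis is tilted out of the image plane, the measured
# retardance scales with the intrinsic value (what a perfectly in-plane
# spindle would give) by the squared in-plane projection of the axis:
# r_meas = r * (1 - u^2), where u is the out-of-plane component of the unit
# spindle axis. With |u| bounded, the worst-case relative deviation is the
# bound squared.

#' Worst-case retardance projection error for a bounded tilt
#'
#' Maximizes the relative deviation `|r - r_meas| / r = u^2` over all
#' admissible spindle orientations with out-of-plane axis component
#' `|u| <= u_max`, by direct numerical maximization over the tilt.
#'
#' @param u_max Bound on the out-of-plane component of the unit spindle
#'   axis (the acquisition protocol keeps this below 0.1).
#' @return Worst-case relative retardance deviation, in percent.
#' @export
tilt_retardance_error <- function(u_max = 0.1) {
  stopifnot(u_max >= 0, u_max <= 1)
  rel_dev <- function(u) {
    # axis tilted out of plane by asin(u): measured = intrinsic * cos^2(tilt)
    tilt <- asin(u)
    1 - cos(tilt)^2
  }
  worst <- optimize(rel_dev, interval = c(0, u_max), maximum = TRUE)$objective
  100 * max(worst, rel_dev(u_max))
}
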