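# Nematic (headless, mod-pi) angle arithmetic. All operations work on the
# doubled angle 2*theta, where the nematic branch cut disappears.

#' Reduce angles to the principal nematic branch
#'
#' Nematic orientations are defined modulo pi. This maps any angle to the
#' representative in `(-pi/2, pi/2]`.
#'
#' @param theta Numeric vector or array of angles (rad).
#' @return Object of the same shape with values in `(-pi/2, pi/2]`.
#' @export
wrap_nematic <- function(theta) {
  out <- atan2(sin(2 * theta), cos(2 * theta)) / 2
  # atan2 returns (-pi, pi]; -pi/2 maps to +pi/2 by nematic equivalence
  out[out <= -pi / 2 + .Machine$double.eps] <- pi / 2
  out
}

#' Nematic mean of a set of orientations
#'
#' Averages orientations that are only defined modulo pi using the resultant
#' of the doubled angles, `mean = arg(sum(exp(2i * theta))) / 2`. The naive
#' arithmetic mean of 0 and pi would be pi/2; the nematic mean is 0.
#'
#' @param theta Numeric vector of angles (rad). `NA`s are dropped.
#' @param tol Minimum length of the mean resultant vector; below this the
#'   average is direction-free (e.g. `c(pi/4, 3*pi/4)`) and an error is
#'   raised.
#' @return Scalar angle in `(-pi/2, pi/2]`.
#' @export
nematic_mean <- function(theta, tol = 1e-8) {
  theta <- theta[is.finite(theta)]
  if (length(theta) == 0L) abort("no finite angles to average", class = "nemspindle_degenerate_average")
  z <- mean(exp(2i * theta))
  if (Mod(z) < tol) {
    abort("degenerate nematic average: resultant magnitude below tolerance",
          class = "nemspindle_degenerate_average")
  }
  wrap_nematic(Arg(z) / 2)
}

#' Nematic angular difference
#'
#' Signed difference `theta1 - theta2` on the mod-pi circle, computed on the
#' doubled angle so that 0 and pi are identical. The magnitude is the nematic
#' distance `d(theta1, theta2) = |arg(exp(2i (theta1 - theta2)))| / 2`.
#'
#' @param theta1,theta2 Angles (rad); recycled to a common shape.
#' @return Signed difference in `(-pi/2, pi/2]`.
#' @export
nematic_diff <- function(theta1, theta2) {
  wrap_nematic(theta1 - theta2)
}

# Reduce an ordinary (vector) angle to (-pi, pi]
wrap_pi <- function(x) {
  out <- atan2(sin(x), cos(x))
  out[out <= -pi + .Machine$double.eps] <- pi
  out
}
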