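# Circle-arc nematic director field.
#
# With strong tangential anchoring on the convex surface and normal anchoring
# on the polar caps, the director inside a tactoid lies tangent to the unique
# family of circles through the two virtual poles (+-L0, 0). The circle
# through (x, y) and both poles has center (0, cy) with
# cy = (x^2 + y^2 - L0^2) / (2 y); the director is the tangent of that circle.

#' Circle-arc director angle
#'
#' Nematic angle of the circle-arc director field at points `(x, y)` for
#' virtual poles at `(+-L0, 0)`. On both axes the field is horizontal
#' (`theta = 0`); the virtual poles themselves are singular.
#'
#' @param x,y Coordinates (um), recycled to a common length.
#' @param L0 Virtual-pole half-spacing (um).
#' @return Nematic angles in `(-pi/2, pi/2]`.
#' @export
theta_arcs <- function(x, y, L0) {
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  at_pole <- abs(y) < .Machine$double.eps^0.5 * max(1, L0) &
    abs(abs(x) - L0) < .Machine$double.eps^0.5 * max(1, L0)
  if (any(at_pole)) {
    abort("director field is singular at the virtual poles (+-L0, 0)",
          class = "nemspindle_singular_point")
  }
  theta_arcs_quiet(x, y, L0)
}

# as theta_arcs, but pixels that happen to fall on a virtual pole (always
# outside the spindle material) get the axis limit instead of an error --
# used when resampling whole grids
theta_arcs_quiet <- function(x, y, L0) {
  cy <- (x^2 + y^2 - L0^2) / (2 * y)   # Inf on the axis; handled below
  # tangent direction t = (y - cy, -x); nematic angle = atan(-x / (y - cy))
  th <- atan2(-x, y - cy)
  th[y == 0] <- 0                      # axis is a field line (limit)
  wrap_nematic(th)
}

#' Circle-arc director field on a pixel grid
#'
#' @param nx,ny Grid size in pixels.
#' @param pixel_size Pixel size (um).
#' @param L0 Virtual-pole half-spacing (um).
#' @param center Grid coordinates (um) of the spindle center; defaults to the
#'   grid midpoint.
#' @return `ny x nx` matrix of nematic angles; row i / column j is centered at
#'   `((j - 0.5) * pixel_size, (i - 0.5) * pixel_size)` relative to the grid
#'   origin.
#' @export
theta_arcs_field <- function(nx, ny, pixel_size, L0, center = NULL) {
  g <- pixel_grid(nx, ny, pixel_size, center)
  matrix(theta_arcs(as.vector(g$x), as.vector(g$y), L0), nrow = ny)
}

# Pixel-center coordinate grids (row-major raster, pixel (i, j) centered at
# ((j - 0.5) dx, (i - 0.5) dx) relative to `center`).
pixel_grid <- function(nx, ny, pixel_size, center = NULL) {
  if (is.null(center)) center <- c(nx, ny) / 2 * pixel_size
  xs <- ((seq_len(nx)) - 0.5) * pixel_size - center[1]
  ys <- ((seq_len(ny)) - 0.5) * pixel_size - center[2]
  list(x = matrix(xs, nrow = ny, ncol = nx, byrow = TRUE),
       y = matrix(ys, nrow = ny, ncol = nx),
       xs = xs, ys = ys)
}

#' Predicted boundary anchoring angle
#'
#' The director meets the tactoid boundary tangentially on the convex arcs
#' and normally on the concave polar caps. This returns that anchoring angle
#' `eta(phi)` for boundary points of a fitted tactoid.
#'
#' @param phi Polar angles (rad).
#' @param tac A [tactoid()].
#' @return Nematic angles in `(-pi/2, pi/2]`.
#' @export
anchoring_angle <- function(phi, tac) {
  a <- wrap_pi(phi)
  rad <- tactoid_radius(tac, a)
  x <- rad * cos(a); y <- rad * sin(a)
  af <- abs(a); af <- pmin(af, pi - af)
  on_cap <- af <= tac$phi_j
  eta <- numeric(length(a))
  if (any(!on_cap)) {
    # tangent of the convex circle with center (0, +-|c|... ) -- center is
    # (0, c) for the upper arc, (0, -c) for the lower one
    cy <- ifelse(y[!on_cap] >= 0, tac$c, -tac$c)
    eta[!on_cap] <- atan2(-x[!on_cap], y[!on_cap] - cy)
  }
  if (any(on_cap)) {
    # cap normal passes through the cap center (+-L0, 0)
    px <- ifelse(x[on_cap] >= 0, tac$L0, -tac$L0)
    eta[on_cap] <- atan2(y[on_cap], x[on_cap] - px)
  }
  wrap_nematic(eta)
}

#' Fold an angle field into the first quadrant
#'
#' Uses the odd mirror symmetry of the director field,
#' `theta(-x, y) = theta(x, -y) = -theta(x, y)`: for each first-quadrant
#' point the four mirror samples are combined as
#' `(theta(x,y) - theta(x,-y) - theta(-x,y) + theta(-x,-y)) / 4`.
#' Constants cancel and symmetric noise is averaged down.
#'
#' @param theta `ny x nx` angle matrix on a grid symmetric about both axes
#'   (even `nx` and `ny`, center at the grid midpoint).
#' @return `(ny/2) x (nx/2)` matrix for the first quadrant, rows ordered with
#'   increasing `y`.
#' @export
symmetrize_quadrant <- function(theta) {
  ny <- nrow(theta); nx <- ncol(theta)
  if (ny %% 2L != 0L || nx %% 2L != 0L) {
    abort("grid must be symmetric about both axes (even dimensions)",
          class = "nemspindle_grid_error")
  }
  hy <- ny %/% 2L; hx <- nx %/% 2L
  q1 <- theta[(hy + 1):ny, (hx + 1):nx]          # x > 0, y > 0
  q2 <- theta[(hy + 1):ny, hx:1]                 # x < 0 mirrored
  q3 <- theta[hy:1, (hx + 1):nx]                 # y < 0 mirrored
  q4 <- theta[hy:1, hx:1]                        # both mirrored
  (q1 - q2 - q3 + q4) / 4
}

#' Compare a measured angle field with the circle-arc model
#'
#' Computes the rms nematic difference between a time-averaged slow-axis
#' field and the circle-arc prediction for the fitted tactoid, inside the
#' spindle outline, together with rescaled line profiles (in units of the
#' virtual-pole half-spacing) for cross-spindle comparison.
#'
#' @param theta_mean `ny x nx` matrix of time-averaged nematic angles (rad).
#' @param tac A [tactoid()] fitted to the same spindle.
#' @param pixel_size Pixel size (um).
#' @param center Spindle center (um) on the grid; defaults to the midpoint.
#' @param profile_bins Number of bins for the rescaled line profiles.
#' @param band Fraction of the local boundary radius excluded at the rim when
#'   computing the rms (avoids boundary interpolation artifacts).
#' @return A list of class `"director_comparison"`: `rms` (rad), and
#'   `profiles`, a tibble of binned angle-vs-position curves along the
#'   rescaled x and y axes (`axis`, `pos`, `theta_obs`, `theta_model`, `se`,
#'   `n`).
#' @export
model_residual <- function(theta_mean, tac, pixel_size, center = NULL,
                           profile_bins = 24L, band = 0.05) {
  ny <- nrow(theta_mean); nx <- ncol(theta_mean)
  g <- pixel_grid(nx, ny, pixel_size, center)
  phi <- atan2(g$y, g$x)
  rad <- sqrt(g$x^2 + g$y^2)
  inside <- rad <= (1 - band) * tactoid_radius(tac, phi)
  if (!any(inside)) abort("no overlap between field and tactoid interior")
  model <- matrix(theta_arcs(as.vector(g$x), as.vector(g$y), tac$L0), nrow = ny)
  d <- nematic_diff(theta_mean, model)
  rms <- sqrt(mean(d[inside]^2))

  # Rescaled line profiles: fold all quadrants into the first and bin theta
  # along lines offset from the axes (on the axes the field is identically
  # horizontal, so offset lines carry the shape information). The horizontal
  # profile runs along |y| = offset * L0, the vertical one along
  # |x| = offset * L0; bands of ~3 pixels half-width.
  offset <- 0.25
  halfw <- 1.5 * pixel_size
  fold <- sign(g$x) * sign(g$y); fold[fold == 0] <- 1
  th_folded <- theta_mean * fold                  # odd symmetry
  mk_profile <- function(sel, pos, axis) {
    if (!any(sel)) return(tibble())
    df <- tibble(pos = pos[sel] / tac$L0,
                 obs = th_folded[sel],
                 model = (model * fold)[sel])
    df$bin <- cut(df$pos, breaks = seq(0, max(df$pos) + 1e-9,
                                       length.out = profile_bins + 1L),
                  include.lowest = TRUE)
    out <- dplyr::summarise(
      dplyr::group_by(df, .data$bin),
      pos = mean(.data$pos),
      theta_obs = nematic_mean(.data$obs),
      theta_model = nematic_mean(.data$model),
      se = sd(.data$obs) / sqrt(dplyr::n()),
      n = dplyr::n(), .groups = "drop")
    out$axis <- axis
    dplyr::select(out, "axis", "pos", "theta_obs", "theta_model", "se", "n")
  }
  prof_x <- mk_profile(inside & abs(abs(g$y) - offset * tac$L0) <= halfw,
                       abs(g$x), "x")
  prof_y <- mk_profile(inside & abs(abs(g$x) - offset * tac$L0) <= halfw,
                       abs(g$y), "y")
  structure(list(rms = rms, profiles = dplyr::bind_rows(prof_x, prof_y)),
            class = "director_comparison")
}

#' @export
print.director_comparison <- function(x, ...) {
  cat(sprintf("Circle-arc model comparison: rms nematic residual = %.4f rad\n", x$rms))
  invisible(x)
}
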