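# Pole-indented tactoid geometry.
#
# The spindle outline is modelled by four circle arcs: two convex arcs through
# the virtual poles (+-L0, 0) with apexes (0, +-R0) (their centers lie on the
# y-axis at c = (R0^2 - L0^2) / (2 R0), radius R1 = R0 - c, and they pass
# through the poles because R1 = sqrt(L0^2 + c^2)), and two concave polar-cap
# arcs of radius r0 centered on the virtual poles. The cap arc meets the
# convex arc at a join point computed from the two-circle intersection; the
# shape's tips sit on the axis at (+-(L0 - r0), 0).

#' Construct a pole-indented tactoid
#'
#' @param L0 Virtual-pole half-spacing (um); the convex boundary arcs
#'   intersect at `(+-L0, 0)`.
#' @param R0 Belt half-width (um): the boundary apex is `(0, +-R0)`.
#' @param r0 Polar-cap radius (um); the concave cap arcs are circles of this
#'   radius centered on the virtual poles.
#' @return An object of class `"tactoid"`: a list with the input parameters
#'   and derived quantities (convex-circle center `c` and radius `R1`, the
#'   cap/convex join point and its polar angle `phi_j`, and the tip abscissa
#'   `L0 - r0`).
#' @export
tactoid <- function(L0, R0, r0) {
  stopifnot(is.numeric(L0), is.numeric(R0), is.numeric(r0))
  if (!(r0 > 0 && r0 < L0)) {
    abort("tactoid requires 0 < r0 < L0", class = "nemspindle_invalid_geometry")
  }
  if (!(R0 > 0)) abort("tactoid requires R0 > 0", class = "nemspindle_invalid_geometry")
  cc <- (R0^2 - L0^2) / (2 * R0)
  R1 <- R0 - cc                        # = sqrt(L0^2 + cc^2)
  if (r0 >= 2 * R1) {
    abort("cap circle does not intersect the convex arc (r0 too large)",
          class = "nemspindle_invalid_geometry")
  }
  # Join point: on the convex circle (center (0, cc), radius R1) at angular
  # offset alpha from the direction of the pole, where the chord to the pole
  # equals r0: |P - pole|^2 = 2 R1^2 (1 - cos(alpha)) = r0^2.
  alpha <- acos(1 - r0^2 / (2 * R1^2))
  pole_ang <- atan2(-cc, L0)           # direction (0,cc) -> (L0, 0)
  vj <- pole_ang + alpha               # rotate toward the apex
  xj <- R1 * cos(vj)
  yj <- cc + R1 * sin(vj)
  if (yj <= 0 || xj <= L0 - r0) {
    abort("degenerate cap/convex join", class = "nemspindle_invalid_geometry")
  }
  structure(
    list(L0 = L0, R0 = R0, r0 = r0, c = cc, R1 = R1,
         xj = xj, yj = yj, phi_j = atan2(yj, xj), tip = L0 - r0),
    class = "tactoid"
  )
}

#' @export
print.tactoid <- function(x, ...) {
  cat(sprintf("Pole-indented tactoid: L0 = %.3g, R0 = %.3g, r0 = %.3g um (tip at %.3g um)\n",
              x$L0, x$R0, x$r0, x$tip))
  invisible(x)
}

#' Boundary radius of a pole-indented tactoid at polar angles
#'
#' @param tac A [tactoid()].
#' @param phi Polar angles (rad) about the spindle center.
#' @return Boundary radius `b(phi)` (um), one value per angle.
#' @export
tactoid_radius <- function(tac, phi) {
  a <- abs(wrap_pi(phi))
  a <- pmin(a, pi - a)                 # fold into the first quadrant sector
  r <- numeric(length(a))
  cap <- a <= tac$phi_j
  if (any(cap)) {
    s2 <- tac$r0^2 - tac$L0^2 * sin(a[cap])^2
    s2[s2 < 0] <- 0                    # numerical guard at the join
    r[cap] <- tac$L0 * cos(a[cap]) - sqrt(s2)
  }
  if (any(!cap)) {
    ac <- a[!cap]
    r[!cap] <- tac$c * sin(ac) + sqrt(tac$c^2 * sin(ac)^2 + tac$R1^2 - tac$c^2)
  }
  r
}

#' Closed boundary curve of a pole-indented tactoid
#'
#' Samples the four-arc outline at equally spaced polar angles. The curve is
#' mirror-symmetric about both axes; the cap arcs are the concave sectors at
#' `|phi| < phi_j` around each pole direction.
#'
#' @param L0,R0,r0 Tactoid parameters (um), see [tactoid()].
#' @param n_points Number of boundary samples (>= 16).
#' @return A tibble with columns `phi` (rad, in `(-pi, pi]`), `radius` (um),
#'   `x`, `y` (um) and `sector` (`"convex"` or `"cap"`).
#' @export
make_tactoid_boundary <- function(L0, R0, r0, n_points = 360L) {
  if (n_points < 16L) abort("n_points must be >= 16")
  tac <- if (inherits(L0, "tactoid")) L0 else tactoid(L0, R0, r0)
  phi <- seq(-pi, pi, length.out = n_points + 1L)[-1L]
  rad <- tactoid_radius(tac, phi)
  af <- abs(wrap_pi(phi)); af <- pmin(af, pi - af)
  tibble(
    phi = phi, radius = rad,
    x = rad * cos(phi), y = rad * sin(phi),
    sector = ifelse(af <= tac$phi_j, "cap", "convex")
  )
}

# Outer silhouette radius of the revolved tactoid at axial position x (um).
# Zero outside |x| <= L0.
tactoid_outer_radius <- function(tac, x) {
  y2 <- tac$R1^2 - x^2
  out <- ifelse(abs(x) <= tac$L0 & y2 > 0, tac$c + sqrt(pmax(y2, 0)), 0)
  pmax(out, 0)
}

# Radius of the polar indentation ball cross-section at axial position x.
tactoid_cap_radius <- function(tac, x) {
  sqrt(pmax(tac$r0^2 - (abs(x) - tac$L0)^2, 0))
}

# Cross-sectional *material* area of the revolved, pole-indented tactoid at x.
tactoid_section_area <- function(tac, x) {
  ro <- tactoid_outer_radius(tac, x)
  ri <- pmin(tactoid_cap_radius(tac, x), ro)
  pi * (ro^2 - ri^2)
}

#' Volume of the revolved pole-indented tactoid
#'
#' Integrates the material cross-section area along the spindle axis
#' (quadrature, not a pixel sum), so it can serve as an independent reference
#' for rendered images.
#'
#' @param tac A [tactoid()].
#' @return Volume (um^3).
#' @export
tactoid_volume <- function(tac) {
  stats::integrate(function(x) tactoid_section_area(tac, x),
                   -tac$L0, tac$L0, rel.tol = 1e-9, subdivisions = 500L)$value
}

# Point-in-solid test for the revolved tactoid (y here is the in-plane
# transverse coordinate, rp the full transverse radius sqrt(y^2 + z^2)).
tactoid_contains <- function(tac, x, rp) {
  ro <- tactoid_outer_radius(tac, x)
  rp <= ro & (abs(x) - tac$L0)^2 + rp^2 >= tac$r0^2
}
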