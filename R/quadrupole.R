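# Two-dimensional defect-quadrupole model of a nematic void.
#
# A void of length beta and width D in an otherwise uniform director field
# (far-field along x) is represented by four half-integer topological
# defects on the x axis: -1/2 at (+-beta/2, 0) and +1/2 at (+-p, 0) with
# 0 < p < beta/2. In the one-constant Frank approximation each defect's
# angle contribution k_i * arg(z - z_i) is harmonic, so the superposition
# solves the bulk Euler-Lagrange equation; the void boundary is the
# director integral curve (separatrix) through the -1/2 defects, and p is
# chosen so that the traced lens has width D.

#' Director field of a set of point defects
#'
#' `theta(x, y) = theta_inf + sum_i k_i * arg(z - z_i)`; the winding of
#' theta around a loop enclosing only defect i is `2 pi k_i`.
#'
#' @param defects Tibble/data frame with columns `x`, `y`, `k` (charges,
#'   half-integer multiples).
#' @param x,y Query coordinates (recycled).
#' @param theta_inf Far-field angle (rad).
#' @return Director angles (rad, not reduced: windings are meaningful).
#' @export
director_from_defects <- function(defects, x, y, theta_inf = 0) {
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  th <- rep(theta_inf, n)
  for (i in seq_len(nrow(defects))) {
    dx <- x - defects$x[i]; dy <- y - defects$y[i]
    if (any(dx == 0 & dy == 0)) {
      abort("evaluation at a defect core", class = "nemspindle_singular_point")
    }
    th <- th + defects$k[i] * atan2(dy, dx)
  }
  th
}

#' Defect positions of a single void quadrupole
#'
#' @param beta Void length (um).
#' @param p Inner (+1/2) defect half-spacing (um), `0 < p < beta/2`.
#' @param center Void center (length 2).
#' @return Tibble with `x`, `y`, `k`.
#' @export
quadrupole_defects <- function(beta, p, center = c(0, 0)) {
  if (!(p > 0 && p < beta / 2)) abort("require 0 < p < beta/2",
                                      class = "nemspindle_invalid_geometry")
  tibble(x = center[1] + c(-beta / 2, -p, p, beta / 2),
         y = rep(center[2], 4),
         k = c(-0.5, 0.5, 0.5, -0.5))
}

#' Trace the void boundary separatrix
#'
#' Integrates the unit director line field from the -1/2 defect at
#' `(-beta/2, 0)` along its upper separatrix branch (which leaves the core
#' at 60 degrees from the axis) until it returns to the axis, which by
#' symmetry must happen at the opposite defect `(+beta/2, 0)`.
#'
#' @param beta,p Quadrupole geometry, see [quadrupole_defects()].
#' @param step Integration step (um); default `beta/400`.
#' @param closure_tol Maximum distance from the endpoint to the target
#'   defect, as a fraction of beta.
#' @return Tibble with the traced upper branch (`x`, `y`), with attributes
#'   `width` (lens full width `D = 2 max y`) and `closure` (endpoint error,
#'   um).
#' @export
trace_void_boundary <- function(beta, p, step = beta / 800,
                                closure_tol = 0.01) {
  defects <- quadrupole_defects(beta, p)
  start_dir <- pi / 3                    # separatrix branch angle at a -1/2 core
  pos <- c(-beta / 2, 0) + 2 * step * c(cos(start_dir), sin(start_dir))
  dir_prev <- c(cos(start_dir), sin(start_dir))
  field_dir <- function(pt, ref) {
    th <- director_from_defects(defects, pt[1], pt[2])
    v <- c(cos(th), sin(th))
    if (sum(v * ref) < 0) v <- -v       # line field: keep orientation continuity
    v
  }
  xs <- numeric(0); ys <- numeric(0)
  max_steps <- ceiling(20 * beta / step)
  done <- FALSE
  for (it in seq_len(max_steps)) {
    xs <- c(xs, pos[1]); ys <- c(ys, pos[2])
    k1 <- field_dir(pos, dir_prev)
    k2 <- field_dir(pos + step / 2 * k1, k1)
    k3 <- field_dir(pos + step / 2 * k2, k2)
    k4 <- field_dir(pos + step * k3, k3)
    stepv <- (k1 + 2 * k2 + 2 * k3 + k4) / 6
    pos_new <- pos + step * stepv
    if (pos_new[1] >= beta / 2) {
      # reached the abscissa of the opposite defect: interpolate to it.
      # (forward shooting along a separatrix is unstable, so the branch is
      # terminated here; the distance to the defect is the closure error)
      f <- (beta / 2 - pos[1]) / (pos_new[1] - pos[1])
      pos <- pos + f * (pos_new - pos)
      xs <- c(xs, pos[1]); ys <- c(ys, pos[2])
      done <- TRUE
      break
    }
    if (pos_new[2] <= 0 && pos[1] > 0) {
      f <- pos[2] / (pos[2] - pos_new[2])
      pos <- pos + f * (pos_new - pos)
      xs <- c(xs, pos[1]); ys <- c(ys, pos[2])
      done <- TRUE
      break
    }
    dir_prev <- stepv / sqrt(sum(stepv^2))
    pos <- pos_new
  }
  if (!done) {
    abort("streamline did not return to the axis", class = "nemspindle_tracing_error")
  }
  closure <- sqrt(sum((pos - c(beta / 2, 0))^2))
  if (closure > closure_tol * beta) {
    abort(sprintf("streamline does not close onto the opposite defect (error %.3g um)",
                  closure),
          class = "nemspindle_tracing_error")
  }
  # the lens is mirror-symmetric about both axes; close the curve with the
  # reflected lower branch
  out <- tibble(x = c(xs, rev(xs)), y = c(ys, -rev(ys)))
  attr(out, "width") <- 2 * max(ys)
  attr(out, "closure") <- closure
  out
}

#' Solve the quadrupole geometry for a void of given length and width
#'
#' Finds the inner defect half-spacing `p` such that the traced separatrix
#' lens through the -1/2 defects has width `D`. The width decreases
#' monotonically in `p` (as `p -> beta/2` each +-1/2 pair annihilates and
#' the deformation vanishes), so bisection on `p` is well posed.
#'
#' @param beta Void length (um).
#' @param D Void width (um), `0 < D < beta`.
#' @param tol Relative tolerance on `p`.
#' @return List of class `"defect_quadrupole"`: `beta`, `D`, `p`,
#'   `defects` (tibble), `boundary` (traced curve).
#' @export
solve_geometry <- function(beta, D, tol = 1e-6) {
  if (!(D > 0 && D < beta)) abort("require 0 < D < beta",
                                  class = "nemspindle_geometry_infeasible")
  width_of <- function(p) attr(trace_void_boundary(beta, p), "width")
  lo <- 0.02 * beta / 2; hi <- 0.995 * beta / 2
  w_lo <- width_of(lo); w_hi <- width_of(hi)
  if (D > w_lo || D < w_hi) {
    abort(sprintf("no inner spacing in (0, beta/2) achieves width %.3g (range %.3g..%.3g)",
                  D, w_hi, w_lo),
          class = "nemspindle_geometry_infeasible")
  }
  root <- stats::uniroot(function(p) width_of(p) - D, c(lo, hi),
                         tol = tol * beta)
  p <- root$root
  structure(list(beta = beta, D = D, p = p,
                 defects = quadrupole_defects(beta, p),
                 boundary = trace_void_boundary(beta, p)),
            class = "defect_quadrupole")
}

#' @export
print.defect_quadrupole <- function(x, ...) {
  cat(sprintf("Defect quadrupole: beta = %.3g um, D = %.3g um, p = %.4g um\n",
              x$beta, x$D, x$p))
  invisible(x)
}

#' Deformation-induced interaction of two parallel voids
#'
#' For two identical, director-aligned quadrupoles whose centers are offset
#' by `d` perpendicular to the far-field director, the interaction energy in
#' units of the Frank constant is the charge-neutral cross-pair sum
#' `U_int(d)/k = -2 pi * sum_{i in A, j in B} k_i k_j ln |r_i - r_j|`
#' (well defined and system-size independent because each cluster is
#' neutral). It is repulsive at all separations and decays as `d^-4` in the
#' far field, the 2D aligned-quadrupole law.
#'
#' @param quad A [solve_geometry()] result (or any list with `defects`).
#' @param d_values Center-to-center distances (um); must exceed the void
#'   width `D` (non-overlapping voids).
#' @return Tibble of class `"interaction_curve"` with `d` and `U` (energy /
#'   Frank constant).
#' @export
interaction_potential <- function(quad, d_values) {
  D <- if (!is.null(quad$D)) quad$D else 0
  if (any(d_values <= D)) {
    abort("separations must exceed the void width (non-overlapping voids)",
          class = "nemspindle_overlap_error")
  }
  A <- quad$defects
  U <- vapply(d_values, function(d) {
    B <- A
    B$y <- B$y + d
    s <- 0
    for (i in seq_len(nrow(A))) {
      r <- sqrt((A$x[i] - B$x)^2 + (A$y[i] - B$y)^2)
      s <- s + sum(A$k[i] * B$k * log(r))
    }
    -2 * pi * s
  }, numeric(1))
  out <- tibble(d = d_values, U = U)
  class(out) <- c("interaction_curve", class(out))
  out
}

#' Far-field power-law exponent of the void-void interaction
#'
#' Log-log slope of `U_int(d)` over a far-field range of `d / beta`.
#'
#' @param quad A [solve_geometry()] result.
#' @param range `d/beta` interval for the fit.
#' @param n Number of sample points (log-spaced).
#' @return One-row tibble: `slope` and `r_squared`.
#' @export
interaction_exponent <- function(quad, range = c(5, 50), n = 40L) {
  d <- quad$beta * exp(seq(log(range[1]), log(range[2]), length.out = n))
  cur <- interaction_potential(quad, d)
  fit <- lm(log(cur$U) ~ log(cur$d))
  tibble(slope = unname(coef(fit)[2]),
         r_squared = summary(fit)$r.squared)
}
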