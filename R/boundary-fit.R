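# Spindle boundary extraction and pole-indented tactoid fitting.

#' Extract the spindle boundary from a time-averaged retardance image
#'
#' Subtracts the background (median of the four 5x5-pixel corners), applies
#' a Gaussian blur, and locates, for each polar-angle bin around the image
#' center, the radius of maximum gradient magnitude along the ray.
#'
#' @param mean_ret Time-averaged retardance image (matrix, nm).
#' @param pixel_size Pixel size (um).
#' @param blur_um Gaussian blur scale (um).
#' @param n_phi Number of polar-angle bins.
#' @param center Spindle center in um on the grid; defaults to the
#'   brightness centroid.
#' @param min_contrast_frac A ray's gradient maximum must exceed this
#'   fraction of the global maximum to count; more than 10% failing rays is
#'   a low-contrast error.
#' @return A tibble of class `"boundary_curve"` with columns `phi` (rad) and
#'   `radius` (um), plus attributes `center` and `pixel_size`.
#' @export
extract_boundary <- function(mean_ret, pixel_size, blur_um = 1.0,
                             n_phi = 360L, center = NULL,
                             min_contrast_frac = 0.1) {
  ny <- nrow(mean_ret); nx <- ncol(mean_ret)
  corners <- c(mean_ret[1:5, 1:5], mean_ret[1:5, (nx - 4):nx],
               mean_ret[(ny - 4):ny, 1:5], mean_ret[(ny - 4):ny, (nx - 4):nx])
  img <- mean_ret - median(corners)
  img <- gaussian_blur(img, blur_um / pixel_size)
  gm <- gradient_mag(img)
  if (is.null(center)) {
    w <- pmax(img, 0)
    if (sum(w) <= 0) abort("image has no signal above background",
                           class = "nemspindle_low_contrast")
    jj <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
    ii <- matrix(seq_len(ny), ny, nx)
    center <- c(sum(jj * w) / sum(w), sum(ii * w) / sum(w)) * pixel_size -
      0.5 * pixel_size
  }
  ctr_px <- center / pixel_size + 0.5     # fractional pixel indices
  phi <- seq(-pi, pi, length.out = n_phi + 1L)[-1L]
  gmax <- max(gm)
  radius <- rep(NA_real_, n_phi)
  ray_limit <- function(cs, sn) {
    tx <- if (cs > 0) (nx - 1 - ctr_px[1]) / cs else if (cs < 0) (2 - ctr_px[1]) / cs else Inf
    ty <- if (sn > 0) (ny - 1 - ctr_px[2]) / sn else if (sn < 0) (2 - ctr_px[2]) / sn else Inf
    min(tx, ty) - 1
  }
  for (k in seq_len(n_phi)) {
    cs <- cos(phi[k]); sn <- sin(phi[k])
    rs <- seq(1, max(2, ray_limit(cs, sn)), by = 0.5)
    cols <- ctr_px[1] + rs * cs
    rows <- ctr_px[2] + rs * sn
    prof <- bilinear_sample(gm, cols, rows, fill = 0)
    pk <- which.max(prof)
    if (length(pk) && prof[pk] > min_contrast_frac * gmax) {
      # parabolic refinement along the ray
      off <- 0
      if (pk > 1 && pk < length(prof)) {
        den <- prof[pk - 1] - 2 * prof[pk] + prof[pk + 1]
        if (abs(den) > 1e-12) off <- 0.5 * (prof[pk - 1] - prof[pk + 1]) / den
      }
      radius[k] <- (rs[pk] + off * 0.5) * pixel_size
    }
  }
  if (mean(is.na(radius)) > 0.10) {
    abort("no gradient maximum above the noise floor in more than 10% of angle bins",
          class = "nemspindle_low_contrast")
  }
  out <- tibble(phi = phi[!is.na(radius)], radius = radius[!is.na(radius)])
  attr(out, "center") <- center
  attr(out, "pixel_size") <- pixel_size
  class(out) <- c("boundary_curve", class(out))
  out
}

#' Fit a pole-indented tactoid to a boundary curve
#'
#' Nested deterministic optimization: for a candidate virtual-pole
#' half-spacing `L0`, boundary points are assigned to the convex or cap arcs
#' (initially caps are within `cap_init_deg` of each pole direction), the
#' convex circle (constrained through `(+-L0, 0)` with center on the y-axis)
#' and cap radius are fitted by least squares, and the assignment is
#' iterated to convergence; an outer 1D search minimizes the total squared
#' radial residual over `L0`.
#'
#' @param boundary A [extract_boundary()] result, or any data frame with
#'   `phi` (rad) and `radius` (um) columns.
#' @param symmetric Enforce full mirror symmetry (both caps share one `r0`,
#'   both convex arcs one center); the asymmetric alternative is not
#'   implemented.
#' @param cap_init_deg Initial cap half-sector (degrees).
#' @param max_iter Maximum assignment iterations per `L0` candidate.
#' @return An object of class `"tactoid_fit"`: the fitted [tactoid()] in
#'   `$tac`, `L0`, `R0`, `r0` (um), `rms` residual (um), `degenerate` flag
#'   (cap indistinguishable from the convex arc, as for a circular
#'   boundary), and the point assignment.
#' @export
fit_tactoid <- function(boundary, symmetric = TRUE, cap_init_deg = 25,
                        max_iter = 50L) {
  phi <- boundary$phi; rad <- boundary$radius
  x <- rad * cos(phi); y <- rad * sin(phi)
  rng <- range(rad)
  if (!symmetric) abort("only the fully mirror-symmetric fit is implemented")

  eval_L0 <- function(L0) {
    af <- abs(wrap_pi(phi)); af <- pmin(af, pi - af)
    is_cap <- af < cap_init_deg * pi / 180
    fit_band <- !is_cap & af > 30 * pi / 180   # clearly-equatorial points
    for (it in seq_len(max_iter)) {
      # convex circle through (+-L0, 0), center (0, c): solve for c by LS on
      # the radial residual |P - (0, +-c)| - sqrt(L0^2 + c^2), mirror-folded
      conv_res_fun <- function(cc) {
        R1 <- sqrt(L0^2 + cc^2)
        sqrt(x^2 + (abs(y) - cc)^2) - R1
      }
      conv_sel <- if (it == 1L && sum(fit_band) >= 8L) fit_band else !is_cap
      obj_c <- function(cc) sum(conv_res_fun(cc)[conv_sel]^2)
      cmax <- max(rng[2], L0)
      copt <- optimize(obj_c, interval = c(-10 * cmax, min(rng[2], L0) - 1e-9))$minimum
      # cap circles centered (+-L0, 0); shared LS radius = mean distance.
      # On the first pass the cap set is a guess that may include convex
      # points, which lie strictly farther from the pole than the cap arc:
      # seed the radius from the innermost pole distances instead.
      dcap <- sqrt((abs(x) - L0)^2 + y^2)
      r0 <- if (!any(is_cap)) {
        NA_real_
      } else if (it == 1L) {
        unname(quantile(dcap[af < pi / 4], 0.05))
      } else {
        mean(dcap[is_cap])
      }
      res_conv <- conv_res_fun(copt)
      res_cap <- dcap - ifelse(is.na(r0), Inf, r0)
      new_cap <- abs(res_cap) < abs(res_conv)
      if (all(new_cap == is_cap)) break
      is_cap <- new_cap
      if (!any(is_cap) || all(is_cap)) break
    }
    res <- ifelse(is_cap, res_cap, res_conv)
    list(ss = sum(res^2), c = copt, r0 = r0, is_cap = is_cap,
         converged = it < max_iter)
  }

  # the loss is not unimodal in L0 once sector re-assignment kicks in:
  # coarse grid scan first, then a local refinement around the best cell
  span <- max(abs(x))
  grid <- span * exp(seq(log(1.002), log(4), length.out = 60L))
  ss_grid <- vapply(grid, function(L0) eval_L0(L0)$ss, numeric(1))
  k <- which.min(ss_grid)
  lo <- grid[max(1L, k - 1L)]; hi <- grid[min(length(grid), k + 1L)]
  opt <- optimize(function(L0) eval_L0(L0)$ss,
                  interval = c(lo, hi), tol = span * 1e-7)
  L0 <- opt$minimum
  fit <- eval_L0(L0)
  if (!fit$converged) abort("sector assignment did not converge",
                            class = "nemspindle_fit_failure")
  R0 <- fit$c + sqrt(L0^2 + fit$c^2)
  r0 <- fit$r0
  degenerate <- !any(fit$is_cap) || is.na(r0) || r0 > 0.95 * L0 ||
    r0 < 0.02 * L0 || sum(fit$is_cap) < max(3, 0.03 * length(phi))
  rms <- sqrt(fit$ss / length(phi))
  tac <- if (!degenerate) {
    tryCatch(tactoid(L0, R0, r0), error = function(e) NULL)
  } else NULL
  if (is.null(tac)) degenerate <- TRUE
  structure(list(tac = tac, L0 = L0, R0 = R0, r0 = r0, rms = rms,
                 degenerate = degenerate, is_cap = fit$is_cap,
                 n_points = length(phi)),
            class = "tactoid_fit")
}

#' @export
print.tactoid_fit <- function(x, ...) {
  cat(sprintf("Tactoid fit: L0 = %.3f, R0 = %.3f, r0 = %.3f um (rms %.4f um)%s\n",
              x$L0, x$R0, x$r0, x$rms,
              if (x$degenerate) " [degenerate: no distinct polar caps]" else ""))
  invisible(x)
}

#' @export
tidy.tactoid_fit <- function(x, ...) {
  tibble(term = c("L0", "R0", "r0"),
         estimate = c(x$L0, x$R0, x$r0),
         unit = "um")
}

#' @export
glance.tactoid_fit <- function(x, ...) {
  tibble(L0 = x$L0, R0 = x$R0, r0 = x$r0, rms = x$rms,
         R0_over_L0 = x$R0 / x$L0, r0_over_L0 = x$r0 / x$L0,
         degenerate = x$degenerate, n_points = x$n_points)
}

#' Pool tactoid fits across spindles
#'
#' Rescales each spindle's belt half-width and cap radius by its own
#' virtual-pole half-spacing and averages the dimensionless shape across
#' spindles (the normalized tactoid has `L0 = 1` by construction).
#'
#' @param fits List of `"tactoid_fit"` objects (or a single one).
#' @return A tibble with one row per shape ratio (`R0_over_L0`,
#'   `r0_over_L0`): `mean`, `se` (NA for a single fit) and `n`.
#' @export
pool_tactoids <- function(fits) {
  if (inherits(fits, "tactoid_fit")) fits <- list(fits)
  r0l <- vapply(fits, function(f) f$r0 / f$L0, numeric(1))
  R0l <- vapply(fits, function(f) f$R0 / f$L0, numeric(1))
  n <- length(fits)
  se <- function(v) if (n < 2) NA_real_ else sd(v) / sqrt(n)
  tibble(ratio = c("R0_over_L0", "r0_over_L0"),
         mean = c(mean(R0l), mean(r0l)),
         se = c(se(R0l), se(r0l)),
         n = n)
}

#' Fit simple reference shapes to a boundary curve
#'
#' Axis-aligned ellipse and rectangle fits used only as baselines when
#' comparing boundary models; the pole-indented tactoid should beat both on
#' spindle-shaped boundaries.
#'
#' @param boundary As in [fit_tactoid()].
#' @return Tibble with `model` and `rms` (um) for `ellipse` and `rectangle`.
#' @export
fit_reference_shapes <- function(boundary) {
  phi <- boundary$phi; rad <- boundary$radius
  ellipse_rms <- function(par) {
    a <- par[1]; b <- par[2]
    pred <- a * b / sqrt((b * cos(phi))^2 + (a * sin(phi))^2)
    sqrt(mean((rad - pred)^2))
  }
  rect_rms <- function(par) {
    hw <- par[1]; hh <- par[2]
    pred <- pmin(hw / pmax(abs(cos(phi)), 1e-12), hh / pmax(abs(sin(phi)), 1e-12))
    sqrt(mean((rad - pred)^2))
  }
  init <- c(max(rad), min(rad))
  e <- optim(init, ellipse_rms)$value
  r <- optim(init, rect_rms)$value
  tibble(model = c("ellipse", "rectangle"), rms = c(e, r))
}
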