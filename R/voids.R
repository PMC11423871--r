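# Inversion of time-averaged retardance into microtubule cross-sectional
# density and the average void shape along the spindle axis.
#
# For a cylindrically symmetric density distribution the retardance profile
# across the spindle at axial position x is
#   r_pred(x, y) = 2 A0 rho_x(x) sqrt(R(x)^2 - y^2)   (x 1e-3 for nm units),
# so each image column yields a local density rho_x and radius R by least
# squares. Density missing from the central spindle relative to the poles is
# attributed to chromosome-associated voids.

#' Fit semicircular cross-section profiles column by column
#'
#' @param mean_ret Registered, time-averaged retardance image (matrix, nm).
#' @param pixel_size Pixel size (um).
#' @param A0 Per-microtubule retardance constant (nm^2).
#' @param min_pixels Columns with fewer valid (above-threshold) pixels are
#'   skipped and flagged.
#' @param threshold Retardance floor (nm) defining valid pixels.
#' @param center Spindle center (um); defaults to the image center.
#' @param R_mode How the local radius is estimated: `"support"` (default)
#'   takes the half-extent of above-threshold pixels and computes the
#'   density from the exact area integral `int r dy / (1e-3 A0 pi R^2)` —
#'   unbiased even when voids deplete the chord interior; `"free"` fits
#'   `(rho, R)` jointly by least squares to the semicircular profile (the
#'   joint fit trades density against radius when voids are present).
#' @return Object of class `"density_profile"`: a tibble with columns `x`
#'   (um), `rho` (um^-2), `rho_rel` (normalized to the near-pole reference),
#'   `R` (um), `rms` (nm) and `ok`, plus the normalization reference
#'   `rho_ref` as an attribute.
#' @export
fit_cross_sections <- function(mean_ret, pixel_size, A0 = 7.5,
                               min_pixels = 5L, threshold = NULL,
                               center = NULL, R_mode = c("support", "free")) {
  R_mode <- match.arg(R_mode)
  ny <- nrow(mean_ret); nx <- ncol(mean_ret)
  g <- pixel_grid(nx, ny, pixel_size, center)
  if (is.null(threshold)) threshold <- 0.05 * max(mean_ret)
  rows_y <- g$ys
  fit_col <- function(j) {
    r <- mean_ret[, j]
    ok <- r > threshold
    if (any(ok)) {
      # keep only the contiguous above-threshold run around the brightest
      # pixel; isolated noise pixels must not stretch the support
      pk <- which.max(r)
      hi <- pk; while (hi < length(r) && r[hi + 1] > threshold) hi <- hi + 1L
      lo <- pk; while (lo > 1 && r[lo - 1] > threshold) lo <- lo - 1L
      run <- logical(length(r)); run[lo:hi] <- TRUE
      ok <- ok & run
    }
    if (sum(ok) < min_pixels) {
      return(c(rho = NA_real_, R = NA_real_, rms = NA_real_, n = sum(ok)))
    }
    y <- rows_y[ok]; robs <- r[ok]
    ymax <- max(abs(y)) + pixel_size
    ls_amp <- function(R) {
      pred_shape <- sqrt(pmax(R^2 - y^2, 0))
      denom <- sum(pred_shape^2)
      if (denom == 0) return(list(ss = Inf, amp = 0))
      amp <- sum(robs * pred_shape) / denom      # linear LS in the amplitude
      list(ss = sum((robs - amp * pred_shape)^2), amp = amp)
    }
    if (R_mode == "support") {
      # Sub-pixel support: the semicircular chord satisfies
      # r^2 = C (R^2 - y^2), so two near-edge samples extrapolate the zero
      # crossing exactly, independent of where R falls within a pixel.
      zero_cross <- function(side) {
        idx <- which(ok)
        edge <- if (side > 0) max(idx) else min(idx)
        i1 <- edge - 2L * side; i2 <- edge - 5L * side
        fallback <- abs(rows_y[edge]) + 0.5 * pixel_size
        if (i2 < 1 || i2 > length(r) || !all(ok[c(i1, i2)])) return(fallback)
        y1 <- rows_y[i1]; y2 <- rows_y[i2]
        C <- (r[i1]^2 - r[i2]^2) / (y2^2 - y1^2)
        if (!is.finite(C) || C <= 0) return(fallback)
        R2 <- y1^2 + r[i1]^2 / C
        if (R2 <= y1^2) fallback else sqrt(R2)
      }
      R <- (zero_cross(1L) + zero_cross(-1L)) / 2
      rho <- sum(r) * pixel_size /
        (1e-3 * A0 * pi * R^2)                   # exact area attribution
      ss <- ls_amp(R)
      c(rho = rho, R = R, rms = sqrt(ss$ss / length(y)), n = sum(ok))
    } else {
      op <- optimize(function(R) ls_amp(R)$ss, interval = c(ymax * 0.5, ymax * 3),
                     tol = 1e-6 * ymax)
      best <- ls_amp(op$minimum)
      rho <- best$amp / (2 * A0 * 1e-3)          # amp = 2 A0 rho * 1e-3
      c(rho = rho, R = op$minimum, rms = sqrt(best$ss / length(y)), n = sum(ok))
    }
  }
  res <- t(vapply(seq_len(nx), fit_col, numeric(4)))
  out <- tibble(x = g$xs, rho = res[, "rho"], R = res[, "R"],
                rms = res[, "rms"], n = res[, "n"], ok = !is.na(res[, "rho"]))
  # normalization reference: robust high quantile of rho over columns with
  # well-developed cross sections (the near-pole, void-free region); stubby
  # tip columns with unreliable radii are excluded
  cand <- out$ok & out$R >= 0.5 * max(out$R, na.rm = TRUE)
  rr <- out$rho[cand]
  if (length(rr) < 4) rr <- out$rho[out$ok]
  rho_ref <- median(rr[rr >= quantile(rr, 0.75)])
  out$rho_rel <- pmin(out$rho / rho_ref, 1)
  attr(out, "rho_ref") <- rho_ref
  class(out) <- c("density_profile", class(out))
  out
}

# Central attribution window: deficits are counted only between the inner
# edges of the void-free reference shoulders (near-pole columns at the
# normalization level); outside it the annular polar-cap cross-sections
# would masquerade as voids.
central_window <- function(profile, ref_level = 0.97) {
  p <- profile[profile$ok, ]
  ref <- p$x[p$rho_rel >= ref_level]
  lo <- suppressWarnings(max(ref[ref < 0]))
  hi <- suppressWarnings(min(ref[ref > 0]))
  if (!is.finite(lo)) lo <- min(p$x)
  if (!is.finite(hi)) hi <- max(p$x)
  c(lo, hi)
}

#' Void volume and plate-area fractions
#'
#' Attributes all density missing relative to the near-pole reference to
#' voids: the plate-area fraction is `1 - rho_rel(0)` and the volume
#' fraction weights the missing density by the local cross-section area.
#'
#' @param profile A [fit_cross_sections()] result (must carry the
#'   normalized `rho_rel` column).
#' @param x_window Half-width (um) of the central window used for the
#'   plate value (averaged for robustness to single-column noise).
#' @return One-row tibble: `volume_fraction`, `plate_area_fraction`.
#' @export
void_fractions <- function(profile, x_window = 0.5) {
  if (!"rho_rel" %in% names(profile)) {
    abort("profile is not normalized (no rho_rel column)")
  }
  p <- profile[profile$ok, ]
  centr <- abs(p$x) <= x_window
  if (!any(centr)) centr <- rank(abs(p$x)) <= 2
  plate <- 1 - mean(p$rho_rel[centr])
  win <- central_window(profile)
  deficit <- ifelse(p$x >= win[1] & p$x <= win[2], 1 - p$rho_rel, 0)
  w <- pi * p$R^2
  vol <- sum(deficit * w) / sum(w)
  tibble(volume_fraction = vol, plate_area_fraction = plate)
}

# circle-arc width profile with waist w (full width at x = 0) and chord
# beta: d(x) = 2 [ sqrt(rc^2 - x^2) - (rc - w/2) ], rc = beta^2/(8 (w/2)) + w/4
arc_width <- function(x, waist, beta) {
  h <- waist / 2
  rc <- beta^2 / (8 * h) + h / 2
  d <- 2 * (sqrt(pmax(rc^2 - x^2, 0)) - (rc - h))
  d[abs(x) > beta / 2] <- 0
  pmax(d, 0)
}

#' Average void width profile along the spindle axis
#'
#' Distributes the missing cross-section area equally over `n_chr` identical
#' voids, converts it to an effective per-void diameter
#' `d_void(x) = 2 sqrt(A_void(x) / pi)`, and fits a circle-arc width profile
#' parameterized by the waist diameter and chord length `beta`.
#'
#' @param profile A [fit_cross_sections()] result.
#' @param n_chr Number of voids assumed (one per chromosome).
#' @return Object of class `"void_shape"`: one-row tibble with `waist` (um),
#'   `beta` (um) and `rms` (um), plus the `d_void(x)` samples as attribute
#'   `profile`.
#' @export
void_width_profile <- function(profile, n_chr = 20) {
  p <- profile[profile$ok & is.finite(profile$R), ]
  miss <- 1 - p$rho_rel
  if (any(miss < 0)) {
    warn("negative missing area clipped to zero")
    miss <- pmax(miss, 0)
  }
  win <- central_window(profile)
  miss[p$x < win[1] | p$x > win[2]] <- 0
  a_void <- miss * pi * p$R^2 / n_chr
  d_void <- 2 * sqrt(a_void / pi)
  obj <- function(par) {
    sum((d_void - arc_width(p$x, par[1], par[2]))^2)
  }
  init <- c(max(d_void), max(4 * max(d_void), diff(range(p$x)) * 0.6))
  op <- optim(init, obj, method = "L-BFGS-B",
              lower = c(1e-3, 1e-2), upper = c(Inf, Inf))
  samples <- tibble(x = p$x, d_void = d_void,
                    d_fit = arc_width(p$x, op$par[1], op$par[2]))
  out <- tibble(waist = op$par[1], beta = op$par[2],
                rms = sqrt(op$value / nrow(p)))
  attr(out, "profile") <- samples
  class(out) <- c("void_shape", class(out))
  out
}
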