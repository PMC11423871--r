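# Metaphase-plate analysis: reslicing confocal stacks onto the plate plane,
# chromosome segmentation, ellipse approximation, and the edge-corrected
# pair correlation g_II(s) with bootstrap extrema.

#' Reslice a two-channel confocal stack onto the metaphase plate
#'
#' Finds the best-fit plane to the chromosome channel via intensity-weighted
#' principal axes (the plane normal is the largest-variance axis of a
#' plate-like distribution... the normal is taken as the *smallest*-variance
#' direction of the chromosome intensity, which is concentrated in a thin
#' slab) and resamples both channels on that plane through the intensity
#' centroid (trilinear interpolation).
#'
#' @param stack List with `chromosomes` and `microtubules` (3D arrays,
#'   index order `[y, z, x]` with x the stack axis) and `voxel_size`
#'   (length-3, um, in the same order).
#' @param out_pixel Pixel size of the resliced plate image (um); defaults
#'   to the finest voxel dimension.
#' @param half_width Half-width (um) of the output image.
#' @return List of class `"plate_image"`: `chromosomes`, `microtubules`
#'   (matrices), `pixel_size`, `normal` (unit vector in the input frame).
#' @export
reslice_to_plate <- function(stack, out_pixel = NULL, half_width = NULL) {
  ch <- stack$chromosomes
  vs <- stack$voxel_size
  w <- as.vector(ch)
  if (sum(w) <= 0) abort("chromosome channel is empty",
                         class = "nemspindle_orientation_undefined")
  d <- dim(ch)
  coords <- cbind(
    y = (as.vector(slice.index(ch, 1)) - 0.5) * vs[1],
    z = (as.vector(slice.index(ch, 2)) - 0.5) * vs[2],
    x = (as.vector(slice.index(ch, 3)) - 0.5) * vs[3]
  )
  mu <- colSums(coords * w) / sum(w)
  cc <- sweep(coords, 2, mu)
  cov <- crossprod(cc * sqrt(w)) / sum(w)
  ev <- eigen(cov, symmetric = TRUE)
  if (ev$values[2] < 1e-9 || ev$values[1] / max(ev$values[2], 1e-300) > 1e6) {
    abort("degenerate intensity distribution; plate orientation undefined",
          class = "nemspindle_orientation_undefined")
  }
  if (ev$values[3] > 0.8 * ev$values[2]) {
    # nearly isotropic in the two smallest directions is fine; a fully
    # isotropic cloud is not
    if (ev$values[3] > 0.8 * ev$values[1]) {
      abort("degenerate intensity distribution; plate orientation undefined",
            class = "nemspindle_orientation_undefined")
    }
  }
  normal <- ev$vectors[, 3]            # smallest variance: the plate normal
  if (normal[3] < 0) normal <- -normal # orient along +x
  e1 <- ev$vectors[, 1]; e2 <- ev$vectors[, 2]
  if (is.null(out_pixel)) out_pixel <- min(vs)
  if (is.null(half_width)) {
    half_width <- 0.5 * max(d * vs)   # cover the whole plate; outside fills 0
  }
  nb <- 2L * ceiling(half_width / out_pixel)
  g <- pixel_grid(nb, nb, out_pixel)
  pts <- sweep(outer(as.vector(g$x), e1) + outer(as.vector(g$y), e2),
               2, mu, "+")
  samp <- function(a) {
    matrix(trilinear_sample(a, pts[, 1] / vs[1] + 0.5, pts[, 2] / vs[2] + 0.5,
                            pts[, 3] / vs[3] + 0.5), nrow = nb)
  }
  structure(list(chromosomes = samp(ch),
                 microtubules = samp(stack$microtubules),
                 pixel_size = out_pixel, normal = normal, center = mu),
            class = "plate_image")
}

# trilinear interpolation into a 3D array at fractional 1-based indices
trilinear_sample <- function(a, i, j, k, fill = 0) {
  d <- dim(a)
  i0 <- floor(i); j0 <- floor(j); k0 <- floor(k)
  fi <- i - i0; fj <- j - j0; fk <- k - k0
  ok <- i0 >= 1 & i0 <= d[1] - 1 & j0 >= 1 & j0 <= d[2] - 1 &
    k0 >= 1 & k0 <= d[3] - 1
  out <- rep(fill, length(i))
  if (!any(ok)) return(out)
  i0 <- i0[ok]; j0 <- j0[ok]; k0 <- k0[ok]
  fi <- fi[ok]; fj <- fj[ok]; fk <- fk[ok]
  at <- function(di, dj, dk) a[cbind(i0 + di, j0 + dj, k0 + dk)]
  v <- at(0, 0, 0) * (1 - fi) * (1 - fj) * (1 - fk) +
    at(1, 0, 0) * fi * (1 - fj) * (1 - fk) +
    at(0, 1, 0) * (1 - fi) * fj * (1 - fk) +
    at(0, 0, 1) * (1 - fi) * (1 - fj) * fk +
    at(1, 1, 0) * fi * fj * (1 - fk) +
    at(1, 0, 1) * fi * (1 - fj) * fk +
    at(0, 1, 1) * (1 - fi) * fj * fk +
    at(1, 1, 1) * fi * fj * fk
  out[ok] <- v
  out
}

#' Segment chromosome sections in a plate image
#'
#' Three-step chain: Gaussian blur, local adaptive binarization, and an
#' erosion with a disk kernel; connected components (4-connectivity) are
#' the chromosome sections. A dataset is acceptable when it shows 19 or 20
#' sections (two chromosomes touching may merge into one component); the
#' decision is returned, never silently applied.
#'
#' @param plate A `"plate_image"` or a chromosome-channel matrix.
#' @param pixel_size Pixel size (um); taken from the plate image if given.
#' @param blur_um Gaussian blur width (um), read as the ~4-sigma full width
#'   (sigma = `blur_um/4`): strong enough to suppress shot noise without
#'   bridging neighbouring chromosomes.
#' @param binarize_um Local binarization radius (um).
#' @param erode_um Erosion disk radius (um).
#' @param boundary Optional 0/1 matrix restricting the plate region. When a
#'   `"plate_image"` with a microtubule channel is supplied it defaults to
#'   the filled outline of that channel (the spindle cross-section);
#'   otherwise to the full frame.
#' @param accept_range Component counts considered acceptable.
#' @return Object of class `"chromosome_plate"`: `mask` (0/1), `labels`
#'   (integer matrix), `n_chr`, `accepted`, `boundary`, `pixel_size`.
#' @export
segment_chromosomes <- function(plate, pixel_size = NULL, blur_um = 2,
                                binarize_um = 1.5, erode_um = 0.4,
                                boundary = NULL, accept_range = c(19L, 20L)) {
  img <- if (inherits(plate, "plate_image")) plate$chromosomes else plate
  if (is.null(pixel_size)) {
    if (!inherits(plate, "plate_image")) abort("pixel_size required")
    pixel_size <- plate$pixel_size
  }
  if (diff(range(img)) < 1e-12) {
    abort("chromosome channel has no contrast", class = "nemspindle_empty_plate")
  }
  if (is.null(boundary) && inherits(plate, "plate_image") &&
      !is.null(plate$microtubules)) {
    boundary <- plate_boundary_mask(plate$microtubules + img, pixel_size)
  }
  b <- gaussian_blur(img, blur_um / 4 / pixel_size)
  m <- local_binarize(b, pixel_size, binarize_um)
  r_px <- max(1L, round(erode_um / pixel_size))
  brush <- EBImage::makeBrush(2L * r_px + 1L, shape = "disc")
  m <- as.matrix(EBImage::erode(m, brush))
  if (!is.null(boundary)) m <- m * boundary
  lab <- label_components(m)
  n_chr <- max(lab)
  if (n_chr == 0L) abort("no chromosome sections found",
                         class = "nemspindle_empty_plate")
  structure(list(mask = (lab > 0) * 1L, labels = lab, n_chr = n_chr,
                 accepted = n_chr >= accept_range[1] & n_chr <= accept_range[2],
                 boundary = boundary, pixel_size = pixel_size),
            class = "chromosome_plate")
}

#' @export
print.chromosome_plate <- function(x, ...) {
  cat(sprintf("Chromosome plate: %d sections (%s)\n", x$n_chr,
              if (x$accepted) "accepted" else "rejected by the 19-20 rule"))
  invisible(x)
}

# Filled outline of the plate cross-section from total (microtubule +
# chromosome) intensity: blur, threshold at half the robust maximum, keep
# the largest component, fill holes.
plate_boundary_mask <- function(total, pixel_size) {
  b <- gaussian_blur(total, 0.5 / pixel_size)
  m <- largest_component((b >= 0.5 * quantile(b, 0.999)) * 1L)
  as.matrix(EBImage::fillHull(m))
}

#' Second-moment ellipse fits of labelled sections
#'
#' Each component is summarized by its area-equivalent second-moment
#' ellipse: full axes `a = 4 sqrt(l1)`, `b = 4 sqrt(l2)` from the eigenvalues
#' of the pixel covariance (exact for a solid ellipse).
#'
#' @param plate A [segment_chromosomes()] result.
#' @param min_pixels Components smaller than this are flagged and excluded
#'   from the summary.
#' @return Object of class `"ellipse_set"`: tibble with per-section
#'   `label`, `cx`, `cy` (um), `a`, `b` (um, full axes), `phi` (rad),
#'   `area` (um^2), `flagged`, `round` (orientation undefined); summary
#'   attribute `summary` = mean a, b over unflagged sections.
#' @export
fit_ellipses <- function(plate, min_pixels = 5L) {
  lab <- plate$labels; px <- plate$pixel_size
  ny <- nrow(lab); nx <- ncol(lab)
  res <- purrr::map_dfr(seq_len(max(lab)), function(k) {
    idx <- which(lab == k)
    n <- length(idx)
    i <- (idx - 1L) %% ny + 1L; j <- (idx - 1L) %/% ny + 1L
    x <- (j - 0.5) * px; y <- (i - 0.5) * px
    if (n < min_pixels) {
      return(tibble(label = k, cx = mean(x), cy = mean(y),
                    a = NA_real_, b = NA_real_, phi = NA_real_,
                    area = n * px^2, flagged = TRUE, round = NA))
    }
    cv <- cov(cbind(x, y)) * (n - 1) / n + diag(2) * px^2 / 12
    ev <- eigen(cv, symmetric = TRUE)
    axes <- 4 * sqrt(pmax(ev$values, 0))
    is_round <- (axes[1] - axes[2]) / axes[1] < 0.05
    tibble(label = k, cx = mean(x), cy = mean(y),
           a = axes[1], b = axes[2],
           phi = if (is_round) NA_real_ else atan2(ev$vectors[2, 1], ev$vectors[1, 1]),
           area = n * px^2, flagged = FALSE, round = is_round)
  })
  good <- !res$flagged
  attr(res, "summary") <- tibble(a = mean(res$a[good]), b = mean(res$b[good]),
                                 area = mean(res$area[good]), n = sum(good))
  class(res) <- c("ellipse_set", class(res))
  res
}

#' Edge-corrected pair correlation of a binary mask
#'
#' `g_II(s)` is the average product of pixel values at separation s,
#' normalized by the squared mean value, with pair counts corrected for the
#' boundary shape by dividing by the boundary-mask pair counts at the same
#' separation. Computed by FFT autocorrelation (exactly equivalent to pair
#' counting) and radially binned.
#'
#' @param mask 0/1 matrix of chromosome pixels.
#' @param boundary 0/1 matrix of plate pixels (the admissible region).
#' @param pixel_size Pixel size (um).
#' @param bin_width Radial bin width (um).
#' @param s_max Largest separation (um); defaults to the boundary diameter.
#' @return Tibble with `s` (bin centers at integer multiples of
#'   `bin_width`) and `gii`.
#' @export
pair_correlation <- function(mask, boundary, pixel_size, bin_width = 0.1,
                             s_max = NULL) {
  if (sum(boundary) == 0) abort("boundary mask is empty")
  I <- mask * boundary
  phi <- sum(I) / sum(boundary)
  ny <- nrow(I); nx <- ncol(I)
  # zero-pad to avoid wrap-around in the circular autocorrelation
  PY <- 2L * ny; PX <- 2L * nx
  pad <- function(m) { out <- matrix(0, PY, PX); out[1:ny, 1:nx] <- m; out }
  acorr <- function(m) {
    F <- fft(pad(m))
    Re(fft(F * Conj(F), inverse = TRUE)) / (PY * PX)
  }
  nII <- acorr(I)
  nBB <- acorr(boundary)
  dxs <- fft_shift_index(PX); dys <- fft_shift_index(PY)
  ss <- sqrt(outer(dys^2, dxs^2, "+")) * pixel_size
  if (is.null(s_max)) s_max <- max(dim(boundary)) * pixel_size
  keep <- ss <= s_max & nBB > 0.5
  bin <- round(ss[keep] / bin_width)
  num <- tapply(nII[keep], bin, sum)
  den <- tapply(nBB[keep], bin, sum)
  s <- as.numeric(names(num)) * bin_width
  dplyr::arrange(tibble(s = s, gii = as.numeric(num / den) / phi^2), .data$s)
}

#' Extrema of averaged pair-correlation curves with bootstrap CIs
#'
#' Averages per-spindle (or per-replicate) g_II curves, lightly smooths the
#' mean (3-point window), and finds the first interior local minimum beyond
#' the near-field shoulder (the first bin where the curve drops below
#' `g(0)/2`) and the following local maximum, both refined by parabolic
#' interpolation. Uncertainty is the SD of the extremum locations over
#' bootstrap resamples of curves.
#'
#' @param curves Tibble with `replicate`, `s`, `gii` (as produced inside
#'   [simulate_ensemble()]), or a list of per-spindle tibbles with `s`,
#'   `gii`.
#' @param n_boot Bootstrap resamples (0 = point estimates only).
#' @param prominence Minimum rise from the minimum to the following maximum
#'   for the pair to count as interior structure (suppresses noise wiggles).
#' @return Tibble with zero rows (no interior extrema: the random-placement
#'   outcome) or one row: `s_min`, `s_min_ci`, `s_max`, `s_max_ci`,
#'   `depth` (g at min), `height` (g at max).
#' @export
gii_extrema <- function(curves, n_boot = 1000L, prominence = 0.05) {
  if (is.data.frame(curves)) {
    if (!"replicate" %in% names(curves)) curves$replicate <- 1L
    mat <- tidyr::pivot_wider(curves, names_from = "s", values_from = "gii",
                              id_cols = "replicate")
    reps <- mat$replicate
    svals <- as.numeric(names(mat)[-1])
    mat <- as.matrix(mat[, -1])
  } else {
    svals <- curves[[1]]$s
    mat <- do.call(rbind, lapply(curves, function(d) d$gii))
  }
  o <- order(svals); svals <- svals[o]; mat <- mat[, o, drop = FALSE]

  locate <- function(g) {
    g <- unname(smooth3(g))
    g0 <- g[1]
    shoulder <- which(g < g0 / 2)[1]
    if (is.na(shoulder)) return(NULL)
    n <- length(g)
    i <- shoulder + 1L
    while (i < n) {
      if (g[i] <= g[i - 1] && g[i] <= g[i + 1]) {
        # candidate minimum; find the following local maximum
        j <- i + 1L
        while (j < n && !(g[j] >= g[j - 1] && g[j] >= g[j + 1])) j <- j + 1L
        if (j < n && g[j] - g[i] >= prominence) {
          return(c(s_min = refine_extremum(svals, g, i),
                   s_max = refine_extremum(svals, g, j),
                   depth = g[i], height = g[j]))
        }
      }
      i <- i + 1L
    }
    NULL
  }
  pt <- locate(colMeans(mat))
  if (is.null(pt)) {
    return(tibble(s_min = numeric(0), s_min_ci = numeric(0),
                  s_max = numeric(0), s_max_ci = numeric(0),
                  depth = numeric(0), height = numeric(0)))
  }
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0 && nrow(mat) > 1) {
    bs <- matrix(NA_real_, n_boot, 2)
    for (bb in seq_len(n_boot)) {
      idx <- sample.int(nrow(mat), replace = TRUE)
      p <- locate(colMeans(mat[idx, , drop = FALSE]))
      if (!is.null(p)) bs[bb, ] <- p[c("s_min", "s_max")]
    }
    ci <- apply(bs, 2, sd, na.rm = TRUE)
  }
  tibble(s_min = pt[["s_min"]], s_min_ci = ci[1],
         s_max = pt[["s_max"]], s_max_ci = ci[2],
         depth = pt[["depth"]], height = pt[["height"]])
}

smooth3 <- function(g) {
  n <- length(g)
  out <- g
  out[2:(n - 1)] <- (g[1:(n - 2)] + g[2:(n - 1)] + g[3:n]) / 3
  out
}

refine_extremum <- function(s, g, i) {
  if (i <= 1 || i >= length(g)) return(s[i])
  den <- g[i - 1] - 2 * g[i] + g[i + 1]
  if (abs(den) < 1e-12) return(s[i])
  off <- 0.5 * (g[i - 1] - g[i + 1]) / den
  s[i] + off * (s[i + 1] - s[i])
}
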