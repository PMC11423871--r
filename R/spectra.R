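# Orientational fluctuation analysis.
#
# Fluctuations delta_n_y are the nematic difference between the registered
# slow axis and the steady-state circle-arc field, identified with the
# transverse director component in the small-angle regime. Correlation
# functions are computed in a centered box of side lambda0:
#   c_nn(q, w) = |FT(delta_n_y)|^2 / (tau0 * lambda0^2)
#   s_nn(q)    = (1/2pi) * integral of c_nn over available frequencies w,
# with mirror padding in all dimensions before the transform and a
# diffraction cutoff removing modes with |q| > 2 pi / lambda_im.

#' Extract orientational fluctuations in a centered box
#'
#' @param reg A `"registered_movie"` (or `"polscope_movie"` already in the
#'   rest frame).
#' @param L0 Virtual-pole half-spacing of the fitted tactoid (um), defining
#'   the steady-state circle-arc reference field.
#' @param lambda0 Box side length (um).
#' @param center Box center (um); defaults to the image center.
#' @param max_mean_angle_deg If the time-averaged angle magnitude exceeds
#'   this anywhere in the box, the small-angle identification of the angle
#'   difference with delta_n_y degrades and a warning is issued.
#' @return Object of class `"fluct_stack"`: `dny` (`n_box x n_box x nt`
#'   array, rad), `pixel_size`, `frame_interval`, `lambda0`, `tau0`.
#' @export
compute_fluctuations <- function(reg, L0, lambda0 = 8, center = NULL,
                                 max_mean_angle_deg = 15) {
  movie <- if (inherits(reg, "registered_movie")) reg$movie else reg
  ang <- movie$slow_axis
  d <- dim(ang); ny <- d[1]; nx <- d[2]; nt <- d[3]
  px <- movie$pixel_size
  if (is.null(center)) center <- c(nx, ny) / 2 * px
  nb <- round(lambda0 / px)
  if (nb < 2) abort("box smaller than 2 pixels")
  j0 <- round(center[1] / px - nb / 2); i0 <- round(center[2] / px - nb / 2)
  if (i0 < 0 || j0 < 0 || i0 + nb > ny || j0 + nb > nx) {
    abort("fluctuation box does not fit inside the movie frame")
  }
  rows <- i0 + seq_len(nb); cols <- j0 + seq_len(nb)
  g <- pixel_grid(nx, ny, px, center = center)
  th_ref <- matrix(theta_arcs(as.vector(g$x), as.vector(g$y), L0), nrow = ny)
  dny <- array(0, dim = c(nb, nb, nt))
  for (t in seq_len(nt)) {
    dny[, , t] <- nematic_diff(ang[rows, cols, t], th_ref[rows, cols])
  }
  tbar <- abs(nematic_mean_field(ang[rows, cols, , drop = FALSE]))
  if (max(tbar) > max_mean_angle_deg * pi / 180) {
    warn("time-averaged angle exceeds the small-angle regime inside the box; delta_n_y identification degrades")
  }
  structure(list(dny = dny, pixel_size = px,
                 frame_interval = movie$frame_interval,
                 lambda0 = nb * px, tau0 = nt * movie$frame_interval),
            class = "fluct_stack")
}

# per-pixel nematic time average of an ny x nx x nt angle array
nematic_mean_field <- function(ang) {
  z <- apply(exp(2i * ang), c(1, 2), mean)
  wrap_nematic(Arg(z) / 2)
}

#' Spatiotemporal and equal-time fluctuation spectra
#'
#' Computes `c_nn(q, w)` and the equal-time spectrum `s_nn(q)` of a
#' fluctuation stack with mirror padding and a diffraction cutoff.
#'
#' @param fluct A [compute_fluctuations()] result (or a bare 3D array plus
#'   `pixel_size` and `frame_interval`).
#' @param lambda_im Diffraction cutoff wavelength (um); modes with
#'   `|q| > 2*pi/lambda_im` are removed (set to `NA`). Use `Inf` to keep
#'   all modes.
#' @param pad_factor Number of mirrored tiles per dimension (1 = standard
#'   mirror padding; larger values only double the padding width again and
#'   must not change the spectrum).
#' @param pad `"mirror"` (default) reflects the stack in all dimensions
#'   before transforming, suppressing boundary artifacts of non-periodic
#'   data; `"none"` transforms directly (appropriate for fields that are
#'   periodic by construction, e.g. synthetic self-consistency checks).
#' @param pixel_size,frame_interval Required when `fluct` is a bare array.
#' @return Object of class `"fluct_spectrum"`: `snn` matrix over `(qy, qx)`
#'   (rows = qy in fft order), `qx`, `qy` (rad/um), `omega` (rad/s),
#'   `lambda_im`, and the real-space variance `var_real` of the padded
#'   stack for bookkeeping.
#' @export
fluct_spectrum <- function(fluct, lambda_im = 0.530, pad_factor = 1L,
                           pad = c("mirror", "none"),
                           pixel_size = NULL, frame_interval = NULL) {
  pad <- match.arg(pad)
  if (inherits(fluct, "fluct_stack")) {
    a <- fluct$dny; px <- fluct$pixel_size; dt <- fluct$frame_interval
  } else {
    a <- fluct; px <- pixel_size; dt <- frame_interval
  }
  if (min(dim(a)[1:2]) < 2) abort("box smaller than 2 pixels")
  m <- a
  if (pad == "mirror") {
    m <- m[c(seq_len(dim(m)[1]), rev(seq_len(dim(m)[1]))), , , drop = FALSE]
    m <- m[, c(seq_len(dim(m)[2]), rev(seq_len(dim(m)[2]))), , drop = FALSE]
    m <- m[, , c(seq_len(dim(m)[3]), rev(seq_len(dim(m)[3]))), drop = FALSE]
  }
  if (pad_factor > 1L) {
    m <- m[rep(seq_len(dim(m)[1]), pad_factor),
           rep(seq_len(dim(m)[2]), pad_factor),
           rep(seq_len(dim(m)[3]), pad_factor), drop = FALSE]
  }
  ny <- dim(m)[1]; nx <- dim(m)[2]; nt <- dim(m)[3]
  Ly <- ny * px; Lx <- nx * px; tau0 <- nt * dt
  Fm <- fft(m) * (px * px * dt)          # discrete approximation to the FT
  cnn <- Re(Fm * Conj(Fm)) / (tau0 * Lx * Ly)
  dw <- 2 * pi / tau0
  snn <- apply(cnn, c(1, 2), sum) * dw / (2 * pi)
  # periodic tiling concentrates all weight into every pad_factor-th mode;
  # renormalize so surviving modes match the single-tile spectrum
  if (pad_factor > 1L) snn <- snn / pad_factor^2
  qx <- fft_freq(nx, px); qy <- fft_freq(ny, px)
  qmag <- sqrt(outer(qy^2, qx^2, "+"))
  if (is.finite(lambda_im)) snn[qmag > 2 * pi / lambda_im] <- NA_real_
  structure(list(snn = snn, qx = qx, qy = qy,
                 omega = fft_freq(nt, dt), lambda_im = lambda_im,
                 dq = c(2 * pi / Lx, 2 * pi / Ly),
                 var_real = mean(m^2)),
            class = "fluct_spectrum")
}

#' @export
print.fluct_spectrum <- function(x, ...) {
  cat(sprintf("Equal-time fluctuation spectrum on a %d x %d q-grid (cutoff %.3g um)\n",
              length(x$qy), length(x$qx), x$lambda_im))
  invisible(x)
}

#' Integrated spectral weight
#'
#' `sum(s_nn) * (dq/2pi)^2` over retained modes; with `lambda_im = Inf` this
#' equals the time-averaged spatial variance of the fluctuations (Parseval),
#' and with a finite cutoff it drops by exactly the weight of the removed
#' ring.
#'
#' @param spec A [fluct_spectrum()].
#' @return Scalar variance (rad^2).
#' @export
spectrum_weight <- function(spec) {
  sum(spec$snn, na.rm = TRUE) * spec$dq[1] * spec$dq[2] / (2 * pi)^2
}

#' Transverse slice of the equal-time spectrum
#'
#' `s_nn(q0, q_y)` with the axial wavevector fixed at the lowest box mode
#' `q0 = 2*pi/lambda0`: the slice is averaged over `+-q0` and symmetrized
#' over `+-q_y`.
#'
#' @param spec A [fluct_spectrum()].
#' @param lambda0 Box side (um) defining `q0`.
#' @return Tibble with `qy` (> 0, rad/um) and `snn`.
#' @export
slice_qy <- function(spec, lambda0 = 8) {
  q0 <- 2 * pi / lambda0
  jpos <- which.min(abs(spec$qx - q0))
  jneg <- which.min(abs(spec$qx + q0))
  s <- rowMeans(cbind(spec$snn[, jpos], spec$snn[, jneg]), na.rm = TRUE)
  qy <- spec$qy
  pos <- qy > 0
  out <- tibble(qy = qy[pos], snn = s[pos])
  isneg <- qy < 0
  neg <- tibble(qy = -qy[isneg], snn = s[isneg])
  out <- dplyr::summarise(dplyr::group_by(dplyr::bind_rows(out, neg), .data$qy),
                          snn = mean(.data$snn, na.rm = TRUE), .groups = "drop")
  # drop the degenerate Nyquist row (mirror padding zeroes it up to rounding)
  floor_snn <- max(out$snn, na.rm = TRUE) * 1e-12
  dplyr::arrange(dplyr::filter(out, is.finite(.data$snn),
                               .data$snn > floor_snn),
                 .data$qy)
}

#' Detect a spectral peak above the power-law background
#'
#' A peak is an interior local maximum of the slice itself; since the
#' slice falls steeply, an absolute local maximum already requires a strong
#' enhancement. The inverse-square background
#' `A (q0^2 + qy^2)^(p/2)` is fitted through the three lowest and three
#' highest points, and the winning maximum must exceed the background
#' residual scatter by `min_excess` MAD units.
#'
#' @param slice A [slice_qy()] tibble.
#' @param lambda0 Box side (um), fixing the axial mode `q0` of the
#'   background model.
#' @param min_excess Detection threshold in MAD units of the background
#'   residuals.
#' @return A one-row tibble with `qy_star` (rad/um), `lambda_star` (um) and
#'   `excess` (residual in MAD units), or a zero-row tibble when no peak
#'   exists (the expected outcome for homogeneous fields).
#' @export
find_spectral_peak <- function(slice, lambda0 = 8, min_excess = 2) {
  n <- nrow(slice)
  empty <- tibble(qy_star = numeric(0), lambda_star = numeric(0),
                  excess = numeric(0))
  if (n < 8) return(empty)
  q0 <- 2 * pi / lambda0
  s <- slice$snn          # raw: the void comb can be a single-bin feature
  ends <- c(1:3, (n - 2):n)
  lq <- log(q0^2 + slice$qy^2)
  fit <- lm(ls ~ lq, data = data.frame(ls = log(s), lq = lq)[ends, ])
  bg <- exp(coef(fit)[1] + coef(fit)[2] * lq)
  rel <- s / bg - 1                     # relative excess above background
  interior <- setdiff(2:(n - 1), ends)
  is_max <- vapply(interior,
                   function(i) s[i] >= s[i - 1] && s[i] >= s[i + 1],
                   logical(1))
  cand <- interior[is_max]
  if (length(cand) == 0) return(empty)
  sc <- mad(rel[interior], constant = 1.4826)
  loc <- cand[which.max(rel[cand])]
  # a genuine peak must beat both the residual scatter and a floor of 50%
  # enhancement (chi-square mode noise never reaches that after averaging)
  if (sc <= 0 || rel[loc] < max(min_excess * sc, 0.5)) return(empty)
  qys <- refine_extremum(slice$qy, s, loc)
  tibble(qy_star = qys, lambda_star = 2 * pi / qys,
         excess = rel[loc] / sc)
}

#' Local adaptive binarization
#'
#' A pixel maps to 1 iff its value is at least the mean over the disk of
#' the given physical radius around it (a constant image therefore maps to
#' all ones).
#'
#' @param image Numeric matrix.
#' @param pixel_size Pixel size (um).
#' @param radius_um Disk radius (um); must be at least one pixel.
#' @return Integer 0/1 matrix.
#' @export
local_binarize <- function(image, pixel_size, radius_um = 2) {
  r_px <- radius_um / pixel_size
  if (r_px < 1) abort("binarization radius is below one pixel")
  eps <- 1e-9 * (diff(range(image)) + 1)   # guard the >= against FP noise
  (image >= disk_mean(image, r_px) - eps) * 1L
}

#' Couple microtubule density to orientational fluctuations
#'
#' Relates the time-averaged retardance (a density proxy) to the
#' time-averaged fluctuation magnitude over box pixels: a least-squares
#' slope (rad/nm), and the ratio of mean fluctuations in low- versus
#' high-density regions of the locally binarized retardance.
#'
#' @param mean_ret Time-averaged retardance in the box (matrix, nm).
#' @param mean_absdth Time-averaged `|delta theta|` in the box (matrix, rad).
#' @param pixel_size Pixel size (um).
#' @param radius_um Local binarization radius (um).
#' @return One-row tibble: `slope` (rad/nm), `ratio`
#'   (`<|dtheta|>_low / <|dtheta|>_high`), and the pixel counts of both
#'   classes.
#' @export
density_fluctuation_coupling <- function(mean_ret, mean_absdth, pixel_size,
                                         radius_um = 2) {
  stopifnot(all(dim(mean_ret) == dim(mean_absdth)))
  fit <- lm(as.vector(mean_absdth) ~ as.vector(mean_ret))
  mask <- local_binarize(mean_ret, pixel_size, radius_um)
  lo <- mean_absdth[mask == 0L]; hi <- mean_absdth[mask == 1L]
  if (length(lo) == 0 || length(hi) == 0) {
    abort("empty low- or high-density class", class = "nemspindle_empty_class")
  }
  tibble(slope = unname(coef(fit)[2]), ratio = mean(lo) / mean(hi),
         n_low = length(lo), n_high = length(hi))
}
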