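# Rigid registration of PolScope movies into the spindle rest frame.
#
# Four steps: (1) the movie is assumed cropped to an ROI containing the
# spindle throughout (synthetic movies are rendered that way); (2) each
# retardance frame is Gaussian-blurred (3 um), thresholded at half its
# robust maximum, and the center of brightness of the largest bright
# component gives the per-frame translation; (3) the whole movie is rotated
# once so the retardance-weighted nematic mean of the slow axis is
# horizontal; (4) a fine alignment translates each frame onto a moving-
# average reference by maximizing the overlap of gradient-magnitude images
# (integer cross-correlation with parabolic sub-pixel refinement). Both
# channels always receive identical transforms and slow-axis *values* are
# rotated along with the frame.

#' Register a PolScope movie into the spindle rest frame
#'
#' @param movie A `"polscope_movie"`.
#' @param blur_um Gaussian blur scale for the coarse centering step (um).
#' @param ref_window Moving-average window (frames) for the fine-alignment
#'   reference.
#' @param max_fine_px Largest fine-alignment translation considered sane
#'   (pixels); beyond it the frame falls back to the coarse result with a
#'   warning.
#' @param fine Run the fine-alignment step (it may be disabled without
#'   substantially altering downstream analysis).
#' @return A list of class `"registered_movie"`: the registered
#'   `"polscope_movie"` as `movie`, and `track`, a tibble with per-frame
#'   `frame`, `tx`, `ty` (um, raw-to-registered translation) and `rot` (rad).
#' @export
register_movie <- function(movie, blur_um = 3, ref_window = 10L,
                           max_fine_px = 6, fine = TRUE) {
  ret <- movie$retardance; ang <- movie$slow_axis
  d <- dim(ret)
  if (is.na(d[3]) || d[3] < 2L) abort("movie must have at least 2 frames")
  ny <- d[1]; nx <- d[2]; nt <- d[3]
  px <- movie$pixel_size
  ctr_px <- c((nx + 1) / 2, (ny + 1) / 2)

  # --- step 2: coarse centering by center of brightness ---------------------
  sigma_px <- blur_um / px
  trans_px <- matrix(0, nt, 2)
  masks_any <- FALSE
  for (t in seq_len(nt)) {
    b <- gaussian_blur(ret[, , t], sigma_px)
    thr <- 0.5 * quantile(b, 0.999)
    m <- largest_component((b >= thr & b > 0) * 1L)
    if (sum(m) == 0 || sum(b * m) <= 0) {
      abort(sprintf("frame %d: no component above threshold", t),
            class = "nemspindle_empty_frame")
    }
    masks_any <- TRUE
    w <- b * m
    jj <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
    ii <- matrix(seq_len(ny), ny, nx)
    cb <- c(sum(jj * w), sum(ii * w)) / sum(w)
    trans_px[t, ] <- ctr_px - cb            # shift that centers the spindle
  }

  # --- step 3: single rotation aligning the mean slow axis with x -----------
  # estimate from coarsely centered frames, weighting by retardance
  zsum <- 0
  for (t in seq_len(nt)) {
    r_t <- warp_rigid(ret[, , t], shift = trans_px[t, ])
    a_t <- warp_angle_rigid(ang[, , t], shift = trans_px[t, ])
    zsum <- zsum + sum(r_t * exp(2i * a_t))
  }
  rot_corr <- -wrap_nematic(Arg(zsum) / 2)

  apply_warp <- function(t, extra_shift = c(0, 0)) {
    s <- trans_px[t, ] + extra_shift
    list(ret = warp_rigid(ret[, , t], shift = s, rot = rot_corr),
         ang = warp_angle_rigid(ang[, , t], shift = s, rot = rot_corr))
  }

  reg_ret <- array(0, dim = d); reg_ang <- array(0, dim = d)
  for (t in seq_len(nt)) {
    w <- apply_warp(t)
    reg_ret[, , t] <- w$ret; reg_ang[, , t] <- w$ang
  }

  fine_px <- matrix(0, nt, 2)
  if (fine) {
    # --- step 4: gradient-overlap alignment to a moving-average reference ---
    grads <- array(0, dim = d)
    for (t in seq_len(nt)) grads[, , t] <- gradient_mag(reg_ret[, , t])
    half <- max(1L, ref_window %/% 2L)
    for (t in seq_len(nt)) {
      win <- setdiff(max(1L, t - half):min(nt, t + half), t)
      refg <- apply(grads[, , win, drop = FALSE], c(1, 2), mean)
      sh <- xcorr_shift(grads[, , t], refg, max_shift = ceiling(max_fine_px))
      if (any(!is.finite(sh)) || max(abs(sh)) > max_fine_px) {
        warn(sprintf("frame %d: fine alignment diverged; keeping coarse result", t))
        sh <- c(0, 0)
      }
      fine_px[t, ] <- sh
      if (any(sh != 0)) {
        w <- apply_warp(t, extra_shift = sh)
        reg_ret[, , t] <- w$ret; reg_ang[, , t] <- w$ang
      }
    }
  }

  total_px <- trans_px + fine_px
  out_movie <- structure(list(retardance = reg_ret, slow_axis = reg_ang,
                              pixel_size = px,
                              frame_interval = movie$frame_interval,
                              truth = movie$truth),
                         class = "polscope_movie")
  structure(list(
    movie = out_movie,
    track = tibble(frame = seq_len(nt),
                   tx = total_px[, 1] * px, ty = total_px[, 2] * px,
                   rot = rep(wrap_pi(rot_corr), nt))
  ), class = "registered_movie")
}

#' @export
print.registered_movie <- function(x, ...) {
  cat(sprintf("Registered movie (%d frames): rotation %.3f deg, mean |shift| %.3f um\n",
              nrow(x$track), x$track$rot[1] * 180 / pi,
              mean(sqrt(x$track$tx^2 + x$track$ty^2))))
  invisible(x)
}

# Translation (c(dx, dy), pixels) that best aligns `img` to `ref`:
# cross-correlation peak on the integer grid within +-max_shift, refined by
# a 1D parabola through the peak and its neighbours in each direction.
xcorr_shift <- function(img, ref, max_shift = 6L) {
  ny <- nrow(img); nx <- ncol(img)
  C <- Re(fft(fft(ref) * Conj(fft(img)), inverse = TRUE)) / (nx * ny)
  # C[i, j] ~ correlation for shift (dx = j - 1, dy = i - 1), wrapped
  dxs <- fft_shift_index(nx); dys <- fft_shift_index(ny)
  ok_x <- abs(dxs) <= max_shift; ok_y <- abs(dys) <= max_shift
  sub <- C[ok_y, ok_x, drop = FALSE]
  pk <- which(sub == max(sub), arr.ind = TRUE)[1, ]
  ix <- which(ok_x)[pk[2]]; iy <- which(ok_y)[pk[1]]
  refine <- function(C, i, n, along, j) {
    get <- function(k) {
      k <- ((k - 1) %% n) + 1
      if (along == "row") C[k, j] else C[j, k]
    }
    y0 <- get(i - 1); y1 <- get(i); y2 <- get(i + 1)
    den <- (y0 - 2 * y1 + y2)
    if (abs(den) < 1e-12) 0 else 0.5 * (y0 - y2) / den
  }
  dx <- dxs[ix] + refine(C, ix, nx, "col", iy)
  dy <- dys[iy] + refine(C, iy, ny, "row", ix)
  # C was built so positive shift means img must move by (dx, dy)
  c(dx, dy)
}

# signed shifts corresponding to fft output index order
fft_shift_index <- function(n) {
  k <- 0:(n - 1)
  ifelse(k <= n %/% 2, k, k - n)
}
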