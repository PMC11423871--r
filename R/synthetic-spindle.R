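# Synthetic LC-PolScope data with known ground truth.
#
# The generator renders a revolved pole-indented tactoid filled with uniform
# microtubule density rho0, perforated by tactoid-like voids, and observed in
# projection: per pixel the retardance is A0 times the line integral of
# density along the optical axis (A0 in nm^2, rho in um^-2, path in um;
# 1 nm^2 um^-1 = 1e-3 nm), and the slow axis is the circle-arc director angle
# plus a sampled orientational fluctuation field. Rigid drift and additive
# noise emulate acquisition.

#' Orientational fluctuation parameters
#'
#' @param amplitude RMS fluctuation scale (rad).
#' @param spectral_exponent Power-law exponent of the equal-time spatial
#'   spectrum (default -2, the signature of nematic elasticity in an active
#'   nematic).
#' @param void_boost Multiplicative fluctuation enhancement inside voids
#'   (>= 1; default 1.07).
#' @param correlation_time Temporal correlation time (s).
#' @return A list of class `"fluct_params"`.
#' @export
fluct_params <- function(amplitude = 0.05, spectral_exponent = -2,
                         void_boost = 1.07, correlation_time = 20) {
  stopifnot(amplitude >= 0, void_boost >= 1, correlation_time > 0)
  structure(list(amplitude = amplitude, spectral_exponent = spectral_exponent,
                 void_boost = void_boost, correlation_time = correlation_time),
            class = "fluct_params")
}

#' Tactoid-like void ground truth
#'
#' A void is the solid obtained by revolving a circle arc of chord `beta`
#' about the spindle axis and scaling the cross-section anisotropically so
#' the waist is an ellipse with semi-axes `a >= b`.
#'
#' @param center Void center, length-3 (um) in spindle coordinates
#'   (x along the axis, (y, z) the metaphase-plate plane).
#' @param beta Void length along the spindle axis (um).
#' @param a,b Waist semi-axes (um), `a >= b > 0`.
#' @param psi In-plane (y-z) orientation of the a-axis (rad).
#' @return A list of class `"void_truth"`.
#' @export
void_truth <- function(center = c(0, 0, 0), beta = 11, a = 0.7, b = 0.36,
                       psi = 0) {
  if (!(a >= b && b > 0)) abort("void requires a >= b > 0",
                                class = "nemspindle_invalid_geometry")
  if (beta <= 0) abort("void requires beta > 0", class = "nemspindle_invalid_geometry")
  structure(list(center = center, beta = beta, a = a, b = b, psi = psi),
            class = "void_truth")
}

# Unit circle-arc width profile: half-width 1 at u = 0, 0 at u = +-beta/2.
void_profile_unit <- function(u, beta) {
  rc <- (beta^2 / 4 + 1) / 2           # circle radius through (+-beta/2, 0), (0, 1)
  h <- sqrt(pmax(rc^2 - u^2, 0)) - (rc - 1)
  h[abs(u) > beta / 2] <- 0
  pmax(h, 0)
}

#' Synthetic spindle ground truth
#'
#' Defaults correspond to a typical MII mouse-oocyte spindle imaged by
#' LC-PolScope: `L0 = 15.2`, `R0 = 8`, `r0 = 4` um; `A0 = 7.5` nm^2 per
#' microtubule; density chosen so the central retardance is a few nm.
#'
#' @param L0,R0,r0 Tactoid geometry (um), see [tactoid()].
#' @param rho0 Microtubule cross-sectional density away from voids (um^-2).
#' @param A0 Per-microtubule retardance constant (nm^2).
#' @param voids List of [void_truth()] objects.
#' @param fluct [fluct_params()] for the slow-axis fluctuation field.
#' @param n_frames Number of movie frames.
#' @param pixel_size Pixel size (um).
#' @param frame_interval Frame interval (s).
#' @param drift Per-frame rigid motion: a data frame with columns `tx`, `ty`
#'   (um) and `rot` (rad), one row per frame, or `NULL` for a static spindle.
#' @param noise_sd Additive Gaussian retardance noise (nm).
#' @param angle_noise_sd Angular jitter on the slow axis (rad).
#' @param margin Clear margin around the spindle (um).
#' @param seed RNG seed used by the renderer.
#' @return A list of class `"spindle_truth"`.
#' @export
spindle_truth <- function(L0 = 15.2, R0 = 8, r0 = 4, rho0 = 25, A0 = 7.5,
                          voids = list(), fluct = fluct_params(),
                          n_frames = 40L, pixel_size = 0.25,
                          frame_interval = 4, drift = NULL,
                          noise_sd = 0.05, angle_noise_sd = 0.01,
                          margin = 3, seed = 1L) {
  tac <- tactoid(L0, R0, r0)
  stopifnot(rho0 > 0, pixel_size > 0, n_frames >= 1)
  for (v in voids) validate_void(tac, v)
  if (!is.null(drift)) {
    drift <- as_tibble(drift)
    stopifnot(all(c("tx", "ty", "rot") %in% names(drift)),
              nrow(drift) == n_frames)
  }
  structure(list(tac = tac, L0 = L0, R0 = R0, r0 = r0, rho0 = rho0, A0 = A0,
                 voids = voids, fluct = fluct, n_frames = as.integer(n_frames),
                 pixel_size = pixel_size, frame_interval = frame_interval,
                 drift = drift, noise_sd = noise_sd,
                 angle_noise_sd = angle_noise_sd, margin = margin,
                 seed = as.integer(seed)),
            class = "spindle_truth")
}

validate_void <- function(tac, v) {
  u <- seq(-v$beta / 2, v$beta / 2, length.out = 21)
  h <- void_profile_unit(u, v$beta) * max(v$a, v$b)
  rr <- sqrt(v$center[2]^2 + v$center[3]^2) + h
  ro <- tactoid_outer_radius(tac, v$center[1] + u)
  if (any(rr > ro) || abs(v$center[1]) + v$beta / 2 > tac$tip) {
    abort("void extends outside the spindle", class = "nemspindle_invalid_geometry")
  }
  invisible(v)
}

#' Evenly spaced plate voids
#'
#' Convenience ground truth: `n` identical voids centered on the metaphase
#' plate (`x = 0`), spaced `spacing` um apart along y, emulating a row of
#' chromosome-associated voids.
#'
#' @param n Number of voids.
#' @param spacing Center-to-center spacing along y (um).
#' @param beta,a,b,psi Per-void parameters, see [void_truth()].
#' @return List of [void_truth()] objects.
#' @export
make_void_row <- function(n = 3, spacing = 2.4, beta = 11, a = 0.7, b = 0.36,
                          psi = 0) {
  ys <- (seq_len(n) - (n + 1) / 2) * spacing
  lapply(ys, function(y) void_truth(center = c(0, y, 0), beta = beta,
                                    a = a, b = b, psi = psi))
}

# Chord length (um) of the optical-axis line through the spindle solid at
# in-plane spindle coordinates (x, y), minus void interiors.
spindle_chord <- function(truth, x, y) {
  tac <- truth$tac
  ro <- tactoid_outer_radius(tac, x)
  chord <- 2 * sqrt(pmax(ro^2 - y^2, 0))
  # polar indentation balls
  for (s in c(-1, 1)) {
    chord <- chord - 2 * sqrt(pmax(tac$r0^2 - (x - s * tac$L0)^2 - y^2, 0))
  }
  for (v in truth$voids) {
    u <- x - v$center[1]
    h <- void_profile_unit(u, v$beta)
    A <- v$a * h; B <- v$b * h
    on <- A > 0
    if (!any(on)) next
    u1 <- cos(v$psi); u2 <- sin(v$psi)
    dy <- y - v$center[2]
    a2 <- u2^2 / A^2 + u1^2 / B^2
    b2 <- 2 * dy * u1 * u2 * (1 / A^2 - 1 / B^2)
    c2 <- dy^2 * (u1^2 / A^2 + u2^2 / B^2) - 1
    disc <- b2^2 - 4 * a2 * c2
    sub <- ifelse(on & disc > 0, sqrt(pmax(disc, 0)) / pmax(a2, 1e-300), 0)
    chord <- chord - sub
  }
  pmax(chord, 0)
}

#' Sample a spatiotemporal orientational fluctuation field
#'
#' Gaussian random field with an isotropic equal-time spatial power spectrum
#' proportional to `|q|^spectral_exponent`, synthesized by spectral filtering
#' of white noise, with Ornstein-Uhlenbeck temporal mixing
#' (`corr(dt) = exp(-dt / correlation_time)`). The realization is rescaled to
#' the requested RMS amplitude and multiplied by `void_boost` inside the
#' supplied void mask.
#'
#' @param fluct [fluct_params()].
#' @param nx,ny,nt Grid dimensions (pixels, frames).
#' @param pixel_size Pixel size (um).
#' @param frame_interval Frame interval (s).
#' @param void_mask Optional `ny x nx` logical/0-1 matrix of void pixels.
#' @param seed RNG seed.
#' @param regularize If `TRUE`, a non-negative spectral exponent is permitted
#'   (cut off at the grid scale); otherwise it is refused.
#' @return `ny x nx x nt` array of angle fluctuations (rad).
#' @export
sample_fluctuation_field <- function(fluct, nx, ny, nt, pixel_size,
                                     frame_interval, void_mask = NULL,
                                     seed = 1L, regularize = FALSE) {
  if (fluct$spectral_exponent >= 0 && !regularize) {
    abort("non-negative spectral exponent is not normalizable on the grid; set regularize = TRUE",
          class = "nemspindle_bad_spectrum")
  }
  out <- array(0, dim = c(ny, nx, nt))
  if (fluct$amplitude == 0) return(out)
  set.seed(seed)
  qx <- fft_freq(nx, pixel_size)
  qy <- fft_freq(ny, pixel_size)
  qq <- sqrt(outer(qy^2, qx^2, "+"))
  qq[1, 1] <- min(qq[qq > 0])          # regularize the DC mode
  filt <- qq^(fluct$spectral_exponent / 2)
  filt[1, 1] <- 0                      # zero-mean field
  draw_field <- function() {
    w <- matrix(rnorm(nx * ny), ny, nx)
    Re(fft(fft(w) * filt, inverse = TRUE)) / (nx * ny)
  }
  phi <- exp(-frame_interval / fluct$correlation_time)
  f <- draw_field()
  out[, , 1] <- f
  if (nt > 1) {
    for (t in 2:nt) {
      f <- phi * f + sqrt(1 - phi^2) * draw_field()
      out[, , t] <- f
    }
  }
  out <- out * (fluct$amplitude / sd(out))
  if (!is.null(void_mask)) {
    boost <- 1 + (fluct$void_boost - 1) * (void_mask > 0)
    for (t in seq_len(nt)) out[, , t] <- out[, , t] * boost
  }
  out
}

#' Render a synthetic LC-PolScope movie
#'
#' Produces paired retardance (nm) and slow-axis (rad) frames for a
#' [spindle_truth()]: retardance by exact line integration of density through
#' the revolved tactoid minus voids, slow axis from the circle-arc director
#' field plus the sampled fluctuation field, with per-frame rigid drift and
#' additive noise.
#'
#' @param truth A [spindle_truth()].
#' @return An object of class `"polscope_movie"`: list with `retardance` and
#'   `slow_axis` (`ny x nx x nt` arrays), `pixel_size`, `frame_interval`, and
#'   the generating `truth`.
#' @export
render_polscope_movie <- function(truth) {
  px <- truth$pixel_size
  tac <- truth$tac
  nx <- 2L * ceiling((tac$L0 + truth$margin) / px)
  ny <- 2L * ceiling((tac$R0 + truth$margin) / px)
  nt <- truth$n_frames
  g <- pixel_grid(nx, ny, px)

  # static (rest-frame) retardance and model director
  chord <- matrix(spindle_chord(truth, as.vector(g$x), as.vector(g$y)), nrow = ny)
  ret0 <- truth$A0 * truth$rho0 * chord * 1e-3    # nm
  th0 <- matrix(theta_arcs_quiet(as.vector(g$x), as.vector(g$y), tac$L0), nrow = ny)

  # void mask in the image plane (pixels whose optical-axis line meets a void)
  vmask <- matrix(0L, ny, nx)
  for (v in truth$voids) {
    u <- g$x - v$center[1]
    h <- void_profile_unit(u, v$beta)
    inside <- h > 0 & abs(g$y - v$center[2]) <= v$a * h   # projected footprint
    vmask[inside] <- 1L
  }

  dth <- sample_fluctuation_field(truth$fluct, nx, ny, nt, px,
                                  truth$frame_interval, void_mask = vmask,
                                  seed = truth$seed)
  set.seed(truth$seed + 1L)
  ret <- array(0, dim = c(ny, nx, nt))
  ang <- array(0, dim = c(ny, nx, nt))
  ctr <- c(nx, ny) / 2 * px
  for (t in seq_len(nt)) {
    th_t <- wrap_nematic(th0 + dth[, , t])
    if (is.null(truth$drift)) {
      r_t <- ret0; a_t <- th_t
    } else {
      d <- truth$drift[t, ]
      # scene moved by (tx, ty) and rotated by rot about the image center:
      # sample the rest-frame scene at the inverse-transformed pixel centers
      cs <- cos(-d$rot); sn <- sin(-d$rot)
      sx <- cs * g$x - sn * g$y - d$tx
      sy <- sn * g$x + cs * g$y - d$ty
      ch <- matrix(spindle_chord(truth, as.vector(sx), as.vector(sy)), nrow = ny)
      r_t <- truth$A0 * truth$rho0 * ch * 1e-3
      th_model <- matrix(theta_arcs_quiet(as.vector(sx), as.vector(sy), tac$L0), nrow = ny)
      # fluctuations ride along with the material; rotation adds to the angle
      a_t <- wrap_nematic(th_model + dth[, , t] + d$rot)
    }
    if (truth$noise_sd > 0) {
      r_t <- pmax(r_t + matrix(rnorm(nx * ny, sd = truth$noise_sd), ny, nx), 0)
    }
    if (truth$angle_noise_sd > 0) {
      a_t <- wrap_nematic(a_t + matrix(rnorm(nx * ny, sd = truth$angle_noise_sd), ny, nx))
    }
    ret[, , t] <- r_t
    ang[, , t] <- a_t
  }
  structure(list(retardance = ret, slow_axis = ang, pixel_size = px,
                 frame_interval = truth$frame_interval, truth = truth),
            class = "polscope_movie")
}

#' @export
print.polscope_movie <- function(x, ...) {
  d <- dim(x$retardance)
  cat(sprintf("PolScope movie: %d x %d px, %d frames, %.3g um/px, %.3g s/frame\n",
              d[2], d[1], d[3], x$pixel_size, x$frame_interval))
  invisible(x)
}

#' Write / read a PolScope movie as a TIFF pair
#'
#' The retardance (nm) and slow-axis (rad) series are written as multi-page
#' 32-bit float TIFFs with a JSON sidecar holding the pixel calibration.
#'
#' @param movie A `"polscope_movie"`.
#' @param path Directory to write into (created if needed).
#' @param prefix File-name prefix.
#' @return `write_polscope_movie` returns the paths invisibly;
#'   `read_polscope_movie` returns a `"polscope_movie"` (without ground
#'   truth).
#' @export
write_polscope_movie <- function(movie, path, prefix = "spindle") {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  nt <- dim(movie$retardance)[3]
  as_pages <- function(a) lapply(seq_len(nt), function(t) a[, , t])
  fr <- file.path(path, paste0(prefix, "_retardance.tif"))
  fa <- file.path(path, paste0(prefix, "_slowaxis.tif"))
  fj <- file.path(path, paste0(prefix, "_meta.json"))
  # map the slow axis into [0, pi) for storage
  ang <- movie$slow_axis %% pi
  tiff::writeTIFF(as_pages(movie$retardance / max(movie$retardance, 1)), fr,
                  bits.per.sample = 32L, reduce = FALSE)
  tiff::writeTIFF(as_pages(ang / pi), fa, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(list(pixel_size = movie$pixel_size,
                            frame_interval = movie$frame_interval,
                            retardance_scale = max(movie$retardance, 1),
                            angle_scale = pi),
                       fj, auto_unbox = TRUE, digits = NA)
  invisible(c(retardance = fr, slow_axis = fa, meta = fj))
}

#' @rdname write_polscope_movie
#' @export
read_polscope_movie <- function(path, prefix = "spindle") {
  meta <- jsonlite::read_json(file.path(path, paste0(prefix, "_meta.json")))
  rd <- tiff::readTIFF(file.path(path, paste0(prefix, "_retardance.tif")), all = TRUE)
  ad <- tiff::readTIFF(file.path(path, paste0(prefix, "_slowaxis.tif")), all = TRUE)
  to_arr <- function(lst) array(unlist(lst), dim = c(dim(lst[[1]]), length(lst)))
  ret <- to_arr(rd) * meta$retardance_scale
  ang <- wrap_nematic(to_arr(ad) * meta$angle_scale)
  structure(list(retardance = ret, slow_axis = ang,
                 pixel_size = meta$pixel_size,
                 frame_interval = meta$frame_interval, truth = NULL),
            class = "polscope_movie")
}
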