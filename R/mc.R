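# Monte Carlo simulation of metaphase-plate chromosome configurations:
# hard ellipses in a disk boundary, optionally interacting through a
# long-range repulsive pair potential of the center-to-center distance.

#' Long-range repulsive pair potentials
#'
#' Returns a vectorized function `U(s)` of the center-to-center distance s
#' (um). Available forms: `none` (hard core only), `inv5` (s^-5, the
#' far-field 3D quadrupole analogue), `inv3` (s^-3), `yukawa`
#' (s^-1 exp(-s/lambda_B)), and `quadrupole_2d` (the defect-quadrupole
#' interaction curve, interpolated from [interaction_potential()]).
#'
#' The amplitude is chosen so that `U(s_ref) = u_ref` in units of the
#' sampling temperature at the end of the annealing schedule. The default
#' pins the interaction at the observed typical chromosome spacing
#' (2.4 um) to one thermal unit: strong enough for robust local ordering,
#' weak enough that the ensemble stays liquid rather than freezing into a
#' boundary-compressed crystal. Both the reference point and the amplitude
#' can be overridden.
#'
#' @param name Potential name.
#' @param amplitude Prefactor; `NULL` selects it from `s_ref`/`u_ref`.
#' @param lambda_B Yukawa screening length (um).
#' @param curve Tibble with `d` and `U` columns for `quadrupole_2d`
#'   (see [interaction_potential()]).
#' @param s_ref,u_ref Calibration point: `U(s_ref) = u_ref`.
#' @return Function `U(s)` with attributes `name` and `amplitude`.
#' @export
chromo_potential <- function(name = c("none", "inv5", "inv3", "yukawa",
                                      "quadrupole_2d"),
                             amplitude = NULL, lambda_B = 1.0, curve = NULL,
                             s_ref = 2.4, u_ref = 1) {
  name <- match.arg(name)
  if (name == "yukawa" && lambda_B <= 0) abort("lambda_B must be positive")
  base <- switch(
    name,
    none = function(s) rep(0, length(s)),
    inv5 = function(s) s^-5,
    inv3 = function(s) s^-3,
    yukawa = function(s) exp(-s / lambda_B) / s,
    quadrupole_2d = {
      if (is.null(curve)) abort("quadrupole_2d requires an interaction curve")
      # log-log interpolation of the tabulated defect-quadrupole potential
      lf <- splinefun(log(curve$d), log(pmax(curve$U, 1e-300)), method = "natural")
      function(s) exp(lf(log(s)))
    })
  if (is.null(amplitude)) {
    amplitude <- if (name == "none") 0 else u_ref / base(s_ref)
  }
  f <- function(s) {
    if (any(s <= 0)) abort("distance must be positive", class = "nemspindle_domain_error")
    amplitude * base(s)
  }
  structure(f, name = name, amplitude = amplitude)
}

new_plate_config <- function(x, y, phi, a, b, boundary_radius,
                             energy = NA_real_, trace = NULL) {
  out <- tibble(x = x, y = y, phi = wrap_pi(phi))
  attr(out, "a") <- a; attr(out, "b") <- b
  attr(out, "boundary_radius") <- boundary_radius
  attr(out, "energy") <- energy
  attr(out, "trace") <- trace
  class(out) <- c("plate_config", class(out))
  out
}

#' Random non-overlapping placement of chromosome sections
#'
#' Random sequential insertion with uniform positions and orientations,
#' rejecting overlaps and boundary violations: the steric-only null model
#' for metaphase-plate order.
#'
#' @param n Number of sections.
#' @param a,b Ellipse full axes (um); defaults are the chromosome-section
#'   dimensions a = 2.1, b = 0.8 um.
#' @param boundary_radius Disk boundary radius (um); the default 6.5 um
#'   puts 20 ellipses at ~20% area coverage.
#' @param sections Optional list of binary mask matrices (pixelated
#'   sections, one per object) to place instead of ellipses; requires
#'   `pixel_size`.
#' @param pixel_size Pixel size (um) for pixelated sections.
#' @param max_attempts Insertion attempts per object before failing.
#' @return A `"plate_config"` tibble (`x`, `y`, `phi`) with shape and
#'   boundary attributes; for pixelated sections, column `section` indexes
#'   the input list.
#' @export
random_placement <- function(n = 20, a = 2.1, b = 0.8, boundary_radius = 6.5,
                             sections = NULL, pixel_size = NULL,
                             max_attempts = 5000L) {
  if (is.null(sections)) {
    res <- random_place_cpp(as.integer(n), a / 2, b / 2, boundary_radius,
                            as.integer(max_attempts))
    if (!isTRUE(res$ok)) {
      abort("packing infeasible: max insertion attempts exceeded",
            class = "nemspindle_packing_infeasible")
    }
    return(new_plate_config(res$x, res$y, res$phi, a, b, boundary_radius))
  }
  place_sections(sections, pixel_size, boundary_radius, max_attempts)
}

# Pixelated-section placement on an occupancy grid. Sections are binary
# matrices at `pixel_size`; each is dropped with a random rotation at a
# random position, rejecting collisions with occupied or out-of-boundary
# pixels.
place_sections <- function(sections, pixel_size, boundary_radius,
                           max_attempts) {
  if (is.null(pixel_size)) abort("pixelated sections require pixel_size")
  nb <- 2L * ceiling(boundary_radius / pixel_size) + 1L
  ctr <- (nb + 1) / 2
  jj <- matrix(seq_len(nb), nb, nb, byrow = TRUE); ii <- matrix(seq_len(nb), nb, nb)
  inside <- ((jj - ctr)^2 + (ii - ctr)^2) * pixel_size^2 <= boundary_radius^2
  occ <- matrix(FALSE, nb, nb)
  out <- NULL
  for (k in seq_along(sections)) {
    sec <- sections[[k]] > 0
    placed <- FALSE
    for (att in seq_len(max_attempts)) {
      ang <- runif(1, 0, pi)
      rot <- rotate_mask(sec, ang)
      pix <- which(rot, arr.ind = TRUE)
      pc <- colMeans(pix)
      u <- runif(1); v <- runif(1)
      r <- boundary_radius / pixel_size * sqrt(u); th <- 2 * pi * v
      di <- round(ctr + r * sin(th) - pc[1]); dj <- round(ctr + r * cos(th) - pc[2])
      ti <- pix[, 1] + di; tj <- pix[, 2] + dj
      if (any(ti < 1 | ti > nb | tj < 1 | tj > nb)) next
      lin <- (tj - 1L) * nb + ti
      if (any(!inside[lin]) || any(occ[lin])) next
      occ[lin] <- TRUE
      out <- rbind(out, c((mean(tj) - ctr) * pixel_size,
                          (mean(ti) - ctr) * pixel_size, ang, k))
      placed <- TRUE
      break
    }
    if (!placed) abort("packing infeasible: max insertion attempts exceeded",
                       class = "nemspindle_packing_infeasible")
  }
  cfg <- new_plate_config(out[, 1], out[, 2], out[, 3], NA_real_, NA_real_,
                          boundary_radius)
  cfg$section <- out[, 4]
  attr(cfg, "occupancy") <- occ * 1L
  attr(cfg, "pixel_size") <- pixel_size
  cfg
}

# nearest-neighbour rotation of a binary mask about its centroid
rotate_mask <- function(mask, angle) {
  ny <- nrow(mask); nx <- ncol(mask)
  d <- ceiling(sqrt(ny^2 + nx^2)) + 2L
  out <- matrix(FALSE, d, d)
  ci <- (d + 1) / 2; cj <- (d + 1) / 2
  mi <- (ny + 1) / 2; mj <- (nx + 1) / 2
  cs <- cos(-angle); sn <- sin(-angle)
  ii <- matrix(seq_len(d), d, d); jj <- matrix(seq_len(d), d, d, byrow = TRUE)
  si <- round(mi + sn * (jj - cj) + cs * (ii - ci))
  sj <- round(mj + cs * (jj - cj) - sn * (ii - ci))
  ok <- si >= 1 & si <= ny & sj >= 1 & sj <= nx
  out[ok] <- mask[cbind(si[ok], sj[ok])]
  out
}

#' Annealed Monte Carlo placement under a repulsive potential
#'
#' Metropolis simulation of `n` hard ellipses in a disk: single-particle
#' translation + rotation moves, hard overlap and boundary constraints
#' rejected outright, pair energy from `potential` evaluated at
#' center-to-center distances, and a geometric temperature schedule from
#' `T0` down to `Tf` (the final temperature defines the energy unit).
#'
#' @param n,a,b,boundary_radius As in [random_placement()].
#' @param potential A [chromo_potential()] function.
#' @param sweeps Number of temperature steps.
#' @param moves_per_sweep Monte Carlo moves per sweep (default `n`).
#' @param T0,Tf Initial and final temperature.
#' @param step_trans,step_rot Maximum move sizes (um, rad).
#' @param init Optional starting `"plate_config"`; defaults to random
#'   placement.
#' @return A `"plate_config"` with attributes `energy` (final total) and
#'   `trace` (tibble with per-sweep `energy` and `acceptance`).
#' @export
anneal_plate <- function(n = 20, a = 2.1, b = 0.8, boundary_radius = 6.5,
                         potential = chromo_potential("inv5"),
                         sweeps = 600L, moves_per_sweep = NULL,
                         T0 = 20, Tf = 1, step_trans = 0.6, step_rot = 0.5,
                         separation = c("center", "surface"), init = NULL) {
  separation <- match.arg(separation)
  if (is.null(init)) init <- random_placement(n, a, b, boundary_radius)
  if (is.null(moves_per_sweep)) moves_per_sweep <- n
  smax <- 2 * boundary_radius + 1
  sg <- seq(1e-3, smax, length.out = 4000L)
  ug <- potential(sg)
  temps <- T0 * (Tf / T0)^(seq(0, 1, length.out = sweeps))
  res <- mc_run_cpp(init$x, init$y, init$phi, a / 2, b / 2, boundary_radius,
                    sg, ug, temps, as.integer(moves_per_sweep),
                    step_trans, step_rot,
                    sep_mode = if (separation == "surface") 1L else 0L)
  warm <- seq_len(min(10L, length(res$acceptance)))
  if (sum(res$acceptance[warm]) == 0) {
    abort("zero acceptance over the initial sweeps; reduce step sizes",
          class = "nemspindle_step_size_error")
  }
  new_plate_config(res$x, res$y, res$phi, a, b, boundary_radius,
                   energy = res$energy[length(res$energy)],
                   trace = tibble(sweep = seq_along(res$energy),
                                  temperature = temps,
                                  energy = res$energy,
                                  acceptance = res$acceptance))
}

#' Total pair energy of a configuration
#'
#' @param config A `"plate_config"`.
#' @param potential A [chromo_potential()] function.
#' @return Scalar energy.
#' @export
config_energy <- function(config, potential) {
  n <- nrow(config)
  if (n < 2) return(0)
  d <- as.vector(dist(cbind(config$x, config$y)))
  sum(potential(d))
}

#' Audit hard-core validity of a configuration
#'
#' Exact Perram-Wertheim separation test over all ellipse pairs.
#'
#' @param config A `"plate_config"`.
#' @return TRUE if no two ellipses overlap.
#' @export
config_valid <- function(config) {
  a <- attr(config, "a"); b <- attr(config, "b")
  !any(config_overlaps_cpp(config$x, config$y, config$phi, a / 2, b / 2))
}

#' Rasterize a configuration into analysis masks
#'
#' Renders the ellipse union and the disk boundary as binary masks at the
#' analysis pixel size, so simulated configurations pass through the same
#' pair-correlation code path as imaging data.
#'
#' @param config A `"plate_config"`.
#' @param pixel_size Pixel size (um).
#' @return List with `mask` and `boundary` (0/1 matrices) and `pixel_size`.
#' @export
rasterize_config <- function(config, pixel_size = 0.1) {
  R <- attr(config, "boundary_radius")
  a <- attr(config, "a"); b <- attr(config, "b")
  nb <- 2L * ceiling((R + 0.2) / pixel_size)
  g <- pixel_grid(nb, nb, pixel_size)
  boundary <- (g$x^2 + g$y^2 <= R^2) * 1L
  mask <- matrix(0L, nb, nb)
  A <- a / 2; B <- b / 2
  for (k in seq_len(nrow(config))) {
    dx <- g$x - config$x[k]; dy <- g$y - config$y[k]
    cs <- cos(config$phi[k]); sn <- sin(config$phi[k])
    u <- cs * dx + sn * dy; v <- -sn * dx + cs * dy
    mask[(u / A)^2 + (v / B)^2 <= 1] <- 1L
  }
  list(mask = mask * boundary, boundary = boundary, pixel_size = pixel_size)
}

#' Simulate an ensemble of plate configurations and their pair correlations
#'
#' Runs `n_replicates` independent simulations (annealed under `potential`,
#' or steric-only random placement when the potential is `none`), rasterizes
#' each final configuration, computes the edge-corrected pair correlation
#' g_II(s) through the identical code path used for imaging data, and
#' locates the extrema of the replicate-averaged curve.
#'
#' @param n_replicates Number of replicates.
#' @param potential A [chromo_potential()].
#' @param n,a,b,boundary_radius Geometry, as in [random_placement()].
#' @param pixel_size Raster pixel size (um).
#' @param bin_width g_II bin width (um).
#' @param n_boot Bootstrap resamples for extrema confidence intervals.
#' @param sweeps,T0,Tf Annealing controls (ignored for `none`).
#' @param separation Pair-separation convention passed to [anneal_plate()].
#' @param seed Optional RNG seed.
#' @param keep_configs Return the final configurations too.
#' @return List of class `"gii_ensemble"`: `curves` (tibble: `replicate`,
#'   `s`, `gii`), `mean_curve`, `extrema` (see [gii_extrema()]), and
#'   optionally `configs`.
#' @export
simulate_ensemble <- function(n_replicates = 200L,
                              potential = chromo_potential("inv5"),
                              n = 20, a = 2.1, b = 0.8, boundary_radius = 6.5,
                              pixel_size = 0.1, bin_width = 0.1,
                              n_boot = 1000L, sweeps = 600L, T0 = 20, Tf = 1,
                              separation = c("center", "surface"),
                              seed = NULL, keep_configs = FALSE) {
  separation <- match.arg(separation)
  if (!is.null(seed)) set.seed(seed)
  steric_only <- attr(potential, "name") == "none"
  curves <- vector("list", n_replicates)
  configs <- if (keep_configs) vector("list", n_replicates) else NULL
  for (r in seq_len(n_replicates)) {
    cfg <- if (steric_only) {
      random_placement(n, a, b, boundary_radius)
    } else {
      anneal_plate(n, a, b, boundary_radius, potential, sweeps = sweeps,
                   T0 = T0, Tf = Tf, separation = separation)
    }
    ras <- rasterize_config(cfg, pixel_size)
    gi <- pair_correlation(ras$mask, ras$boundary, pixel_size,
                           bin_width = bin_width)
    gi$replicate <- r
    curves[[r]] <- gi
    if (keep_configs) configs[[r]] <- cfg
  }
  curves <- dplyr::bind_rows(curves)
  ext <- gii_extrema(curves, n_boot = n_boot)
  mean_curve <- dplyr::summarise(dplyr::group_by(curves, .data$s),
                                 gii = mean(.data$gii), .groups = "drop")
  structure(list(curves = curves, mean_curve = mean_curve, extrema = ext,
                 configs = configs),
            class = "gii_ensemble")
}

#' @export
print.gii_ensemble <- function(x, ...) {
  nr <- length(unique(x$curves$replicate))
  cat(sprintf("g_II ensemble over %d replicates\n", nr))
  print(x$extrema)
  invisible(x)
}
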