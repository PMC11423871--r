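# Synthetic metaphase-plate and confocal ground truth.

#' Ground-truth plate configuration
#'
#' Places `n_chr` identical ellipses inside a disk boundary, either by
#' steric-only random sequential insertion or by annealed Monte Carlo under
#' a repulsive potential, and stores the generating parameters.
#'
#' @param n_chr Number of chromosome sections.
#' @param a,b Ellipse full axes (um).
#' @param boundary_radius Disk radius (um).
#' @param potential_name One of the [chromo_potential()] names; `"none"`
#'   gives steric-only placement.
#' @param potential_params Optional list passed to [chromo_potential()]
#'   (e.g. `lambda_B`, `amplitude`, `curve`).
#' @param sweeps Annealing sweeps when a potential is active.
#' @param seed RNG seed.
#' @return Object of class `"plate_truth"`: the `"plate_config"` in
#'   `$config` plus generator metadata.
#' @export
make_plate_truth <- function(n_chr = 20, a = 2.1, b = 0.8,
                             boundary_radius = 6.5,
                             potential_name = "none",
                             potential_params = list(), sweeps = 600L,
                             seed = 1L) {
  stopifnot(n_chr >= 1)
  set.seed(seed)
  pot <- do.call(chromo_potential, c(list(name = potential_name),
                                     potential_params))
  config <- if (potential_name == "none") {
    random_placement(n_chr, a, b, boundary_radius)
  } else {
    anneal_plate(n_chr, a, b, boundary_radius, pot, sweeps = sweeps)
  }
  structure(list(config = config, n_chr = n_chr, a = a, b = b,
                 boundary_radius = boundary_radius,
                 potential_name = potential_name, seed = seed),
            class = "plate_truth")
}

#' Render a plate ground truth as a two-channel image
#'
#' Chromosome channel: blurred indicator of the ellipse union. Microtubule
#' channel: blurred indicator of the boundary disk minus the dilated
#' ellipses (the voids around chromosomes exclude microtubules).
#'
#' @param truth A [make_plate_truth()] result.
#' @param pixel_size Pixel size (um).
#' @param psf_sd Gaussian point-spread sigma (um).
#' @param noise Additive Gaussian noise SD (intensity units of a 0-1
#'   indicator).
#' @param void_margin Dilation margin (um) between a chromosome and its
#'   microtubule-free void.
#' @return List of class `"plate_image"`: `chromosomes`, `microtubules`,
#'   `pixel_size`, and the generating `truth`.
#' @export
render_plate_image <- function(truth, pixel_size = 0.1, psf_sd = 0.17,
                               noise = 0, void_margin = 0.15) {
  ras <- rasterize_config(truth$config, pixel_size)
  chrom <- ras$mask
  grown <- rasterize_config(grow_config(truth$config, 2 * void_margin),
                            pixel_size)$mask
  mt <- ras$boundary * (1L - grown)
  blur <- function(m) gaussian_blur(m, psf_sd / pixel_size)
  ch <- blur(chrom); mtb <- blur(mt)
  if (noise > 0) {
    ch <- ch + matrix(rnorm(length(ch), sd = noise), nrow(ch))
    mtb <- mtb + matrix(rnorm(length(mtb), sd = noise), nrow(mtb))
  }
  structure(list(chromosomes = ch, microtubules = mtb,
                 pixel_size = pixel_size, truth = truth),
            class = "plate_image")
}

# enlarge every ellipse of a configuration by `extra` on both full axes
grow_config <- function(config, extra) {
  out <- config
  attr(out, "a") <- attr(config, "a") + extra
  attr(out, "b") <- attr(config, "b") + extra
  out
}

#' Render a synthetic two-channel confocal stack around the plate
#'
#' Extrudes a plate ground truth into a thin 3D slab (chromosomes) plus a
#' microtubule background that excludes the chromosome voids, optionally
#' tilting the plate normal away from the stack axis; used to exercise
#' plate reslicing with known orientation.
#'
#' @param truth A [make_plate_truth()] result.
#' @param voxel_size Length-3 voxel size (um), order `[y, z, x]`.
#' @param thickness Chromosome slab thickness along the spindle axis (um).
#' @param tilt_deg Tilt of the plate normal away from the stack x-axis
#'   (rotation in the x-y plane, degrees).
#' @param extent_x Stack half-extent along x (um).
#' @return List: `chromosomes`, `microtubules` (arrays `[y, z, x]`),
#'   `voxel_size`, `normal` (true plate normal).
#' @export
render_confocal_stack <- function(truth, voxel_size = c(0.2, 0.2, 0.4),
                                  thickness = 1.6, tilt_deg = 0,
                                  extent_x = 4) {
  R <- truth$boundary_radius
  cfg <- truth$config
  ny <- 2L * ceiling((R + 1) / voxel_size[1])
  nz <- 2L * ceiling((R + 1) / voxel_size[2])
  nxs <- 2L * ceiling(extent_x / voxel_size[3])
  ys <- ((seq_len(ny)) - 0.5) * voxel_size[1] - ny / 2 * voxel_size[1]
  zs <- ((seq_len(nz)) - 0.5) * voxel_size[2] - nz / 2 * voxel_size[2]
  xs <- ((seq_len(nxs)) - 0.5) * voxel_size[3] - nxs / 2 * voxel_size[3]
  co <- expand.grid(y = ys, z = zs, x = xs)
  tl <- tilt_deg * pi / 180
  # plate frame: rotate (x, y) by -tilt so the plate normal is
  # (cos tilt, sin tilt, 0) in stack coordinates
  xp <- cos(tl) * co$x + sin(tl) * co$y
  yp <- -sin(tl) * co$x + cos(tl) * co$y
  zp <- co$z
  A <- truth$a / 2; B <- truth$b / 2
  chrom <- rep(FALSE, nrow(co))
  inslab <- abs(xp) <= thickness / 2
  for (k in seq_len(nrow(cfg))) {
    dy <- yp - cfg$x[k]; dz <- zp - cfg$y[k]
    cs <- cos(cfg$phi[k]); sn <- sin(cfg$phi[k])
    u <- cs * dy + sn * dz; v <- -sn * dy + cs * dz
    chrom <- chrom | (inslab & (u / A)^2 + (v / B)^2 <= 1)
  }
  indisk <- yp^2 + zp^2 <= R^2
  mt <- indisk & !chrom
  dim3 <- c(ny, nz, nxs)
  list(chromosomes = array(as.numeric(chrom), dim3),
       microtubules = array(as.numeric(mt), dim3),
       voxel_size = voxel_size,
       normal = c(sin(tl), 0, cos(tl)))  # (y, z, x) order
}
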