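# Raster helpers shared across modules. Images are plain numeric matrices,
# row i / column j with pixel centers at ((j - 0.5) dx, (i - 0.5) dx) in
# physical units; movies are ny x nx x nt arrays.

# Angular FFT frequencies (rad per unit) for n samples with spacing dx,
# in standard fft layout (0, +, ..., -).
fft_freq <- function(n, dx = 1) {
  k <- c(0:(n %/% 2), if (n > 2) -((n - n %/% 2 - 1):1))
  2 * pi * k[seq_len(n)] / (n * dx)
}

# Isotropic Gaussian blur, sigma in pixels.
gaussian_blur <- function(img, sigma_px) {
  if (sigma_px <= 0) return(img)
  as.matrix(EBImage::gblur(img, sigma = sigma_px, radius = max(3L, 2L * ceiling(3 * sigma_px) + 1L)))
}

# Gradient magnitude by central differences (per pixel; divide by pixel size
# for physical units if needed).
gradient_mag <- function(img) {
  ny <- nrow(img); nx <- ncol(img)
  gx <- img; gy <- img
  gx[, 2:(nx - 1)] <- (img[, 3:nx] - img[, 1:(nx - 2)]) / 2
  gx[, c(1, nx)] <- 0
  gy[2:(ny - 1), ] <- (img[3:ny, ] - img[1:(ny - 2), ]) / 2
  gy[c(1, ny), ] <- 0
  sqrt(gx^2 + gy^2)
}

# Bilinear sampling of img at fractional pixel-index coordinates (col, row),
# 1-based. Points outside the image return `fill`.
bilinear_sample <- function(img, col, row, fill = 0) {
  ny <- nrow(img); nx <- ncol(img)
  j0 <- floor(col); i0 <- floor(row)
  fj <- col - j0; fi <- row - i0
  ok <- j0 >= 1 & j0 <= nx - 1 & i0 >= 1 & i0 <= ny - 1
  out <- rep(fill, length(col))
  if (!any(ok)) return(out)
  j0 <- j0[ok]; i0 <- i0[ok]; fj <- fj[ok]; fi <- fi[ok]
  idx <- function(i, j) (j - 1) * ny + i
  v <- img[idx(i0, j0)] * (1 - fi) * (1 - fj) +
    img[idx(i0 + 1, j0)] * fi * (1 - fj) +
    img[idx(i0, j0 + 1)] * (1 - fi) * fj +
    img[idx(i0 + 1, j0 + 1)] * fi * fj
  out[ok] <- v
  out
}

# Rigid resampling: output pixel p is sampled from the input at
# R(-rot) %*% (p - center) + center - shift, i.e. the returned image is the
# input translated by `shift` (pixels, c(dx, dy)) and rotated by `rot` (rad,
# counter-clockwise about `center`).
warp_rigid <- function(img, shift = c(0, 0), rot = 0, center = NULL, fill = 0) {
  ny <- nrow(img); nx <- ncol(img)
  if (is.null(center)) center <- c((nx + 1) / 2, (ny + 1) / 2)
  jj <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  ii <- matrix(seq_len(ny), ny, nx)
  xc <- jj - center[1]; yc <- ii - center[2]
  cs <- cos(-rot); sn <- sin(-rot)
  src_col <- cs * xc - sn * yc + center[1] - shift[1]
  src_row <- sn * xc + cs * yc + center[2] - shift[2]
  matrix(bilinear_sample(img, as.vector(src_col), as.vector(src_row), fill = fill),
         nrow = ny)
}

# Rigid resampling for a nematic angle field: the doubled-angle vector field
# (cos 2 theta, sin 2 theta) is resampled component-wise (avoiding averaging
# across the mod-pi branch cut) and the frame rotation is added to the
# angle *values* so that orientations transform as directions, not scalars.
warp_angle_rigid <- function(theta, shift = c(0, 0), rot = 0, center = NULL) {
  c2 <- warp_rigid(cos(2 * theta), shift, rot, center, fill = NA_real_)
  s2 <- warp_rigid(sin(2 * theta), shift, rot, center, fill = NA_real_)
  out <- atan2(s2, c2) / 2 + rot
  out[is.na(out)] <- 0
  wrap_nematic(out)
}

# Mean over a disk neighbourhood of the given pixel radius, with replicated
# borders (each pixel's mean uses only in-image samples via mask
# normalization).
disk_mean <- function(img, radius_px) {
  if (radius_px < 1) abort("disk radius must be at least 1 pixel")
  if (radius_px >= sqrt(nrow(img)^2 + ncol(img)^2)) {
    # disk covers the whole image from every pixel: global mean
    return(matrix(mean(img), nrow(img), ncol(img)))
  }
  r <- ceiling(radius_px)
  d <- 2L * r + 1L
  k <- matrix(0, d, d)
  cx <- r + 1
  for (i in seq_len(d)) for (j in seq_len(d)) {
    if ((i - cx)^2 + (j - cx)^2 <= radius_px^2) k[i, j] <- 1
  }
  num <- as.matrix(EBImage::filter2(img, k, boundary = 0))
  den <- as.matrix(EBImage::filter2(matrix(1, nrow(img), ncol(img)), k, boundary = 0))
  num / den
}

# Connected-component labelling of a binary mask (4-connectivity, matching
# the component-count contract used for chromosome sections).
label_components <- function(mask) {
  ny <- nrow(mask); nx <- ncol(mask)
  lab <- matrix(0L, ny, nx)
  cur <- 0L
  idx_all <- which(mask > 0)
  for (start in idx_all) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue) > 0) {
      p <- queue
      queue <- integer(0)
      i <- (p - 1L) %% ny + 1L
      j <- (p - 1L) %/% ny + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        ii <- i + d[1]; jj <- j + d[2]
        keep <- ii >= 1L & ii <= ny & jj >= 1L & jj <= nx
        q <- (jj[keep] - 1L) * ny + ii[keep]
        q <- q[mask[q] > 0 & lab[q] == 0L]
        if (length(q)) {
          lab[q] <- cur
          queue <- c(queue, unique(q))
        }
      }
    }
  }
  lab
}

# Largest connected component of a binary mask.
largest_component <- function(mask) {
  lab <- label_components(mask)
  if (max(lab) == 0L) return(mask * 0L)
  sizes <- tabulate(lab[lab > 0L])
  (lab == which.max(sizes)) * 1L
}
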