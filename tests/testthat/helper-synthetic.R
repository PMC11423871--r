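# Shared synthetic fixtures, built in code at test time.

# small, fast, noiseless static spindle movie
quiet_spindle <- function(n_frames = 2, pixel_size = 0.4, ...) {
  spindle_truth(n_frames = n_frames, pixel_size = pixel_size,
                fluct = fluct_params(amplitude = 0), noise_sd = 0,
                angle_noise_sd = 0, ...)
}

mean_retardance <- function(movie) apply(movie$retardance, c(1, 2), mean)

# disk boundary mask matching a rendered plate image frame
disk_boundary <- function(n, pixel_size, radius) {
  g <- nemspindle:::pixel_grid(n, n, pixel_size)
  (g$x^2 + g$y^2 <= radius^2) * 1L
}

# Brute-force oracle for the two-void interaction: numerically integrate the
# cross term of the one-constant Frank energy, grad(theta_A).grad(theta_B),
# over the plane. Core 1/r singularities are regularized by subtracting, in
# a small disk around each defect, that core's rotational field times the
# other cluster's local gradient (a term whose disk integral vanishes by
# angular symmetry).
frank_cross_energy <- function(q, d, rc = 0.12, h_coarse = 0.05,
                               h_fine = 0.01, extent = 40) {
  A <- q$defects
  B <- A; B$y <- B$y + d
  grad_one <- function(k, x0, y0, X, Y) {
    dx <- X - x0; dy <- Y - y0; r2 <- dx^2 + dy^2
    list(gx = k * (-dy) / r2, gy = k * dx / r2)
  }
  grad_sum <- function(defs, X, Y) {
    gx <- 0; gy <- 0
    for (i in seq_len(nrow(defs))) {
      g <- grad_one(defs$k[i], defs$x[i], defs$y[i], X, Y)
      gx <- gx + g$gx; gy <- gy + g$gy
    }
    list(gx = gx, gy = gy)
  }
  integ <- function(x0, x1, y0, y1, h, skip = NULL) {
    xs <- seq(x0 + h / 2, x1 - h / 2, by = h)
    ys <- seq(y0 + h / 2, y1 - h / 2, by = h)
    tot <- 0
    for (chunk in split(seq_along(ys), ceiling(seq_along(ys) / 300))) {
      Y <- matrix(ys[chunk], length(chunk), length(xs))
      X <- matrix(xs, length(chunk), length(xs), byrow = TRUE)
      gA <- grad_sum(A, X, Y); gB <- grad_sum(B, X, Y)
      v <- gA$gx * gB$gx + gA$gy * gB$gy
      for (set in list(list(A, B), list(B, A))) {
        own <- set[[1]]; oth <- set[[2]]
        for (i in seq_len(nrow(own))) {
          chi <- (X - own$x[i])^2 + (Y - own$y[i])^2 < rc^2
          if (!any(chi)) next
          cb <- unlist(grad_sum(oth, own$x[i], own$y[i]))
          g1 <- grad_one(own$k[i], own$x[i], own$y[i], X, Y)
          v[chi] <- v[chi] - (g1$gx * cb[1] + g1$gy * cb[2])[chi]
        }
      }
      if (!is.null(skip)) {
        v[X > skip[1] & X < skip[2] & Y > skip[3] & Y < skip[4]] <- 0
      }
      tot <- tot + sum(v) * h^2
    }
    tot
  }
  box <- c(min(A$x) - 0.9, max(A$x) + 0.9, -1.0, d + 1.0)
  integ(-extent, extent, -extent, extent, h_coarse, skip = box) +
    integ(box[1], box[2], box[3], box[4], h_fine)
}

# banded void mask in a square box (bands along x, spaced along y)
band_mask <- function(n, pixel_size, centers, half_width) {
  g <- nemspindle:::pixel_grid(n, n, pixel_size)
  m <- matrix(0L, n, n)
  for (yc in centers) m[abs(g$y - yc) <= half_width] <- 1L
  m
}
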