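make_voided_spindle <- function(n_voids = 20, ab = 0.7, seed = 2,
                                pixel_size = 0.2) {
  set.seed(seed)
  pl <- random_placement(n_voids, a = 1.5, b = 1.5, boundary_radius = 6.3)
  voids <- lapply(seq_len(n_voids), function(k) {
    void_truth(center = c(0, pl$x[k], pl$y[k]), beta = 11, a = ab, b = ab)
  })
  quiet_spindle(pixel_size = pixel_size, voids = voids)
}

test_that("an exact semicircular profile inverts to machine precision", {
  px <- 0.1
  ys <- ((1:200) - 0.5) * px - 10
  img <- matrix(0, 200, 9)
  for (j in 1:9) img[, j] <- 2 * 7.5 * 50 * sqrt(pmax(64 - ys^2, 0)) * 1e-3
  prof <- fit_cross_sections(img, px, R_mode = "free")
  expect_equal(prof$rho[5], 50, tolerance = 1e-4)
  expect_equal(prof$R[5], 8, tolerance = 1e-3)
})

test_that("voids depress the central density by the built-in area fraction", {
  tr <- make_voided_spindle()
  prof <- fit_cross_sections(mean_retardance(render_polscope_movie(tr)), 0.2)
  area_true <- 20 * pi * 0.7^2 / (pi * 8^2)        # 15.3% of the plate
  vf <- void_fractions(prof)
  expect_lt(abs(vf$plate_area_fraction - area_true), 0.025)
  # the same attribution read off the normalized profile at the center
  p <- prof[prof$ok, ]
  expect_lt(abs(mean(p$rho_rel[abs(p$x) < 0.5]) - (1 - area_true)), 0.025)
})

test_that("void volume fraction is recovered within a percentage point", {
  tr <- make_voided_spindle()
  prof <- fit_cross_sections(mean_retardance(render_polscope_movie(tr)), 0.2)
  h2 <- integrate(function(u) nemspindle:::void_profile_unit(u, 11)^2,
                  -5.5, 5.5)$value
  vol_voids <- 20 * pi * 0.7^2 * h2
  vol_true <- vol_voids / (tactoid_volume(tr$tac) + vol_voids)
  vf <- void_fractions(prof)
  expect_lt(abs(vf$volume_fraction - vol_true), 0.012)
})

test_that("void-free spindles give zero void fractions", {
  tr <- quiet_spindle(pixel_size = 0.25)
  prof <- fit_cross_sections(mean_retardance(render_polscope_movie(tr)), 0.25)
  vf <- void_fractions(prof)
  expect_lt(abs(vf$volume_fraction), 0.01)
  expect_lt(abs(vf$plate_area_fraction), 0.01)
})

test_that("a constant 10% deficit gives exactly 10% volume", {
  prof <- tibble::tibble(x = seq(-5, 5, 0.5), rho = 0.9, R = 5,
                         rms = 0, n = 50, ok = TRUE, rho_rel = 0.9)
  class(prof) <- c("density_profile", class(prof))
  vf <- void_fractions(prof)
  expect_equal(vf$volume_fraction, 0.1, tolerance = 1e-12)
})

test_that("noise leaves the inversion bias small", {
  tr <- make_voided_spindle()
  mr <- mean_retardance(render_polscope_movie(tr))
  set.seed(9)
  noisy <- mr + matrix(rnorm(length(mr), sd = 0.05 * max(mr)), nrow(mr))
  p0 <- fit_cross_sections(mr, 0.2, threshold = 0.08 * max(mr))
  p1 <- fit_cross_sections(noisy, 0.2, threshold = 0.08 * max(mr))
  m0 <- p0$rho_rel[p0$ok & abs(p0$x) < 0.5]
  m1 <- p1$rho_rel[p1$ok & abs(p1$x) < 0.5]
  expect_lt(abs(mean(m1) - mean(m0)), 0.02)
})

test_that("column radii agree with the tactoid silhouette", {
  tr <- make_voided_spindle()
  prof <- fit_cross_sections(mean_retardance(render_polscope_movie(tr)), 0.2)
  p <- prof[prof$ok & abs(prof$x) < 10, ]
  truth <- nemspindle:::tactoid_outer_radius(tr$tac, p$x)
  expect_lt(max(abs(p$R - truth) / truth), 0.03)
})

test_that("arc width profile obeys the sagitta relation", {
  # three-point circle construction: (0, w/2), (+-beta/2, 0)
  w <- 1.3; beta <- 9
  d <- nemspindle:::arc_width(c(0, beta / 2, -beta / 2, beta), w, beta)
  expect_equal(d, c(w, 0, 0, 0), tolerance = 1e-12)
  x1 <- 2.2
  rc <- beta^2 / (8 * (w / 2)) + w / 4
  expect_equal(nemspindle:::arc_width(x1, w, beta),
               2 * (sqrt(rc^2 - x1^2) - rc + w / 2), tolerance = 1e-12)
})

test_that("void waist and length are recovered within 15%", {
  tr <- make_voided_spindle()
  prof <- fit_cross_sections(mean_retardance(render_polscope_movie(tr)), 0.2)
  vs <- void_width_profile(prof, n_chr = 20)
  expect_equal(vs$waist, 2 * 0.7, tolerance = 0.15 * 1.4)
  expect_equal(vs$beta, 11, tolerance = 0.15 * 11)
})

test_that("the waist estimates the geometric mean across aspect ratios", {
  # same waist area (a*b fixed), growing anisotropy
  for (ar in c(1, 2.5)) {
    ab <- 0.7
    a <- ab * sqrt(ar); b <- ab / sqrt(ar)
    set.seed(4)
    # clearance circles of full axis 2a guarantee the voids stay disjoint
    pl <- random_placement(10, a = 2 * a, b = 2 * a, boundary_radius = 6.3)
    voids <- lapply(seq_len(10), function(k) {
      void_truth(center = c(0, pl$x[k], pl$y[k]), beta = 11, a = a, b = b,
                 psi = runif(1, 0, pi))
    })
    tr <- quiet_spindle(pixel_size = 0.2, voids = voids)
    prof <- fit_cross_sections(mean_retardance(render_polscope_movie(tr)), 0.2)
    vs <- void_width_profile(prof, n_chr = 10)
    expect_equal(vs$waist, 2 * sqrt(a * b), tolerance = 0.15)
  }
})

test_that("doubling the assumed void count scales the waist by 1/sqrt(2)", {
  tr <- make_voided_spindle()
  prof <- fit_cross_sections(mean_retardance(render_polscope_movie(tr)), 0.2)
  w20 <- void_width_profile(prof, n_chr = 20)$waist
  w40 <- void_width_profile(prof, n_chr = 40)$waist
  expect_equal(w40 / w20, 1 / sqrt(2), tolerance = 0.02)
})
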