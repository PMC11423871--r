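ordered_truth <- function(n = 18, seed = 8, sweeps = 600) {
  set.seed(seed)
  cfg <- anneal_plate(n = n, potential = chromo_potential("inv5", u_ref = 3),
                      sweeps = sweeps)
  structure(list(config = cfg, n_chr = n, a = 2.1, b = 0.8,
                 boundary_radius = 6.5), class = "plate_truth")
}

test_that("reslicing recovers the plate plane of a tilted stack", {
  truth <- make_plate_truth(n_chr = 12, seed = 3)
  # aligned stack: identity reslice
  st0 <- render_confocal_stack(truth, tilt_deg = 0)
  p0 <- reslice_to_plate(st0)
  expect_lt(acos(abs(sum(p0$normal * st0$normal))) * 180 / pi, 1)
  # 30-degree tilt
  st <- render_confocal_stack(truth, tilt_deg = 30)
  p <- reslice_to_plate(st)
  expect_lt(acos(abs(sum(p$normal * st$normal))) * 180 / pi, 2)
  # the resliced chromosome channel contains the sections
  expect_gt(sum(p$chromosomes > 0.5), 200)
})

test_that("an empty chromosome channel is an orientation error", {
  truth <- make_plate_truth(n_chr = 5, seed = 3)
  st <- render_confocal_stack(truth)
  st$chromosomes[] <- 0
  expect_error(reslice_to_plate(st),
               class = "nemspindle_orientation_undefined")
})

test_that("segmentation counts well-separated sections and applies the 19-20 rule", {
  truth <- ordered_truth(n = 18)
  img <- render_plate_image(truth, pixel_size = 0.1, psf_sd = 0.17,
                            noise = 0.02)
  seg <- segment_chromosomes(img)
  expect_equal(seg$n_chr, 18)
  expect_false(seg$accepted)          # 18 is outside the 19-20 window
  # counts inside the window are accepted
  truth20 <- ordered_truth(n = 20, seed = 12)
  seg20 <- segment_chromosomes(render_plate_image(truth20, noise = 0.02))
  expect_true(seg20$n_chr <= 20)
  expect_identical(seg20$accepted, seg20$n_chr >= 19 && seg20$n_chr <= 20)
  # sparse plates are rejected by the same rule
  truth8 <- make_plate_truth(n_chr = 8, seed = 4)
  seg8 <- segment_chromosomes(render_plate_image(truth8, noise = 0.02))
  expect_false(seg8$accepted)
})

test_that("an empty plate raises an empty-plate error", {
  img <- matrix(0, 80, 80)
  expect_error(segment_chromosomes(img, pixel_size = 0.1),
               class = "nemspindle_empty_plate")
})

test_that("second-moment ellipses recover ideal masks within 5%", {
  px <- 0.05
  g <- nemspindle:::pixel_grid(120, 120, px)
  phi0 <- 0.4
  u <- cos(phi0) * g$x + sin(phi0) * g$y
  v <- -sin(phi0) * g$x + cos(phi0) * g$y
  mask <- ((u / 1.05)^2 + (v / 0.4)^2 <= 1) * 1L
  plate <- list(labels = mask, pixel_size = px)
  es <- fit_ellipses(plate)
  expect_equal(es$a, 2.1, tolerance = 0.05)
  expect_equal(es$b, 0.8, tolerance = 0.05)
  expect_lt(abs(nematic_diff(es$phi, phi0)), 0.02)
  expect_equal(es$area, pi * 1.05 * 0.4, tolerance = 0.05)
  # a circle has no defined orientation
  circ <- (g$x^2 + g$y^2 <= 1) * 1L
  ec <- fit_ellipses(list(labels = circ, pixel_size = px))
  expect_true(ec$round)
  expect_true(is.na(ec$phi))
})

test_that("tiny components are flagged and excluded from the summary", {
  lab <- matrix(0L, 40, 40)
  lab[10:20, 10:16] <- 1L
  lab[30, 30] <- 2L
  es <- fit_ellipses(list(labels = lab, pixel_size = 0.1))
  expect_true(es$flagged[2])
  expect_equal(attr(es, "summary")$n, 1)
})

test_that("segmentation-ellipse-mask round trip has high overlap", {
  truth <- ordered_truth(n = 18)
  img <- render_plate_image(truth, pixel_size = 0.1, psf_sd = 0.17,
                            noise = 0.02)
  seg <- segment_chromosomes(img)
  es <- fit_ellipses(seg)
  nb <- nrow(seg$mask); px <- seg$pixel_size
  g <- nemspindle:::pixel_grid(nb, nb, px)
  render <- matrix(0L, nb, nb)
  for (k in seq_len(nrow(es))) {
    if (es$flagged[k]) next
    dx <- g$x - (es$cx[k] - nb * px / 2); dy <- g$y - (es$cy[k] - nb * px / 2)
    ph <- ifelse(is.na(es$phi[k]), 0, es$phi[k])
    u <- cos(ph) * dx + sin(ph) * dy; v <- -sin(ph) * dx + cos(ph) * dy
    render[(u / (es$a[k] / 2))^2 + (v / (es$b[k] / 2))^2 <= 1] <- 1L
  }
  jac <- sum(render & seg$mask) / sum(render | seg$mask)
  expect_gte(jac, 0.8)
})

test_that("pair correlation satisfies its exact identities", {
  n <- 80; px <- 0.1
  bnd <- disk_boundary(n, px, 3.5)
  # all-white mask: g = 1 everywhere
  g1 <- pair_correlation(bnd, bnd, px)
  expect_equal(g1$gii, rep(1, nrow(g1)), tolerance = 1e-9)
  # white fraction phi: g(0) = 1/phi
  set.seed(6)
  rnd <- matrix(rbinom(n * n, 1, 0.2), n, n) * bnd
  g2 <- pair_correlation(rnd, bnd, px)
  expect_equal(g2$gii[g2$s == 0], sum(bnd) / sum(rnd), tolerance = 1e-9)
})

test_that("edge correction keeps random masks flat at any density", {
  n <- 80; px <- 0.1
  bnd <- disk_boundary(n, px, 3.5)
  for (dens in c(0.15, 0.5)) {
    set.seed(round(100 * dens))
    curves <- lapply(1:20, function(r) {
      m <- matrix(rbinom(n * n, 1, dens), n, n) * bnd
      gi <- pair_correlation(m, bnd, px, s_max = 6)
      gi$replicate <- r
      gi
    })
    curves <- dplyr::bind_rows(curves)
    mc <- dplyr::summarise(dplyr::group_by(curves, s),
                           m = mean(gii), se = sd(gii) / sqrt(20),
                           .groups = "drop")
    mc <- mc[mc$s > 0 & mc$s < 5, ]
    expect_true(all(abs(mc$m - 1) < pmax(3 * mc$se, 0.02)))
    expect_equal(nrow(gii_extrema(curves, n_boot = 0)), 0)
  }
})

test_that("pair correlation is stable under pixel-size halving", {
  truth <- ordered_truth(n = 18)
  r1 <- rasterize_config(truth$config, 0.1)
  r2 <- rasterize_config(truth$config, 0.05)
  g1 <- pair_correlation(r1$mask, r1$boundary, 0.1, s_max = 6)
  g2 <- pair_correlation(r2$mask, r2$boundary, 0.05, s_max = 6)
  m <- merge(as.data.frame(g1), as.data.frame(g2), by = "s")
  m <- m[m$s > 0.2 & m$s < 5, ]
  expect_lt(max(abs(m$gii.y - m$gii.x) / m$gii.x), 0.05)
})

test_that("bootstrap extrema report the curve structure with uncertainty", {
  set.seed(14)
  s <- seq(0, 6, 0.1)
  curves <- dplyr::bind_rows(lapply(1:15, function(r) {
    g <- 1 + 4 * exp(-s / 0.4) - 0.6 * exp(-(s - 1.3)^2 / 0.18) +
      0.25 * exp(-(s - 2.4)^2 / 0.3) + rnorm(length(s), sd = 0.02)
    tibble::tibble(replicate = r, s = s, gii = g)
  }))
  ext <- gii_extrema(curves, n_boot = 100)
  expect_equal(nrow(ext), 1)
  expect_lt(abs(ext$s_min - 1.3), 0.15)
  expect_lt(abs(ext$s_max - 2.4), 0.2)
  expect_true(is.finite(ext$s_min_ci) && ext$s_min_ci < 0.2)
  # n_boot = 0: extrema with undefined CI
  e0 <- gii_extrema(curves, n_boot = 0)
  expect_true(is.na(e0$s_min_ci))
})
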