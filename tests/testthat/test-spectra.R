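test_that("fluctuation extraction reproduces trivial identities", {
  tr <- quiet_spindle(n_frames = 2, pixel_size = 0.25)
  mv <- render_polscope_movie(tr)
  fl <- compute_fluctuations(mv, L0 = 15.2, lambda0 = 8)
  expect_lt(max(abs(fl$dny)), 1e-10)
  # constant offset propagates
  mv2 <- mv
  mv2$slow_axis <- wrap_nematic(mv2$slow_axis + 0.1)
  fl2 <- compute_fluctuations(mv2, L0 = 15.2, lambda0 = 8)
  expect_equal(mean(fl2$dny), 0.1, tolerance = 1e-6)
})

test_that("rendered fluctuation amplitude is recovered in the box", {
  tr <- spindle_truth(n_frames = 20, pixel_size = 0.25,
                      fluct = fluct_params(amplitude = 0.05,
                                           correlation_time = 2),
                      noise_sd = 0, angle_noise_sd = 0)
  mv <- render_polscope_movie(tr)
  fl <- compute_fluctuations(mv, L0 = 15.2, lambda0 = 8)
  expect_equal(sqrt(mean(fl$dny^2)), 0.05, tolerance = 0.1 * 0.05)
})

test_that("white noise has a flat equal-time spectrum", {
  set.seed(5)
  w <- array(rnorm(48 * 48 * 16), c(48, 48, 16))
  sl <- slice_qy(fluct_spectrum(w, lambda_im = Inf, pixel_size = 0.125,
                                frame_interval = 4), 6)
  slope <- unname(coef(lm(log(snn) ~ log(qy), data = sl))[2])
  expect_lt(abs(slope), 0.15)
})

test_that("integrated spectral weight satisfies Parseval", {
  f <- sample_fluctuation_field(fluct_params(amplitude = 0.04), 48, 48, 16,
                                0.125, 4, seed = 2)
  sp <- fluct_spectrum(f, lambda_im = Inf, pixel_size = 0.125,
                       frame_interval = 4)
  expect_lt(abs(spectrum_weight(sp) / mean(f^2) - 1), 0.05)
})

test_that("the diffraction cutoff removes exactly the high-q ring weight", {
  f <- sample_fluctuation_field(fluct_params(amplitude = 0.04), 48, 48, 8,
                                0.125, 4, seed = 2)
  full <- fluct_spectrum(f, lambda_im = Inf, pixel_size = 0.125,
                         frame_interval = 4)
  cut <- fluct_spectrum(f, lambda_im = 0.530, pixel_size = 0.125,
                        frame_interval = 4)
  qmag <- sqrt(outer(full$qy^2, full$qx^2, "+"))
  ring <- sum(full$snn[qmag > 2 * pi / 0.530]) * full$dq[1] * full$dq[2] / (2 * pi)^2
  expect_equal(spectrum_weight(full) - spectrum_weight(cut), ring,
               tolerance = 1e-12)
})

test_that("spectra are invariant to doubling the mirror padding", {
  f <- sample_fluctuation_field(fluct_params(amplitude = 0.04), 32, 32, 8,
                                0.25, 4, seed = 4)
  s1 <- slice_qy(fluct_spectrum(f, lambda_im = Inf, pixel_size = 0.25,
                                frame_interval = 4), 8)
  s2 <- slice_qy(fluct_spectrum(f, lambda_im = Inf, pad_factor = 2L,
                                pixel_size = 0.25, frame_interval = 4), 8)
  common <- merge(round(as.data.frame(s1), 10), round(as.data.frame(s2), 10),
                  by = "qy")
  expect_gt(nrow(common), 10)
  expect_equal(common$snn.y, common$snn.x, tolerance = 0.02)
})

test_that("regularly spaced boosted voids imprint a peak at their spacing", {
  spacing <- 2.4
  acc <- NULL
  for (s in 1:8) {
    set.seed(400 + s)
    centers <- seq(-3.6, 3.6, by = spacing) + runif(4, -0.4, 0.4)
    mask <- band_mask(64, 0.125, centers, 0.65)
    f <- sample_fluctuation_field(
      fluct_params(amplitude = 0.05, void_boost = 2.5, correlation_time = 2),
      64, 64, 48, 0.125, 4, void_mask = mask, seed = s)
    sl <- slice_qy(fluct_spectrum(f, lambda_im = Inf, pixel_size = 0.125,
                                  frame_interval = 4), 8)
    acc <- if (is.null(acc)) sl$snn else acc + sl$snn
  }
  sl$snn <- acc / 8
  pk <- find_spectral_peak(sl)
  expect_equal(nrow(pk), 1)
  expect_lt(abs(pk$qy_star - 2 * pi / spacing), 0.4)
  expect_lt(abs(pk$lambda_star - spacing), 0.4)
})

test_that("homogeneous power-law fields show no spectral peak", {
  acc <- NULL
  for (s in 1:6) {
    f <- sample_fluctuation_field(
      fluct_params(amplitude = 0.05, correlation_time = 2),
      64, 64, 48, 0.125, 4, seed = 100 + s)
    sl <- slice_qy(fluct_spectrum(f, lambda_im = Inf, pixel_size = 0.125,
                                  frame_interval = 4), 8)
    acc <- if (is.null(acc)) sl$snn else acc + sl$snn
  }
  sl$snn <- acc / 6
  expect_equal(nrow(find_spectral_peak(sl)), 0)
})

test_that("local binarization follows its defining identities", {
  # the >= in the definition maps any locally constant region to 1
  expect_true(all(local_binarize(matrix(3, 20, 20), 0.25, 2) == 1L))
  # step image, direct evaluation: locally constant regions (both halves,
  # away from the step) map to 1; the dark side of the transition band sees
  # an elevated local mean and maps to 0
  img <- cbind(matrix(0, 40, 20), matrix(1, 40, 20))
  m <- local_binarize(img, 0.25, 2)      # radius 8 px, step at column 20|21
  expect_true(all(m[, 1:11] == 1L))      # dark, beyond the band
  expect_true(all(m[, 13:20] == 0L))     # dark side of the band
  expect_true(all(m[, 21:40] == 1L))     # bright half
  expect_error(local_binarize(img, 0.25, 0.1))
  # radius covering the whole image: global-threshold behaviour
  g <- local_binarize(img, 1, 60)
  expect_equal(g, (img >= mean(img)) * 1L)
})

test_that("density-fluctuation coupling detects the built-in void boost", {
  # A row of voids with boosted fluctuations: the local-binarization classes
  # only partly coincide with the true void footprints, so the class ratio
  # is a diluted readout of the built-in boost -- detectably above one,
  # bounded by the truth, zero for no boost, and monotone in the boost.
  ratio_for <- function(boost, seed) {
    voids <- make_void_row(3, spacing = 2.4, beta = 11, a = 0.7, b = 0.36)
    tr <- spindle_truth(voids = voids, n_frames = 30, pixel_size = 0.25,
                        fluct = fluct_params(amplitude = 0.05,
                                             void_boost = boost,
                                             correlation_time = 2),
                        noise_sd = 0, angle_noise_sd = 0, seed = seed)
    mv <- render_polscope_movie(tr)
    fl <- compute_fluctuations(mv, L0 = 15.2, lambda0 = 8)
    nb <- dim(fl$dny)[1]
    i0 <- (dim(mv$retardance)[1] - nb) %/% 2
    j0 <- (dim(mv$retardance)[2] - nb) %/% 2
    ret_box <- apply(mv$retardance[i0 + 1:nb, j0 + 1:nb, , drop = FALSE],
                     c(1, 2), mean)
    absd <- apply(abs(fl$dny), c(1, 2), mean)
    density_fluctuation_coupling(ret_box, absd, 0.25)
  }
  avg <- function(boost, seeds) {
    rs <- purrr::map_dfr(seeds, function(sd) ratio_for(boost, sd))
    list(ratio = mean(rs$ratio), slope = mean(rs$slope))
  }
  r107 <- avg(1.07, 101:106)
  expect_gt(r107$ratio, 1.01)            # coupling detected
  expect_lt(r107$ratio, 1.09)            # bounded by the built-in boost
  r100 <- avg(1, 107:112)
  expect_lt(abs(r100$ratio - 1.00), 0.02)
  r120 <- avg(1.2, 101:106)
  expect_gt(r120$ratio, r107$ratio)      # monotone in the boost
  expect_lt(r120$slope, 0)               # anti-correlation with density
})
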