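test_that("pair potentials follow their defining forms", {
  inv5 <- chromo_potential("inv5", amplitude = 1)
  expect_equal(inv5(2) / inv5(1), 2^-5, tolerance = 1e-12)
  inv3 <- chromo_potential("inv3", amplitude = 1)
  expect_equal(inv3(2) / inv3(1), 2^-3, tolerance = 1e-12)
  yk <- chromo_potential("yukawa", amplitude = 1, lambda_B = 1e6)
  s <- seq(0.5, 5, 0.5)
  expect_equal(yk(s), 1 / s, tolerance = 0.01)      # Coulomb limit
  for (nm in c("inv5", "inv3", "yukawa")) {
    u <- chromo_potential(nm)(seq(0.2, 20, length.out = 200))
    expect_true(all(diff(u) < 0))
  }
  expect_equal(chromo_potential("none")(s), rep(0, length(s)))
  expect_error(inv5(-1), class = "nemspindle_domain_error")
  # default calibration: one thermal unit at the typical spacing
  expect_equal(chromo_potential("inv5")(2.4), 1, tolerance = 1e-12)
})

test_that("the quadrupole potential plugs in through interpolation", {
  q <- solve_geometry(11, 1)
  cur <- interaction_potential(q, exp(seq(log(1.2), log(60), length.out = 80)))
  pot <- chromo_potential("quadrupole_2d", curve = cur)
  expect_equal(pot(2.4), 1, tolerance = 1e-6)
  s <- seq(1.5, 12, 0.5)
  expect_true(all(diff(pot(s)) < 0))
})

test_that("Perram-Wertheim contact agrees with a point-membership oracle", {
  set.seed(17)
  overlap_mc <- function(e1, e2, n = 4000) {
    tt <- runif(n, 0, 2 * pi); rr <- sqrt(runif(n))
    px <- e1[4] * rr * cos(tt); py <- e1[5] * rr * sin(tt)
    x <- e1[1] + px * cos(e1[3]) - py * sin(e1[3])
    y <- e1[2] + px * sin(e1[3]) + py * cos(e1[3])
    dx <- x - e2[1]; dy <- y - e2[2]
    u <- dx * cos(e2[3]) + dy * sin(e2[3])
    v <- -dx * sin(e2[3]) + dy * cos(e2[3])
    any((u / e2[4])^2 + (v / e2[5])^2 <= 1)
  }
  n_checked <- 0
  for (i in 1:60) {
    e1 <- c(0, 0, runif(1, 0, pi), 1.05, 0.4)
    e2 <- c(runif(2, -2, 2), runif(1, 0, pi), 1.05, 0.4)
    F <- pw_contact_cpp(e1[1], e1[2], e1[3], e1[4], e1[5],
                        e2[1], e2[2], e2[3], e2[4], e2[5])
    mc <- overlap_mc(e1, e2) || overlap_mc(e2, e1)
    if (abs(F - 1) > 0.05) {       # skip near-tangent cases the MC can miss
      expect_identical(F < 1, mc)
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 30)
})

test_that("random placement is seed-deterministic and overlap-free", {
  set.seed(5); c1 <- random_placement()
  set.seed(5); c2 <- random_placement()
  expect_identical(c1$x, c2$x)
  expect_identical(c1$phi, c2$phi)
  expect_true(config_valid(c1))
  # all ellipses inside the disk
  ok <- vapply(seq_len(nrow(c1)), function(i) {
    ellipse_in_disk_cpp(c1$x[i], c1$y[i], c1$phi[i], 1.05, 0.4, 6.5)
  }, logical(1))
  expect_true(all(ok))
  # area coverage near 20%
  ras <- rasterize_config(c1, 0.1)
  expect_equal(sum(ras$mask) / sum(ras$boundary), 0.199, tolerance = 0.02)
})

test_that("infeasible packings raise a packing error", {
  expect_error(random_placement(n = 200, boundary_radius = 5,
                                max_attempts = 50L),
               class = "nemspindle_packing_infeasible")
})

test_that("a single ellipse lands uniformly over its admissible region", {
  set.seed(23)
  n <- 1500
  xs <- numeric(n); ys <- numeric(n)
  for (i in seq_len(n)) {
    cfg <- random_placement(1, a = 2.1, b = 0.8, boundary_radius = 6.5)
    xs[i] <- cfg$x; ys[i] <- cfg$y
  }
  r <- sqrt(xs^2 + ys^2)
  # admissible centers reach at least 6.5 - 1.05; compare the radial CDF
  # against uniform-over-disk on a conservative interior disk
  rmax <- 6.5 - 1.05
  inner <- r[r <= rmax]
  counts <- hist(inner^2 / rmax^2, breaks = seq(0, 1, 0.2),
                 plot = FALSE)$counts
  expect_gt(chisq.test(counts)$p.value, 0.001)
})

test_that("pixelated sections can be placed without overlap", {
  sec <- matrix(0L, 15, 25)
  sec[5:11, 3:23] <- 1L
  set.seed(7)
  cfg <- random_placement(sections = rep(list(sec), 6), pixel_size = 0.1,
                          boundary_radius = 6.5)
  expect_equal(nrow(cfg), 6)
  occ <- attr(cfg, "occupancy")
  # nearest-neighbour rotation changes each section's pixel count by a few
  # pixels, but no pixel may be claimed twice
  expect_lt(abs(sum(occ) - 6 * sum(sec)), 0.05 * 6 * sum(sec))
  expect_lte(max(occ), 1)
})

test_that("annealing conserves hard constraints and tracks energy", {
  set.seed(9)
  pot <- chromo_potential("inv5")
  cfg <- anneal_plate(potential = pot, sweeps = 300)
  expect_true(config_valid(cfg))
  tr <- attr(cfg, "trace")
  expect_equal(nrow(tr), 300)
  # reported running energy matches a fresh evaluation
  expect_equal(attr(cfg, "energy"), config_energy(cfg, pot),
               tolerance = 1e-6 * max(1, config_energy(cfg, pot)))
  # energy decreases in expectation along the cooling schedule
  expect_lt(mean(tr$energy[251:300]), mean(tr$energy[1:50]))
})

test_that("a null potential reproduces steric-only statistics", {
  set.seed(31)
  pot0 <- chromo_potential("none")
  r_anneal <- replicate(12, {
    cfg <- anneal_plate(potential = pot0, sweeps = 150)
    mean(sqrt(cfg$x^2 + cfg$y^2))
  })
  r_rsa <- replicate(40, {
    cfg <- random_placement()
    mean(sqrt(cfg$x^2 + cfg$y^2))
  })
  # same mean radial statistic within sampling error
  se <- sqrt(var(r_anneal) / 12 + var(r_rsa) / 40)
  expect_lt(abs(mean(r_anneal) - mean(r_rsa)), 3.5 * se + 0.05)
})

test_that("fixed-temperature sampling obeys detailed balance on a toy system", {
  # two ellipses on a line: compare MC occupancy of the separation with the
  # exact Boltzmann weight of the tabulated potential
  set.seed(41)
  pot <- chromo_potential("inv3", amplitude = 20)
  xs <- c(); n_runs <- 60
  for (r in seq_len(n_runs)) {
    cfg <- anneal_plate(n = 2, a = 1.6, b = 1.6, boundary_radius = 3.2,
                        potential = pot, sweeps = 120, T0 = 1, Tf = 1,
                        step_trans = 0.8)
    xs <- c(xs, sqrt(diff(cfg$x)^2 + diff(cfg$y)^2))
  }
  # independent brute-force oracle: Boltzmann-weighted uniform pairs
  R <- 3.2 - 0.8
  m <- 4e5
  draw <- function() {
    t1 <- runif(m, 0, 2 * pi); r1 <- R * sqrt(runif(m))
    cbind(r1 * cos(t1), r1 * sin(t1))
  }
  p1 <- draw(); p2 <- draw()
  s <- sqrt(rowSums((p1 - p2)^2))
  keep <- s > 1.6                      # hard-core exclusion of circles
  w <- exp(-pot(s[keep]))
  exact_mean <- sum(s[keep] * w) / sum(w)
  expect_lt(abs(mean(xs) / exact_mean - 1), 0.1)
})

test_that("ordering survives threefold amplitude changes", {
  base <- chromo_potential("inv5")
  locs <- vapply(c(1 / 3, 1, 3), function(f) {
    pot <- chromo_potential("inv5", amplitude = attr(base, "amplitude") * f)
    ens <- simulate_ensemble(n_replicates = 25, potential = pot, seed = 77,
                             n_boot = 0)
    expect_equal(nrow(ens$extrema), 1)
    ens$extrema$s_min
  }, numeric(1))
  expect_lt(max(locs) - min(locs), 0.25)
})

test_that("repulsive ensembles develop interior extrema; ring structure emerges", {
  ens <- simulate_ensemble(n_replicates = 30, seed = 19, n_boot = 50,
                           keep_configs = TRUE)
  expect_equal(nrow(ens$extrema), 1)
  expect_true(ens$extrema$s_min < ens$extrema$s_max)
  expect_true(is.finite(ens$extrema$s_min_ci))
  # most chromosomes sit in an outer annulus, as in imaged plates
  outer_frac <- mean(vapply(ens$configs, function(cfg) {
    mean(sqrt(cfg$x^2 + cfg$y^2) > 4.2)
  }, numeric(1)))
  expect_gt(outer_frac, 0.5)
})
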