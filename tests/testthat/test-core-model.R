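# Forward model: offset conversions, water rotating-frame relaxation,
# exchange-relayed rates and the steady-state Z-profile.

test_that("ppm/angular offset conversion is exact, signed, and invertible", {
  expect_identical(ppm_to_angular_offset(4.7, 4.7, fs700), 0)
  # 1 ppm = 700 Hz at 700 MHz
  expect_equal(ppm_to_angular_offset(5.7, 4.7, fs700), 2 * pi * 700,
               tolerance = 1e-12)
  expect_lt(ppm_to_angular_offset(3.0, 4.7, fs700), 0)  # upfield negative
  ppm <- c(-138.2, -10.3, 0, 4.7, 4.71)
  back <- angular_offset_to_ppm(ppm_to_angular_offset(ppm, 4.7, fs700),
                                4.7, fs700)
  expect_equal(back, ppm, tolerance = 1e-12)
  expect_error(ppm_to_angular_offset(NaN, 4.7, fs700),
               class = "cmt_invalid_argument")
})

test_that("r1rho_water interpolates between R1 and R2 with the expected limits", {
  w <- water_default(R1 = 0.4, R2 = 6.3)
  # far off resonance -> R1; on resonance -> R2; crossover at dw = w1
  expect_equal(r1rho_water(2 * pi * 1e8, 2 * pi * 100, w), w$R1_per_s,
               tolerance = 1e-6)
  expect_equal(r1rho_water(0, 2 * pi * 100, w), w$R2_per_s)
  expect_equal(r1rho_water(2 * pi * 250, 2 * pi * 250, w),
               (w$R1_per_s + w$R2_per_s) / 2, tolerance = 1e-12)
  dw <- 2 * pi * 10^runif(200, 0, 6) * sample(c(-1, 1), 200, TRUE)
  w1 <- 2 * pi * 10^runif(200, 1, 3)
  r <- r1rho_water(dw, w1, w)
  expect_true(all(r >= w$R1_per_s - 1e-12 & r <= w$R2_per_s + 1e-12))
  expect_error(r1rho_water(0, 0, w), class = "cmt_degenerate_input")
})

test_that("r_mt vanishes without exchange and far off resonance", {
  sys <- one_pool_system()
  dead <- semisolid_pool("dead", 0, 0, 7.8e-6)
  dead$center_ppm <- 4.7
  expect_equal(
    r_mt(dead, sys$water, 2 * pi * c(-5e4, -1e3), 2 * pi * 250, fs700),
    c(0, 0), tolerance = 1e-10)
  live <- sys$pools[[1]]
  far <- r_mt(live, sys$water, 2 * pi * -1e8, 2 * pi * 250, fs700)
  expect_lt(abs(far), 1e-6)
  near <- r_mt(live, sys$water, 2 * pi * -5e3, 2 * pi * 1000, fs700)
  expect_gt(near, 0)
})

test_that("Z-profile recovers to 1 far off resonance and stays in (0, 1]", {
  sys0 <- spin_system(fs700, water_pool(0.4, 0.8))
  g <- saturation_grid(c(100, 1000), 4.7 + c(-1, 1) * 1e5 / 700)
  z <- z_profile(sys0, g)$z_values
  expect_true(all(z > 0.99))
  gfar <- saturation_grid(500, 4.7 - 1e6 / 700)
  expect_equal(z_profile(sys0, gfar)$z_values, 1, tolerance = 1e-3)
  # bounds over a broad physical grid, with and without pools
  g2 <- upfield_grid(20, min_hz = 300)
  for (s in list(sys0, one_pool_system(), one_pool_system(agarose_pool()))) {
    z <- z_profile(s, g2)$z_values
    z <- z[!is.na(z)]
    expect_true(all(z > 0 & z <= 1 + 1e-12))
  }
})

test_that("adding a semi-solid pool never increases Z at any offset", {
  g <- upfield_grid(15, min_hz = 400)
  base <- spin_system(fs700, water_default())
  z0 <- z_profile(base, g)$z_values
  set.seed(42)
  for (i in 1:8) {
    pool <- semisolid_pool("p", kb <- 10^runif(1, 1, 2.8),
                           10^runif(1, -2, 0), 10^runif(1, -6, -4.5),
                           lineshape = sample(c("gaussian", "super_lorentzian"), 1))
    z1 <- z_profile(spin_system(fs700, water_default(), list(pool)), g)$z_values
    ok <- !is.na(z1) & !is.na(z0)
    expect_true(all(z1[ok] <= z0[ok] + 1e-10))
  }
})

test_that("two-pool Z equals water plus the sum of per-pool relayed rates", {
  sys <- spin_system(fs700, water_default(),
                     list(agarose_pool(), condensate_pool()))
  g <- upfield_grid(10, min_hz = 500)
  z2 <- z_profile(sys, g)
  pts <- g$points[!z2$excluded, ]
  dw <- ppm_to_angular_offset(pts$offset_ppm, 4.7, fs700)
  w1 <- 2 * pi * pts$b1_hz
  r1rw <- r1rho_water(dw, w1, sys$water)
  rmt <- Reduce(`+`, lapply(sys$pools, r_mt, water = sys$water,
                            delta_omega_water = dw, omega1 = w1,
                            field = fs700))
  z_manual <- dw^2 / (dw^2 + w1^2) * sys$water$R1_per_s / (r1rw + rmt)
  expect_equal(z2$z_values[!z2$excluded], z_manual, tolerance = 1e-12)
})

test_that("apparent dip half-width grows monotonically with B1", {
  sys <- one_pool_system()
  b1s <- c(100, 170, 250, 330, 500, 650, 780, 1000)
  offs <- 4.7 - exp(seq(log(400), log(1e5), length.out = 80)) / 700
  halfwidth <- vapply(b1s, function(b1) {
    z <- z_profile(sys, saturation_grid(b1, offs))$z_values
    depth <- max(1 - z, na.rm = TRUE)
    max(abs(offs[!is.na(z) & (1 - z) > depth / 2] - 4.7))
  }, numeric(1))
  expect_true(all(diff(halfwidth) > 0))
})

test_that("pool population follows detailed balance", {
  expect_equal(pool_population(1, 1), 0.5)
  expect_equal(pool_population(0.258, 215), 0.258 / 215.258, tolerance = 1e-12)
  expect_identical(pool_population(0, 5), 0)
  expect_error(pool_population(0, 0), class = "cmt_undefined_population")
  # P * k_pool_to_water == (1 - P) * k_water_to_pool, exactly
  set.seed(3)
  kf <- 10^runif(50, -3, 1); kb <- 10^runif(50, 0, 3)
  P <- pool_population(kf, kb)
  expect_equal(P * kb, (1 - P) * kf, tolerance = 1e-12)
  expect_true(all(P >= 0 & P < 1))
})

test_that("relaxation_terms decomposition is consistent and non-negative", {
  sys <- spin_system(fs700, water_default(),
                     list(agarose_pool(), condensate_pool()))
  rt <- relaxation_terms(sys, b1_Hz = 500, offset_ppm = -10)
  expect_gt(rt$r1rho_water_per_s, 0)
  expect_true(all(unlist(rt$r_rf_pool_per_s) >= 0))
  expect_true(all(unlist(rt$r_mt_pool_per_s) >= 0))
  expect_equal(rt$r1rho_total_per_s,
               rt$r1rho_water_per_s + Reduce(`+`, rt$r_mt_pool_per_s),
               tolerance = 1e-12)
})

test_that("spin system enforces its invariants", {
  expect_error(spin_system(fs700, water_default(),
                           list(agarose_pool(), agarose_pool())),
               class = "cmt_invalid_argument")
  expect_error(
    spin_system(fs700, water_default(),
                list(agarose_pool(), condensate_pool(),
                     semisolid_pool("x", 1, 1, 1e-5))),
    class = "cmt_invalid_argument")
  expect_error(semisolid_pool("p", -1, 0.1, 1e-5),
               class = "cmt_invalid_argument")
  expect_error(water_pool(0, 1), class = "cmt_invalid_argument")
  expect_warning(water_pool(2, 1), class = "cmt_unphysical")
})
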