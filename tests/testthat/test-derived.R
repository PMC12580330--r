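# Derived physical analyses.

test_that("expected proton population reproduces the worked arithmetic", {
  # 1,100 protons at 0.15 mM against 2 x 53 M water protons -> ~0.15%
  p <- expected_proton_population(1100, 0.15)
  expect_equal(p, 1100 * 0.15 / (2 * 53 * 1e3 + 1100 * 0.15),
               tolerance = 1e-12)
  expect_lt(abs(100 * p - 0.15), 0.01)
  expect_identical(expected_proton_population(0, 5), 0)
  # linear in concentration while n*c << c_w
  half <- expected_proton_population(1100, 0.075)
  expect_equal(half / p, 0.5, tolerance = 1e-3)
  # strictly increasing in both arguments, saturating at 1
  expect_true(all(diff(expected_proton_population(1100, c(0.1, 1, 10))) > 0))
  expect_true(all(diff(expected_proton_population(c(100, 1000, 5000), 1)) > 0))
  expect_equal(expected_proton_population(1e12, 1e6), 1, tolerance = 1e-6)
})

test_that("net MT effect subtracts matched grids and flags mismatches", {
  pre <- scenario_preset("agarose_only")
  profs <- generate_profiles(pre, noise_sigma = 0)
  d0 <- net_mt_effect(profs[[1]], profs[[1]])
  expect_true(all(d0$net_effect == 0))
  # agarose+condensate saturates water at least as much as agarose alone
  smp_sys <- scenario_preset("cag31_150uM")$system
  smp_sys$water$R2_per_s <- pre$system$water$R2_per_s  # isolate pool effect
  g <- upfield_grid(15, min_hz = 400)
  z_ref <- z_profile(pre$system, g)
  z_smp <- z_profile(smp_sys, g)
  keep <- !z_smp$excluded
  gk <- saturation_grid(unique(g$points$b1_hz[keep]),
                        lapply(unique(g$points$b1_hz[keep]), function(b)
                          g$points$offset_ppm[keep & g$points$b1_hz == b]))
  eff <- net_mt_effect(
    mt_profile(gk, z_smp$z_values[keep]),
    mt_profile(gk, z_ref$z_values[keep]))
  expect_true(all(eff$net_effect >= -1e-10))
  # difference grows with the condensate uptake rate
  grow <- vapply(c(0.1, 0.25, 0.6), function(kf) {
    pool <- semisolid_pool("c", 215, kf, 7.8e-6)
    z <- z_profile(spin_system(fs700, pre$system$water,
                               list(pre$system$pools[[1]], pool)), gk)
    max(z_ref$z_values[keep] - z$z_values)
  }, numeric(1))
  expect_true(all(diff(grow) > 0))
  # grid mismatch errors
  g2 <- saturation_grid(250, c(-10, -20))
  expect_error(net_mt_effect(mt_profile(g2, c(0.9, 0.95)), profs[[1]]),
               class = "cmt_grid_mismatch")
})

test_that("partition estimates follow the integral arithmetic", {
  eq <- partition_from_integrals(3.2, 3.2)
  expect_equal(eq$fraction_dilute, 1)
  expect_equal(eq$partition_coefficient, 0)
  pe <- partition_from_integrals(0.2, 1)
  expect_equal(pe$fraction_dilute, 0.2)
  expect_equal(pe$fraction_condensed, 0.8)
  expect_equal(pe$partition_coefficient, 4)
  expect_equal(pe$fraction_dilute + pe$fraction_condensed, 1)
  full <- partition_from_integrals(0, 1)
  expect_true(full$capped)
  expect_identical(full$partition_coefficient, Inf)
  expect_error(partition_from_integrals(2, 1),
               class = "cmt_inconsistent_input")
})

test_that("BPP hydration inverts its own forward model exactly", {
  for (tau in c(0.1, 0.5, 3.6, 20, 100)) {
    fb <- 0.02
    fwd <- bpp_excess_rates(fb, tau)
    h <- hydration_bpp(fwd$delta_R2_per_s, condensate_population = 0.0012,
                       delta_R1_per_s = fwd$delta_R1_per_s)
    expect_equal(h$tau_c_bound_water_ns, tau, tolerance = 1e-6)
    expect_equal(h$bound_fraction, fb, tolerance = 1e-6)
    expect_equal(h$water_protons_per_rna_proton, fb / 0.0012,
                 tolerance = 1e-6)
    expect_equal(h$water_molecules_per_rna_proton,
                 h$water_protons_per_rna_proton / 2)
  }
})

test_that("BPP edge cases behave as documented", {
  h0 <- hydration_bpp(0, 0.0012, tau_c_ns = 3.6)
  expect_identical(h0$water_protons_per_rna_proton, 0)
  expect_error(hydration_bpp(2, 0.001, delta_R1_per_s = 4),
               class = "cmt_no_solution")   # ratio < 1: not invertible
  expect_error(hydration_bpp(2, 0.001), class = "cmt_invalid_argument")
  h <- hydration_bpp(2.17, 0.0012, tau_c_ns = 3.6)
  expect_identical(h$assumptions$rates_used, "delta_R2 only (tau_c supplied)")
  expect_equal(h$assumptions$hh_distance_A, 1.59)
})

test_that("tumbling estimate is a monotone order-of-magnitude map", {
  est <- tumbling_estimate(7.8e-6)
  expect_true(est$order_of_magnitude)
  expect_true(est$semi_solid)
  expect_gt(est$tau_c_s, 0.5e-6); expect_lt(est$tau_c_s, 50e-6)
  liquid <- tumbling_estimate(1e-3)
  expect_lt(liquid$tau_c_s, 1e-7)
  expect_false(liquid$semi_solid)
  taus <- tumbling_estimate(c(1e-6, 1e-5, 1e-4))$tau_c_s
  expect_true(all(diff(taus) < 0))
})

test_that("sensitivity scan is a thin wrapper over Z differencing", {
  base <- spin_system(fs700, water_default())
  offs <- offset_schedule(16, 1e5, field = fs700)
  sc <- sensitivity_scan(base, grid_T2_s = c(7.8e-6, 3e-5),
                         grid_kex_per_s = c(60, 215),
                         b1_list_Hz = c(250, 1000), offsets_ppm = offs)
  # recompute one cell directly
  g <- saturation_grid(c(250, 1000), offs)
  z0 <- z_profile(base, g)
  pool <- semisolid_pool("probe", 215, 0.0012 * 215 / (1 - 0.0012), 7.8e-6)
  z1 <- z_profile(spin_system(fs700, base$water, list(pool)), g)
  ok <- !z1$excluded
  direct <- max(abs(z0$z_values[ok] - z1$z_values[ok]))
  got <- sc$map$max_effect[sc$map$T2_s == 7.8e-6 & sc$map$kex_per_s == 215]
  expect_identical(got, direct)
  # zero population -> nothing detectable
  sc0 <- sensitivity_scan(base, c(7.8e-6), c(215), b1_list_Hz = 250,
                          population = 0, offsets_ppm = offs)
  expect_false(any(sc0$map$detectable))
  # detectability monotone in population
  effs <- vapply(c(1e-4, 5e-4, 2e-3), function(p) {
    sensitivity_scan(base, 7.8e-6, 215, b1_list_Hz = 1000, population = p,
                     offsets_ppm = offs)$map$max_effect
  }, numeric(1))
  expect_true(all(diff(effs) > 0))
})
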