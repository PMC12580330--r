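# Shared builders for small test systems and grids.

fs700 <- field_settings(700, 4.7)

water_default <- function(R1 = 0.40, R2 = 6.3) water_pool(R1, R2)

condensate_pool <- function(population = 0.0012, kb = 215, T2 = 7.8e-6,
                            lineshape = "super_lorentzian") {
  semisolid_pool("condensate", kb, population * kb / (1 - population), T2,
                 lineshape = lineshape)
}

agarose_pool <- function() {
  semisolid_pool("agarose", 60, 60 * 3e-4 / (1 - 3e-4), 12e-6,
                 center_ppm = 5.3, lineshape = "gaussian")
}

one_pool_system <- function(pool = condensate_pool(), R2 = 6.3) {
  spin_system(fs700, water_default(R2 = R2), list(pool))
}

upfield_grid <- function(n_offsets = 12, b1 = c(100, 250, 500, 1000),
                         min_hz = 500, max_hz = 1e5) {
  offs <- 4.7 - exp(seq(log(min_hz), log(max_hz), length.out = n_offsets)) / 700
  saturation_grid(b1, offs)
}

cag31_truth <- c(k_pool_to_water = 215,
                 k_water_to_pool = 0.0012 * 215 / (1 - 0.0012),
                 T2_pool = 7.8e-6,
                 R2_water = 6.3)

default_fit_config <- function(...) {
  fit_config(fixed = list(R1_water = 0.40, R1_pool = 1), ...)
}
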