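# Seeded generator of MT profiles and inversion-recovery curves with the
# acquisition geometry of a multi-B1 water-detected experiment, so the
# fitting and analysis layers are testable without any measured data.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Saturation offset schedule
#'
#' Log-spaced offset magnitudes from `min_offset_Hz` to `max_offset_Hz`
#' (dense near the water resonance, sparse far off), placed upfield of
#' water, or mirror-symmetrically on both sides when `two_sided`.
#'
#' @param n_points Total number of offsets (must be even when two-sided).
#' @param max_offset_Hz Largest offset magnitude from water, Hz.
#' @param two_sided Place offsets on both sides of water?
#' @param field A [field_settings()] object.
#' @param min_offset_Hz Smallest offset magnitude, Hz.
#' @return Sorted numeric vector of offsets on the ppm axis.
#' @export
offset_schedule <- function(n_points, max_offset_Hz = 1e5, two_sided = FALSE,
                            field = field_settings(), min_offset_Hz = 10) {
  if (n_points < 4) cmt_stop("invalid_argument", "need at least 4 offsets")
  if (two_sided && n_points %% 2 != 0) {
    cmt_stop("invalid_argument", "two-sided schedule needs an even n_points")
  }
  n_side <- if (two_sided) n_points / 2 else n_points
  mags <- exp(seq(log(min_offset_Hz), log(max_offset_Hz), length.out = n_side))
  ppm_mag <- mags / field$larmor_frequency_MHz
  w <- field$water_reference_ppm
  out <- if (two_sided) c(w - ppm_mag, w + ppm_mag) else w - ppm_mag
  sort(out)
}

.default_b1_Hz <- c(100, 170, 250, 330, 500, 650, 780, 1000)

#' Named scenario presets
#'
#' Immutable generator scenarios covering the study conditions: a pure
#' buffer (`water_only`), the agarose meshwork alone (`agarose_only`,
#' Gaussian pool centred at 5.3 ppm), a 150 uM 31-repeat CAG condensate
#' embedded in agarose (`cag31_150uM`: super-Lorentzian pool of population
#' 0.12%, pool-to-water exchange 215/s, T2 7.8 us, water R2 6.3/s) and a
#' weak-condensate variant (`low_population`, population 0.02%). All use
#' 8 B1 amplitudes between 100 and 1000 Hz and a 46-point upfield offset
#' schedule reaching 100 kHz, with 0.5% additive Gaussian noise on Z.
#'
#' @param name Preset name.
#' @param field A [field_settings()] object.
#' @return A list of class `mt_scenario` with `name`, `system`, `grid`,
#'   `noise_sigma` and `seed`.
#' @export
scenario_preset <- function(name = c("water_only", "agarose_only",
                                     "cag31_150uM", "low_population"),
                            field = field_settings()) {
  name <- match.arg(name)
  agarose <- semisolid_pool("agarose",
                            k_pool_to_water_per_s = 60,
                            k_water_to_pool_per_s = 60 * 3e-4 / (1 - 3e-4),
                            T2_pool_s = 12e-6,
                            center_ppm = 5.3, lineshape = "gaussian")
  cond <- function(pop, kb) {
    semisolid_pool("condensate", k_pool_to_water_per_s = kb,
                   k_water_to_pool_per_s = pop * kb / (1 - pop),
                   T2_pool_s = 7.8e-6, lineshape = "super_lorentzian",
                   center_ppm = field$water_reference_ppm)
  }
  system <- switch(
    name,
    water_only = spin_system(field, water_pool(0.40, 0.8)),
    agarose_only = spin_system(field, water_pool(0.40, 4.13), list(agarose)),
    cag31_150uM = spin_system(field, water_pool(0.40, 6.3),
                              list(agarose, cond(0.0012, 215))),
    low_population = spin_system(field, water_pool(0.40, 4.5),
                                 list(agarose, cond(2e-4, 215)))
  )
  structure(
    list(name = name, system = system,
         grid = saturation_grid(.default_b1_Hz,
                                offset_schedule(46, 1e5, FALSE, field)),
         noise_sigma = 0.005, seed = 1L),
    class = "mt_scenario"
  )
}

#' Generate noisy MT profiles from a scenario
#'
#' Evaluates the forward model on the scenario grid, adds i.i.d. Gaussian
#' noise of standard deviation `noise_sigma` to Z, clips to
#' `[-0.05, 1.10]`, and drops grid points the model flags as excluded
#' (inside a super-Lorentzian on-resonance window). Output is reproducible
#' given the seed; one profile is returned per B1 amplitude.
#'
#' @param preset A [scenario_preset()] (its `system`/`grid`/`noise_sigma`
#'   fields may be modified before the call).
#' @param seed Integer seed; defaults to the preset's.
#' @param noise_sigma Overrides the preset noise level if given.
#' @return List of [mt_profile()] objects, one per B1 amplitude.
#' @export
generate_profiles <- function(preset, seed = preset$seed,
                              noise_sigma = preset$noise_sigma) {
  stopifnot(inherits(preset, "mt_scenario"))
  model <- z_profile(preset$system, preset$grid)
  keep <- !model$excluded
  pts <- preset$grid$points[keep, , drop = FALSE]
  z_clean <- model$z_values[keep]
  z <- if (noise_sigma > 0) {
    .with_seed(seed, pmin(1.10, pmax(-0.05,
      z_clean + stats::rnorm(length(z_clean), 0, noise_sigma))))
  } else z_clean
  lapply(unique(pts$b1_hz), function(b1) {
    ix <- pts$b1_hz == b1
    g <- saturation_grid(b1, pts$offset_ppm[ix],
                         duration_s = preset$grid$duration_s)
    mt_profile(g, z[ix],
               sample_label = sprintf("%s_b1_%g", preset$name, b1))
  })
}

#' Generate a synthetic inversion-recovery curve
#'
#' `M(t) = M0 * (1 - 2*a*exp(-t/T1))` plus additive Gaussian noise. The
#' default delay schedule uses 24 delays up to 15 s, denser at short times.
#'
#' @param T1_s Longitudinal relaxation time, seconds.
#' @param delays_s Recovery delays; default 24 log-ish spaced up to 15 s.
#' @param inversion_efficiency Inversion efficiency `a` in (0.5, 1].
#' @param M0 Equilibrium intensity.
#' @param noise_sigma Noise standard deviation (same units as M0).
#' @param seed Integer seed.
#' @return An [ir_curve()].
#' @export
generate_ir <- function(T1_s, delays_s = NULL, inversion_efficiency = 1,
                        M0 = 1, noise_sigma = 0, seed = 1L) {
  if (T1_s <= 0) cmt_stop("invalid_argument", "T1_s must be > 0")
  if (is.null(delays_s)) {
    delays_s <- c(0, exp(seq(log(0.01), log(15), length.out = 23)))
  }
  m <- M0 * (1 - 2 * inversion_efficiency * exp(-delays_s / T1_s))
  if (noise_sigma > 0) {
    m <- .with_seed(seed, m + stats::rnorm(length(m), 0, noise_sigma))
  }
  ir_curve(delays_s, m, label = sprintf("synthetic_T1_%g", T1_s))
}
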