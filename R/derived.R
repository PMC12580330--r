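# Physical quantities derived from fits and auxiliary measurements.

#' Expected proton population of a dissolved biomolecule
#'
#' The relative proton population a fully condensed biomolecule would
#' contribute to a semi-solid pool: `n*c / (c_w + n*c)`, where `n` is the
#' proton count per molecule, `c` its molar concentration and `c_w` the
#' water proton concentration (default 2 x 53 M = 106 M, i.e. 106,000 mM).
#'
#' @param protons_per_molecule Number of protons per molecule.
#' @param molecule_conc_mM Molecule concentration in mM.
#' @param water_proton_conc_mM Water proton concentration in mM.
#' @return Expected population as a fraction.
#' @examples
#' expected_proton_population(1100, 0.15)   # ~0.0015, i.e. ~0.15%
#' @export
expected_proton_population <- function(protons_per_molecule, molecule_conc_mM,
                                       water_proton_conc_mM = 2 * 53 * 1e3) {
  check_finite(protons_per_molecule, "protons_per_molecule")
  check_finite(molecule_conc_mM, "molecule_conc_mM")
  check_finite(water_proton_conc_mM, "water_proton_conc_mM")
  if (any(protons_per_molecule < 0) || any(molecule_conc_mM < 0) ||
      any(water_proton_conc_mM <= 0)) {
    cmt_stop("invalid_argument", "concentrations must be positive")
  }
  nc <- protons_per_molecule * molecule_conc_mM
  nc / (water_proton_conc_mM + nc)
}

#' Net MT effect of a sample relative to a reference
#'
#' Point-by-point difference `Z_reference - Z_sample` over matching
#' (B1, offset) grids: positive where the sample saturates water more than
#' the reference. Grids must match exactly; no interpolation is performed.
#'
#' @param sample,reference [mt_profile()] objects on identical grids
#'   (point order may differ).
#' @return A data frame with `b1_hz`, `offset_ppm`, `net_effect`.
#' @export
net_mt_effect <- function(sample, reference) {
  stopifnot(inherits(sample, "mt_profile"), inherits(reference, "mt_profile"))
  key <- function(p) paste(format(p$grid$points$b1_hz, digits = 12),
                           format(p$grid$points$offset_ppm, digits = 12))
  ks <- key(sample); kr <- key(reference)
  if (length(ks) != length(kr) || !setequal(ks, kr) ||
      anyDuplicated(ks) || anyDuplicated(kr)) {
    miss <- c(setdiff(ks, kr), setdiff(kr, ks))
    cmt_stop("grid_mismatch",
             sprintf("profile grids do not match; unmatched points: %s",
                     paste(utils::head(miss, 5), collapse = "; ")))
  }
  idx <- match(ks, kr)
  data.frame(
    b1_hz = sample$grid$points$b1_hz,
    offset_ppm = sample$grid$points$offset_ppm,
    net_effect = reference$z_values[idx] - sample$z_values
  )
}

#' Partition estimate from 1D signal integrals
#'
#' The dilute-phase fraction of the biomolecule is the ratio of the signal
#' integral under biphasic conditions (only the dilute phase is visible) to
#' the monophasic integral (everything visible); the condensed fraction is
#' its complement, and the partition coefficient their ratio.
#'
#' @param integral_biphasic,integral_monophasic Signal integrals (> 0,
#'   arbitrary but identical units).
#' @return A list of class `partition_estimate` with `fraction_dilute`,
#'   `fraction_condensed`, `partition_coefficient` and a `capped` flag set
#'   when the dilute fraction is zero (coefficient reported as `Inf`).
#' @export
partition_from_integrals <- function(integral_biphasic, integral_monophasic) {
  check_finite(integral_biphasic, "integral_biphasic")
  check_finite(integral_monophasic, "integral_monophasic")
  if (integral_biphasic < 0 || integral_monophasic <= 0) {
    cmt_stop("invalid_argument", "integrals must be positive")
  }
  if (integral_biphasic > 1.05 * integral_monophasic) {
    cmt_stop("inconsistent_input",
             "biphasic integral exceeds monophasic integral beyond noise tolerance")
  }
  fd <- min(1, max(0, integral_biphasic / integral_monophasic))
  fc <- 1 - fd
  capped <- fd == 0
  structure(
    list(fraction_dilute = fd, fraction_condensed = fc,
         partition_coefficient = if (capped) Inf else fc / fd,
         capped = capped),
    class = "partition_estimate"
  )
}

# ---- Bloembergen-Purcell-Pound bound-water analysis ------------------------

.bpp_constants <- function(hh_distance_A) {
  gamma_h <- 2.6752218744e8      # rad/s/T
  hbar <- 1.054571817e-34        # J s
  mu0_4pi <- 1e-7                # T^2 m^3 / J
  r <- hh_distance_A * 1e-10
  d <- mu0_4pi * gamma_h^2 * hbar / r^3   # rad/s
  list(d2 = d^2, gamma_h = gamma_h, hh_distance_A = hh_distance_A)
}

# Homonuclear intramolecular dipolar relaxation, J(w) = tau/(1 + w^2 tau^2)
.bpp_rates <- function(tau_c_s, omega0, d2) {
  J <- function(w) tau_c_s / (1 + (w * tau_c_s)^2)
  list(
    R1 = (3 / 10) * d2 * (J(omega0) + 4 * J(2 * omega0)),
    R2 = (3 / 20) * d2 * (3 * J(0) + 5 * J(omega0) + 2 * J(2 * omega0))
  )
}

#' Forward BPP excess rates of a bound-water pool
#'
#' Fast-exchange two-site model: a fraction `bound_fraction` of water
#' protons is transiently bound with rotational correlation time `tau_c`;
#' the excess bulk-water rates are `delta_R1 = f_b * R1b(tau_c)` and
#' `delta_R2 = f_b * R2b(tau_c)` with the homonuclear dipolar BPP rates.
#' Used to generate test inputs for [hydration_bpp()] round trips.
#'
#' @param bound_fraction Fraction of water protons bound (0-1).
#' @param tau_c_ns Rotational correlation time of bound water, ns.
#' @param field A [field_settings()] object.
#' @param hh_distance_A Intramolecular water H-H distance in Angstrom.
#' @return List with `delta_R1_per_s`, `delta_R2_per_s`.
#' @export
bpp_excess_rates <- function(bound_fraction, tau_c_ns,
                             field = field_settings(),
                             hh_distance_A = 1.59) {
  cst <- .bpp_constants(hh_distance_A)
  omega0 <- 2 * pi * field$larmor_frequency_MHz * 1e6
  r <- .bpp_rates(tau_c_ns * 1e-9, omega0, cst$d2)
  list(delta_R1_per_s = bound_fraction * r$R1,
       delta_R2_per_s = bound_fraction * r$R2)
}

#' Bound-water hydration estimate via BPP relaxation
#'
#' Inverts the fast-exchange BPP model: the ratio `delta_R2/delta_R1` of the
#' excess bulk-water rates depends only on the bound-water correlation time
#' `tau_c` (strictly increasing, from 1 in the extreme-narrowing limit), so
#' `tau_c` is solved from the ratio; the bound fraction then follows from
#' `delta_R2 / R2b(tau_c)` and the water-proton-per-biomolecule-proton ratio
#' from `bound_fraction / condensate_population`. When only `delta_R2` is
#' measured, `tau_c_ns` must be supplied and only the fraction/ratio is
#' solved.
#'
#' @param delta_R2_per_s Excess transverse water rate (sample minus
#'   reference), 1/s.
#' @param condensate_population Semi-solid pool population (fraction), from
#'   the MT fit.
#' @param delta_R1_per_s Excess longitudinal water rate, 1/s, or `NULL`.
#' @param tau_c_ns Bound-water correlation time in ns; required when
#'   `delta_R1_per_s` is `NULL`.
#' @param field A [field_settings()] object.
#' @param hh_distance_A Intramolecular water H-H distance, Angstrom.
#' @return An object of class `hydration_estimate`: `tau_c_bound_water_ns`,
#'   `water_protons_per_rna_proton`, `water_molecules_per_rna_proton`
#'   (protons/2), `bound_fraction`, and an `assumptions` record.
#' @export
hydration_bpp <- function(delta_R2_per_s, condensate_population,
                          delta_R1_per_s = NULL, tau_c_ns = NULL,
                          field = field_settings(), hh_distance_A = 1.59) {
  check_finite(delta_R2_per_s, "delta_R2_per_s")
  if (delta_R2_per_s < 0) cmt_stop("invalid_argument", "delta_R2 must be >= 0")
  if (condensate_population <= 0) {
    cmt_stop("invalid_argument", "condensate_population must be > 0")
  }
  cst <- .bpp_constants(hh_distance_A)
  omega0 <- 2 * pi * field$larmor_frequency_MHz * 1e6
  used <- "delta_R2 only (tau_c supplied)"
  if (!is.null(delta_R1_per_s)) {
    if (delta_R1_per_s <= 0) {
      cmt_stop("invalid_argument", "delta_R1 must be > 0 when supplied")
    }
    target <- delta_R2_per_s / delta_R1_per_s
    ratio <- function(tau) {
      r <- .bpp_rates(tau, omega0, cst$d2)
      r$R2 / r$R1 - target
    }
    if (target <= 1 + 1e-9 || ratio(1e-4) < 0) {
      cmt_stop("no_solution",
               "delta_R2/delta_R1 ratio outside the invertible BPP range")
    }
    sol <- stats::uniroot(ratio, c(1e-13, 1e-4), tol = 1e-16)
    tau_c_s <- sol$root
    used <- "delta_R2/delta_R1 ratio"
  } else if (!is.null(tau_c_ns)) {
    tau_c_s <- tau_c_ns * 1e-9
  } else {
    cmt_stop("invalid_argument",
             "supply either delta_R1_per_s or tau_c_ns to fix tau_c")
  }
  rates <- .bpp_rates(tau_c_s, omega0, cst$d2)
  fb <- delta_R2_per_s / rates$R2
  ratio_protons <- fb / condensate_population
  structure(
    list(tau_c_bound_water_ns = tau_c_s * 1e9,
         water_protons_per_rna_proton = ratio_protons,
         water_molecules_per_rna_proton = ratio_protons / 2,
         bound_fraction = fb,
         bound_fraction_per_unit_population = ratio_protons,
         assumptions = list(
           hh_distance_A = hh_distance_A,
           larmor_frequency_MHz = field$larmor_frequency_MHz,
           rates_used = used,
           spectral_density = "J(w) = tau/(1 + w^2 tau^2), homonuclear dipolar",
           R1b_per_s = rates$R1, R2b_per_s = rates$R2)),
    class = "hydration_estimate"
  )
}

#' @export
print.hydration_estimate <- function(x, ...) {
  cat(sprintf("<hydration_estimate> tau_c = %.3g ns, %.3g water protons (%.3g molecules) per biomolecule proton\n",
              x$tau_c_bound_water_ns, x$water_protons_per_rna_proton,
              x$water_molecules_per_rna_proton))
  cat(sprintf("  bound fraction %.3g; from %s; r(H-H) = %.3g A at %g MHz\n",
              x$bound_fraction, x$assumptions$rates_used,
              x$assumptions$hh_distance_A, x$assumptions$larmor_frequency_MHz))
  invisible(x)
}

#' Order-of-magnitude tumbling estimate from a semi-solid T2
#'
#' In the slow-motion dipolar regime the transverse relaxation rate of a
#' rigid proton network is approximately `1/T2 = M2 * tau_c`, with `M2` the
#' rigid-lattice second moment. Inverting gives
#' `tau_c = 1/(M2 * T2)` -- an order-of-magnitude estimate only, since `M2`
#' of the condensed material is not measured independently.
#'
#' @param T2_pool_s Semi-solid T2 in seconds.
#' @param second_moment_rad2_s2 Rigid-lattice second moment, rad^2/s^2;
#'   default `(2*pi*20e3)^2` (a 20 kHz rigid proton linewidth).
#' @return A list of class `tumbling_estimate`: `tau_c_s`, the constant
#'   used, an `order_of_magnitude` flag (always `TRUE`), and `semi_solid`
#'   (`FALSE` when tau_c falls below 100 ns, i.e. liquid-like input).
#' @export
tumbling_estimate <- function(T2_pool_s,
                              second_moment_rad2_s2 = (2 * pi * 2e4)^2) {
  check_finite(T2_pool_s, "T2_pool_s")
  if (any(T2_pool_s <= 0)) cmt_stop("invalid_argument", "T2_pool_s must be > 0")
  tau <- 1 / (second_moment_rad2_s2 * T2_pool_s)
  structure(
    list(tau_c_s = tau,
         second_moment_rad2_s2 = second_moment_rad2_s2,
         order_of_magnitude = TRUE,
         semi_solid = tau > 1e-7),
    class = "tumbling_estimate"
  )
}

#' @export
print.tumbling_estimate <- function(x, ...) {
  cat(sprintf("<tumbling_estimate> tau_c ~ %.3g s (order of magnitude; %s regime)\n",
              x$tau_c_s, if (all(x$semi_solid)) "semi-solid" else "liquid-like"))
  invisible(x)
}

#' Detectability scan over pool T2 and exchange rate
#'
#' For each (T2, k_ex) combination, adds a semi-solid pool of the given
#' population to the base system and records the maximum absolute Z
#' difference against the base system over the acquisition grid; the pool is
#' called detectable when that maximum exceeds the noise floor. Also
#' reports the offset band in which the pool contributes nothing but water
#' saturation is still appreciable -- the region sensitive exclusively to
#' the water R2.
#'
#' @param base_system [spin_system()] without the probe pool (typically
#'   water only, or water + reference pool).
#' @param grid_T2_s Vector of pool T2 values, seconds.
#' @param grid_kex_per_s Vector of pool-to-water exchange rate constants.
#' @param b1_list_Hz Saturation amplitudes to scan.
#' @param population Probe pool population used for every grid cell.
#' @param noise_floor Detectability threshold on |delta Z| (fraction of Z).
#' @param offsets_ppm Offset schedule; defaults to the 46-point upfield
#'   schedule.
#' @param lineshape Lineshape of the probe pool.
#' @return A list of class `sensitivity_scan`: `map` (data frame with
#'   `T2_s`, `kex_per_s`, `max_effect`, `detectable`) and
#'   `r2_sensitive_band_ppm` (range of offsets where only the water R2
#'   matters, or `NULL`).
#' @export
sensitivity_scan <- function(base_system, grid_T2_s, grid_kex_per_s,
                             b1_list_Hz = c(100, 170, 250, 330, 500, 650, 780, 1000),
                             population = 0.0012, noise_floor = 0.005,
                             offsets_ppm = NULL,
                             lineshape = "super_lorentzian") {
  stopifnot(inherits(base_system, "spin_system"))
  if (length(grid_T2_s) == 0 || length(grid_kex_per_s) == 0) {
    cmt_stop("invalid_argument", "parameter grids must be non-empty")
  }
  if (noise_floor <= 0) cmt_stop("invalid_argument", "noise_floor must be > 0")
  if (is.null(offsets_ppm)) {
    offsets_ppm <- offset_schedule(46, 1e5, two_sided = FALSE,
                                   field = base_system$field)
  }
  grid <- saturation_grid(b1_list_Hz, offsets_ppm)
  z_base <- z_profile(base_system, grid)
  cells <- expand.grid(T2_s = grid_T2_s, kex_per_s = grid_kex_per_s,
                       KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(cells)), function(i) {
    kb <- cells$kex_per_s[i]
    kf <- if (population > 0) population * kb / (1 - population) else 0
    pool <- semisolid_pool("probe", kb, kf, cells$T2_s[i],
                           lineshape = lineshape)
    sys2 <- spin_system(base_system$field, base_system$water,
                        c(base_system$pools, list(pool)))
    zp <- z_profile(sys2, grid)
    dz <- abs(z_base$z_values - zp$z_values)
    ok <- !zp$excluded & !z_base$excluded
    data.frame(T2_s = cells$T2_s[i], kex_per_s = kb,
               max_effect = max(dz[ok]),
               detectable = max(dz[ok]) > noise_floor)
  })
  map <- do.call(rbind, res)

  # R2-only band: per offset, pool effect below the floor at every B1 while
  # water self-saturation is still above it (probe with median grid cell)
  mid <- cells[ceiling(nrow(cells) / 2), ]
  kb <- mid$kex_per_s
  kf <- if (population > 0) population * kb / (1 - population) else 0
  pool <- semisolid_pool("probe", kb, kf, mid$T2_s, lineshape = lineshape)
  sys2 <- spin_system(base_system$field, base_system$water,
                      c(base_system$pools, list(pool)))
  zp <- z_profile(sys2, grid)
  pts <- grid$points
  per_off <- vapply(split(seq_len(nrow(pts)), pts$offset_ppm), function(ix) {
    ok <- !zp$excluded[ix] & !z_base$excluded[ix]
    if (!any(ok)) return(c(NA, NA))
    c(max(abs(z_base$z_values[ix][ok] - zp$z_values[ix][ok])),
      max(1 - z_base$z_values[ix][ok]))
  }, numeric(2))
  offs <- as.numeric(colnames(per_off))
  band <- offs[!is.na(per_off[1, ]) & per_off[1, ] < noise_floor &
                 per_off[2, ] > noise_floor]
  structure(
    list(map = map,
         r2_sensitive_band_ppm = if (length(band)) range(band) else NULL,
         noise_floor = noise_floor, population = population),
    class = "sensitivity_scan"
  )
}
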