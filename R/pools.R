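#' Saturation grid
#'
#' The acquisition geometry of a water-detected MT experiment: one or more
#' continuous-wave saturation amplitudes B1 (in Hz) and the saturation
#' offsets (on the ppm axis) at which the water signal is read out.
#'
#' @param b1_amplitudes_Hz Vector of B1 amplitudes (Hz), all > 0.
#' @param offsets_ppm Either a numeric vector of offsets shared by all B1
#'   amplitudes, or a list with one offset vector per B1 amplitude.
#' @param duration_s Saturation time in seconds (metadata only; the model is
#'   steady state).
#' @return An object of class `mt_grid` with a canonical `points` data frame
#'   (`b1_hz`, `offset_ppm`).
#' @export
saturation_grid <- function(b1_amplitudes_Hz, offsets_ppm, duration_s = 5) {
  check_finite(b1_amplitudes_Hz, "b1_amplitudes_Hz")
  if (any(b1_amplitudes_Hz <= 0)) {
    cmt_stop("invalid_argument", "all B1 amplitudes must be > 0")
  }
  if (is.list(offsets_ppm)) {
    if (length(offsets_ppm) != length(b1_amplitudes_Hz)) {
      cmt_stop("invalid_argument",
               "offsets_ppm list must have one entry per B1 amplitude")
    }
    pts <- do.call(rbind, lapply(seq_along(b1_amplitudes_Hz), function(i) {
      check_finite(offsets_ppm[[i]], "offsets_ppm")
      data.frame(b1_hz = b1_amplitudes_Hz[i], offset_ppm = offsets_ppm[[i]])
    }))
  } else {
    check_finite(offsets_ppm, "offsets_ppm")
    pts <- expand.grid(offset_ppm = offsets_ppm, b1_hz = b1_amplitudes_Hz,
                       KEEP.OUT.ATTRS = FALSE)[, c("b1_hz", "offset_ppm")]
  }
  if (anyDuplicated(pts)) {
    cmt_stop("invalid_argument", "duplicate (B1, offset) pairs in grid")
  }
  structure(
    list(points = pts, b1_amplitudes_Hz = unique(pts$b1_hz),
         duration_s = duration_s),
    class = "mt_grid"
  )
}

#' MT profile
#'
#' Normalized bulk-water intensities Z over a saturation grid for one sample.
#' Z is dimensionless and expected in `[-0.05, 1.10]` (the slack admits noise
#' excursions). Points flagged as excluded (e.g. inside the on-resonance
#' exclusion window of a super-Lorentzian pool) may carry `NA`.
#'
#' @param grid A [saturation_grid()].
#' @param z_values Numeric vector of Z values, one per grid point.
#' @param sample_label Free-text sample identifier.
#' @param temperature_C Sample temperature (metadata).
#' @param excluded Optional logical vector flagging non-evaluated points.
#' @return An object of class `mt_profile`.
#' @export
mt_profile <- function(grid, z_values, sample_label = "",
                       temperature_C = NA_real_, excluded = NULL) {
  stopifnot(inherits(grid, "mt_grid"))
  n <- nrow(grid$points)
  if (length(z_values) != n) {
    cmt_stop("invalid_argument",
             sprintf("z_values has length %d but grid has %d points",
                     length(z_values), n))
  }
  if (is.null(excluded)) excluded <- rep(FALSE, n)
  ok <- !excluded
  if (anyNA(z_values[ok]) || any(!is.finite(z_values[ok]))) {
    cmt_stop("invalid_argument", "non-finite Z at a non-excluded grid point")
  }
  zr <- z_values[ok]
  if (length(zr) && (min(zr) < -0.05 || max(zr) > 1.10)) {
    cmt_stop("invalid_argument", "Z values outside [-0.05, 1.10]")
  }
  structure(
    list(grid = grid, z_values = as.numeric(z_values),
         sample_label = sample_label, temperature_C = temperature_C,
         excluded = excluded),
    class = "mt_profile"
  )
}

#' Liquid water pool
#'
#' Relaxation parameters of the detected bulk-water pool. R1 is normally
#' fixed from an inversion-recovery measurement; R2 is a fit parameter. The
#' water population is treated as 1 in the exchange bookkeeping.
#'
#' @param R1_per_s Longitudinal relaxation rate of water (1/s).
#' @param R2_per_s Transverse relaxation rate of water (1/s). Physically
#'   `R2 >= R1`; a value below R1 triggers a warning, not an error, so that
#'   optimizers may traverse the boundary.
#' @return An object of class `water_pool`.
#' @export
water_pool <- function(R1_per_s, R2_per_s) {
  check_finite(R1_per_s, "R1_per_s"); check_finite(R2_per_s, "R2_per_s")
  if (R1_per_s <= 0 || R2_per_s <= 0) {
    cmt_stop("invalid_argument", "water R1 and R2 must be > 0")
  }
  if (R2_per_s < R1_per_s) {
    cmt_warn("unphysical", "water R2 < R1 is unphysical")
  }
  structure(list(R1_per_s = R1_per_s, R2_per_s = R2_per_s, population = 1),
            class = "water_pool")
}

#' Semi-solid MT pool
#'
#' One semi-solid proton pool exchanging with bulk water: condensed RNA, an
#' agarose meshwork, or similar material with microsecond-scale T2. The pool
#' population follows from the two exchange rate constants through detailed
#' balance (see [pool_population()]); R1 of the pool is conventionally held
#' at 1/s because the model is only weakly sensitive to it.
#'
#' @param name Pool identifier (must be unique within a system).
#' @param k_pool_to_water_per_s Exchange rate constant pool -> water (1/s).
#' @param k_water_to_pool_per_s Exchange rate constant water -> pool (1/s).
#' @param T2_pool_s Transverse relaxation time of the pool, in seconds.
#' @param R1_pool_per_s Longitudinal rate of the pool (1/s); fixed by
#'   convention, default 1.
#' @param center_ppm Chemical-shift center of the pool resonance; `NA` means
#'   "use the water reference of the system's field settings" (the default
#'   convention for condensate pools).
#' @param lineshape `"super_lorentzian"` (partially ordered semi-solids) or
#'   `"gaussian"`.
#' @return An object of class `mt_pool`.
#' @export
semisolid_pool <- function(name,
                           k_pool_to_water_per_s,
                           k_water_to_pool_per_s,
                           T2_pool_s,
                           R1_pool_per_s = 1,
                           center_ppm = NA_real_,
                           lineshape = c("super_lorentzian", "gaussian")) {
  lineshape <- match.arg(lineshape)
  check_finite(k_pool_to_water_per_s, "k_pool_to_water_per_s")
  check_finite(k_water_to_pool_per_s, "k_water_to_pool_per_s")
  check_finite(T2_pool_s, "T2_pool_s")
  if (k_pool_to_water_per_s < 0 || k_water_to_pool_per_s < 0) {
    cmt_stop("invalid_argument", "exchange rate constants must be >= 0")
  }
  if (T2_pool_s <= 0) cmt_stop("invalid_argument", "T2_pool_s must be > 0")
  if (R1_pool_per_s <= 0) cmt_stop("invalid_argument", "R1_pool_per_s must be > 0")
  structure(
    list(name = as.character(name),
         k_pool_to_water_per_s = k_pool_to_water_per_s,
         k_water_to_pool_per_s = k_water_to_pool_per_s,
         T2_pool_s = T2_pool_s,
         R1_pool_per_s = R1_pool_per_s,
         center_ppm = center_ppm,
         lineshape = lineshape),
    class = "mt_pool"
  )
}

#' Spin system: water plus up to two semi-solid MT pools
#'
#' The forward-model input. Pools are independent (no direct pool-pool
#' exchange); their exchange-relayed contributions to the rotating-frame
#' relaxation of water add linearly.
#'
#' @param field A [field_settings()] object.
#' @param water A [water_pool()].
#' @param pools List of 0-2 [semisolid_pool()] objects with unique names.
#'   Pools with `center_ppm = NA` are centered at the water reference.
#' @return An object of class `spin_system`.
#' @export
spin_system <- function(field, water, pools = list()) {
  stopifnot(inherits(field, "mt_field"), inherits(water, "water_pool"))
  if (inherits(pools, "mt_pool")) pools <- list(pools)
  if (length(pools) > 2) {
    cmt_stop("invalid_argument", "at most 2 semi-solid pools are supported")
  }
  for (p in pools) stopifnot(inherits(p, "mt_pool"))
  nm <- vapply(pools, `[[`, "", "name")
  if (anyDuplicated(nm)) cmt_stop("invalid_argument", "pool names must be unique")
  pools <- lapply(pools, function(p) {
    if (is.na(p$center_ppm)) p$center_ppm <- field$water_reference_ppm
    p
  })
  structure(list(field = field, water = water, pools = pools),
            class = "spin_system")
}

#' Pool population from exchange rate constants
#'
#' Detailed balance between a semi-solid pool and water ties the relative
#' pool population to the two exchange rate constants:
#' `P = k_water_to_pool / (k_water_to_pool + k_pool_to_water)`.
#'
#' @param k_water_to_pool_per_s Rate constant water -> pool (1/s).
#' @param k_pool_to_water_per_s Rate constant pool -> water (1/s).
#' @return Pool population, a fraction in `[0, 1)`.
#' @examples
#' pool_population(0.258, 215)   # ~0.0012, i.e. 0.12%
#' @export
pool_population <- function(k_water_to_pool_per_s, k_pool_to_water_per_s) {
  check_finite(k_water_to_pool_per_s, "k_water_to_pool_per_s")
  check_finite(k_pool_to_water_per_s, "k_pool_to_water_per_s")
  if (any(k_water_to_pool_per_s < 0) || any(k_pool_to_water_per_s < 0)) {
    cmt_stop("invalid_argument", "rate constants must be >= 0")
  }
  s <- k_water_to_pool_per_s + k_pool_to_water_per_s
  if (any(s == 0)) {
    cmt_stop("undefined_population",
             "both exchange rate constants are zero: population undefined")
  }
  k_water_to_pool_per_s / s
}

#' @export
print.mt_profile <- function(x, ...) {
  cat(sprintf("<mt_profile> '%s': %d points, %d B1 amplitude(s), %d excluded\n",
              x$sample_label, nrow(x$grid$points),
              length(x$grid$b1_amplitudes_Hz), sum(x$excluded)))
  invisible(x)
}

#' @export
print.spin_system <- function(x, ...) {
  cat(sprintf("<spin_system> %g MHz, water R1=%.3g R2=%.3g, %d pool(s)\n",
              x$field$larmor_frequency_MHz, x$water$R1_per_s,
              x$water$R2_per_s, length(x$pools)))
  for (p in x$pools) {
    cat(sprintf("  pool '%s' [%s]: k_pw=%.4g k_wp=%.4g T2=%.3g us center=%.2f ppm (P=%.3g)\n",
                p$name, p$lineshape, p$k_pool_to_water_per_s,
                p$k_water_to_pool_per_s, p$T2_pool_s * 1e6, p$center_ppm,
                pool_population(p$k_water_to_pool_per_s, p$k_pool_to_water_per_s)))
  }
  invisible(x)
}
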