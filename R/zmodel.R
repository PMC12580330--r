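# Steady-state Z model: water rotating-frame relaxation plus additive
# exchange-relayed contributions from up to two semi-solid MT pools.

#' Rotating-frame relaxation of water in isolation
#'
#' `R1rho = R1 * dw^2/(dw^2 + w1^2) + R2 * w1^2/(dw^2 + w1^2)`: an
#' offset-weighted mix of the longitudinal and transverse water rates,
#' always bounded between R1 and R2.
#'
#' @param delta_omega Offset from the water resonance, rad/s (vectorized).
#' @param omega1 Saturation amplitude `2*pi*B1`, rad/s (vectorized).
#' @param water A [water_pool()].
#' @return Rate(s) in 1/s.
#' @export
r1rho_water <- function(delta_omega, omega1, water) {
  stopifnot(inherits(water, "water_pool"))
  check_finite(delta_omega, "delta_omega")
  check_finite(omega1, "omega1")
  if (any(omega1 < 0)) cmt_stop("invalid_argument", "omega1 must be >= 0")
  if (any(delta_omega == 0 & omega1 == 0)) {
    cmt_stop("degenerate_input",
             "delta_omega and omega1 are both zero: weights undefined")
  }
  d2 <- delta_omega^2
  w2 <- omega1^2
  (water$R1_per_s * d2 + water$R2_per_s * w2) / (d2 + w2)
}

# Vectorized exchange-relayed rate; closed-form steady state of the coupled
# two-site longitudinal system (water along its effective field, pool along
# z, exchange respecting detailed balance). `r1rho_w` is the isolated-water
# rate at the same grid points; `rrf` the pool saturation-loss rate.
.r_mt_core <- function(r1rho_w, cos2, R1w, kb, kf, R1p, rrf) {
  if (kb == 0 && kf == 0) return(rep(0, length(r1rho_w)))
  Db <- R1p + rrf + kb
  R1w * (r1rho_w + kf * (Db - kb * cos2) / Db) /
    (R1w + kf * R1p / Db) - r1rho_w
}

.pool_rrf <- function(pool, dwp, w1, sl_normalization, sl_method = "table") {
  if (pool$lineshape == "gaussian") {
    r_rf_gaussian(dwp, w1, pool$T2_pool_s)
  } else {
    r_rf_superlorentzian(dwp, w1, pool$T2_pool_s,
                         normalization = sl_normalization,
                         method = sl_method)
  }
}

#' Exchange-relayed relaxation contribution of a semi-solid pool
#'
#' The additional rotating-frame relaxation that off-resonance saturation of
#' a semi-solid pool relays to bulk water through proton exchange. Derived
#' from the steady state of the coupled two-site longitudinal
#' Bloch-McConnell system: the water pool relaxes at its isolated rate (see
#' [r1rho_water()]), the semi-solid pool loses magnetization at its
#' lineshape-dependent saturation rate, and the two exchange with rate
#' constants satisfying detailed balance. Vanishes when both exchange rate
#' constants are zero and far off resonance.
#'
#' @param pool A [semisolid_pool()]; its `center_ppm` must be resolved (use
#'   pools taken from a [spin_system()], where `NA` centers are filled in).
#' @param water A [water_pool()].
#' @param delta_omega_water Offset from the water resonance, rad/s
#'   (vectorized).
#' @param omega1 Saturation amplitude, rad/s.
#' @param field A [field_settings()] object (converts the water-relative
#'   offset to the pool-relative offset).
#' @param sl_normalization Super-Lorentzian normalization constant, see
#'   [r_rf_superlorentzian()].
#' @param sl_method Evaluation method for the super-Lorentzian shape factor.
#' @return Exchange-relayed rate(s) in 1/s.
#' @export
r_mt <- function(pool, water, delta_omega_water, omega1, field,
                 sl_normalization = "printed", sl_method = "table") {
  stopifnot(inherits(pool, "mt_pool"), inherits(water, "water_pool"),
            inherits(field, "mt_field"))
  center <- if (is.na(pool$center_ppm)) field$water_reference_ppm else pool$center_ppm
  dwp <- delta_omega_water +
    2 * pi * (field$water_reference_ppm - center) * field$larmor_frequency_MHz
  w1 <- omega1
  r1rw <- r1rho_water(delta_omega_water, w1, water)
  cos2 <- delta_omega_water^2 / (delta_omega_water^2 + w1^2)
  rrf <- .pool_rrf(pool, dwp, w1, sl_normalization, sl_method)
  .r_mt_core(r1rw, cos2, water$R1_per_s, pool$k_pool_to_water_per_s,
             pool$k_water_to_pool_per_s, pool$R1_pool_per_s, rrf)
}

# Internal fast path over a points data frame (b1_hz, offset_ppm).
# Returns list(z, excluded, r1rho_water, r_mt = list per pool).
.z_model <- function(points, field, water, pools,
                     exclusion_ppm = 0.3, sl_normalization = "printed",
                     keep_terms = FALSE) {
  mhz <- field$larmor_frequency_MHz
  dw <- 2 * pi * (points$offset_ppm - field$water_reference_ppm) * mhz
  w1 <- 2 * pi * points$b1_hz
  excluded <- rep(FALSE, nrow(points))
  for (p in pools) {
    if (p$lineshape == "super_lorentzian") {
      excluded <- excluded |
        abs(points$offset_ppm - p$center_ppm) < exclusion_ppm
    }
  }
  ok <- !excluded
  r1rw <- rep(NA_real_, length(dw))
  r1rw[ok] <- r1rho_water(dw[ok], w1[ok], water)
  cos2 <- dw^2 / (dw^2 + w1^2)
  rmt_total <- rep(0, length(dw))
  terms <- list()
  for (p in pools) {
    dwp <- dw + 2 * pi * (field$water_reference_ppm - p$center_ppm) * mhz
    rmt <- rep(NA_real_, length(dw))
    rrf <- .pool_rrf(p, dwp[ok], w1[ok], sl_normalization)
    rmt[ok] <- .r_mt_core(r1rw[ok], cos2[ok], water$R1_per_s,
                          p$k_pool_to_water_per_s, p$k_water_to_pool_per_s,
                          p$R1_pool_per_s, rrf)
    rmt_total[ok] <- rmt_total[ok] + rmt[ok]
    if (keep_terms) terms[[p$name]] <- list(r_rf = rrf, r_mt = rmt)
  }
  z <- rep(NA_real_, length(dw))
  z[ok] <- cos2[ok] * water$R1_per_s / (r1rw[ok] + rmt_total[ok])
  out <- list(z = z, excluded = excluded)
  if (keep_terms) {
    out$r1rho_water <- r1rw
    out$r1rho_total <- r1rw + rmt_total
    out$pool_terms <- terms
  }
  out
}

#' Steady-state water Z-profile of a spin system
#'
#' For each grid point the observed relative water magnetization is
#' `Z = dw^2/(dw^2 + w1^2) * R1_water / R1rho(dw)`, with
#' `R1rho(dw) = R1rho_water + sum of per-pool exchange-relayed rates`.
#' Z lies in `(0, 1]` for physical parameters and tends to 1 far off
#' resonance. Grid points inside the exclusion window around the center of a
#' super-Lorentzian pool are flagged as excluded and carry `NA` (the shape
#' diverges there; direct water saturation dominates that region anyway).
#'
#' @param system A [spin_system()].
#' @param grid A [saturation_grid()].
#' @param exclusion_ppm Half-width (ppm) of the window around each
#'   super-Lorentzian pool center that is flagged instead of evaluated.
#' @param sl_normalization See [r_rf_superlorentzian()].
#' @param sample_label Label attached to the returned profile.
#' @return An [mt_profile()] with the model Z values.
#' @export
z_profile <- function(system, grid, exclusion_ppm = 0.3,
                      sl_normalization = "printed", sample_label = "model") {
  stopifnot(inherits(system, "spin_system"), inherits(grid, "mt_grid"))
  if (nrow(grid$points) == 0) cmt_stop("invalid_argument", "empty grid")
  m <- .z_model(grid$points, system$field, system$water, system$pools,
                exclusion_ppm = exclusion_ppm,
                sl_normalization = sl_normalization)
  mt_profile(grid, m$z, sample_label = sample_label, excluded = m$excluded)
}

#' Decomposition of the rotating-frame relaxation at one grid point
#'
#' Reports the isolated-water rate, each pool's saturation-loss and
#' exchange-relayed rates, and their sum, for inspection of what drives the
#' Z attenuation at a given (B1, offset).
#'
#' @inheritParams z_profile
#' @param b1_Hz Saturation amplitude, Hz.
#' @param offset_ppm Saturation offset, ppm.
#' @return A list with `r1rho_water_per_s`, per-pool `r_rf_pool_per_s` and
#'   `r_mt_pool_per_s`, and `r1rho_total_per_s`.
#' @export
relaxation_terms <- function(system, b1_Hz, offset_ppm,
                             sl_normalization = "printed") {
  pts <- data.frame(b1_hz = b1_Hz, offset_ppm = offset_ppm)
  m <- .z_model(pts, system$field, system$water, system$pools,
                exclusion_ppm = 0, sl_normalization = sl_normalization,
                keep_terms = TRUE)
  list(
    r1rho_water_per_s = m$r1rho_water,
    r_rf_pool_per_s = lapply(m$pool_terms, `[[`, "r_rf"),
    r_mt_pool_per_s = lapply(m$pool_terms, `[[`, "r_mt"),
    r1rho_total_per_s = m$r1rho_total,
    z = m$z
  )
}

#' Numerical Bloch-McConnell steady-state reference
#'
#' Independent cross-check of [z_profile()]: integrates the coupled
#' longitudinal magnetization equations (water along its effective field,
#' each semi-solid pool along z, exchange obeying detailed balance, the
#' pools losing magnetization at their lineshape saturation rate) to steady
#' state with a stiff ODE solver, instead of using the closed-form rates.
#' Used by the validation suite; agreement within 1% over the physical
#' parameter range is a design requirement of the model.
#'
#' @inheritParams z_profile
#' @param t_max Initial integration horizon (s); extended automatically
#'   until the solution is stationary.
#' @return An [mt_profile()] with the numerically obtained Z values.
#' @export
z_profile_bm <- function(system, grid, exclusion_ppm = 0.3,
                         sl_normalization = "printed", t_max = 400) {
  stopifnot(inherits(system, "spin_system"), inherits(grid, "mt_grid"))
  field <- system$field; water <- system$water; pools <- system$pools
  mhz <- field$larmor_frequency_MHz
  pts <- grid$points
  excluded <- rep(FALSE, nrow(pts))
  for (p in pools) {
    if (p$lineshape == "super_lorentzian") {
      excluded <- excluded | abs(pts$offset_ppm - p$center_ppm) < exclusion_ppm
    }
  }
  z <- rep(NA_real_, nrow(pts))
  for (i in which(!excluded)) {
    dw <- 2 * pi * (pts$offset_ppm[i] - field$water_reference_ppm) * mhz
    w1 <- 2 * pi * pts$b1_hz[i]
    costh <- dw / sqrt(dw^2 + w1^2)
    r1rw <- r1rho_water(dw, w1, water)
    kf <- vapply(pools, `[[`, 0, "k_water_to_pool_per_s")
    kb <- vapply(pools, `[[`, 0, "k_pool_to_water_per_s")
    loss <- vapply(seq_along(pools), function(j) {
      p <- pools[[j]]
      dwp <- dw + 2 * pi * (field$water_reference_ppm - p$center_ppm) * mhz
      p$R1_pool_per_s + kb[j] + .pool_rrf(p, dwp, w1, sl_normalization)
    }, numeric(1))
    R1p <- vapply(pools, `[[`, 0, "R1_pool_per_s")
    np <- length(pools)
    deriv <- function(t, y, parms) {
      a <- y[1]; b <- y[-1]
      da <- -(r1rw + sum(kf)) * a + sum(kf * costh * b) + water$R1_per_s * costh
      db <- kb * costh * a - loss * b + R1p
      list(c(da, db))
    }
    y0 <- c(costh, rep(1, np))
    tt <- t_max
    for (attempt in 1:4) {
      sol <- deSolve::lsoda(y0, times = c(0, tt / 2, tt), func = deriv,
                            rtol = 1e-11, atol = 1e-13)
      z_half <- sol[2, 2] * costh
      z_full <- sol[3, 2] * costh
      if (abs(z_full - z_half) < 1e-9) break
      tt <- tt * 5
    }
    z[i] <- z_full
  }
  mt_profile(grid, z, sample_label = "bloch-mcconnell reference",
             excluded = excluded)
}
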