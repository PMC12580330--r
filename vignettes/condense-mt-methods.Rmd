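---
title: "Water-detected semi-solid magnetization transfer: model, fitting and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Water-detected semi-solid magnetization transfer: model, fitting and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condensemt)
```

## The physical problem

Biomolecular condensates -- here, the motivating system is droplets of CAG
repeat-expansion RNA -- can be so dynamically arrested that their proton T2
drops to microseconds. Their resonances are then kilohertz-wide and invisible
to direct NMR detection. What survives is proton exchange with bulk water:
continuous-wave irradiation applied far off resonance saturates the broad
semi-solid line, and exchange relays that saturation to the water signal,
which is easy to measure. Recording the normalized water intensity `Z` as a
function of saturation offset and amplitude (a *Z-profile* or *MT profile*)
therefore encodes the condensate's population, exchange kinetics and T2,
even though the condensate itself is never observed.

## The steady-state model

For a saturation offset `dw` (rad/s, measured from the water resonance) and
amplitude `w1 = 2*pi*B1`, the steady-state relative water magnetization is

```
Z(dw) = dw^2 / (dw^2 + w1^2) * R1_water / R1rho(dw)
```

with the total rotating-frame relaxation rate written as a sum,

```
R1rho(dw) = R1rho_water(dw) + R_MT,pool1(dw) [+ R_MT,pool2(dw)]
```

* `R1rho_water` (see `r1rho_water()`) is the isolated-water term, an
  offset-weighted mix of the water R1 and R2; it is bounded between the two
  rates, equals R2 on resonance and R1 far off resonance. The region of
  small offsets at moderate `B1` is therefore sensitive *only* to the water
  R2 -- which is how the method detects motion-restricted ("bound") water.
* `R_MT` (see `r_mt()`) is the exchange-relayed contribution of one
  semi-solid pool. We derive it in closed form as the exact steady state of
  the coupled two-site longitudinal system: water relaxing at its isolated
  rate along its effective field, the pool losing magnetization at its
  saturation rate `R_rf`, and exchange with rate constants
  `k_pool_to_water` / `k_water_to_pool` obeying detailed balance
  (`pool_population()`). It vanishes without exchange and far off
  resonance, and saturates at `k_water_to_pool` when the pool is fully
  saturated.

Two pools (the stabilizing agarose meshwork and the condensate) enter
additively and independently; direct pool-pool exchange is neglected, which
is appropriate because both pools are vastly dilute relative to water.

Because the additive `R1rho` decomposition is an approximation, the package
carries its own referee: `z_profile_bm()` integrates the same coupled
equations numerically with a stiff ODE solver (deSolve) to steady state.
The test suite requires closed form and solver to agree within 1% over
`k_ex` 10-600 1/s, T2 1-30 us, B1 100-1000 Hz and offsets 1-100 kHz; in
practice the agreement is at solver precision (~1e-10 relative), because
the closed form is the algebraic steady state of the same system.

## Lineshapes and the on-resonance window

The pool saturation rate `R_rf` carries the lineshape:

* **Gaussian** (`r_rf_gaussian()`), appropriate for amorphous meshworks such
  as agarose: `w1^2 * sqrt(pi/2) * T2 * exp(-(dw*T2)^2/2)`.
* **Super-Lorentzian** (`r_rf_superlorentzian()`), appropriate for partially
  ordered semi-solids such as condensates: the same Gaussian kernel averaged
  over the dipolar orientation angle, each orientation contributing an
  effective `T2/|3cos^2(theta)-1|`.

Numerical choices for the angular integral: adaptive Gauss-Kronrod
quadrature with the interval split at the magic angle
`theta_m = acos(1/sqrt(3))` (where the integrand is non-smooth), relative
tolerance 1e-8. Because the integral depends on offset and T2 only through
`x = |dw|*T2`, the forward model and the fits evaluate it through a
session-cached spline table of that universal shape factor (1500 support
points, validated against direct quadrature to better than 1e-6 relative in
the tests); the exported function defaults to direct quadrature, and a
fixed-order Gauss-Legendre mode (`nodes=`) exists so convergence can be
demonstrated by node doubling.

The orientation average diverges logarithmically as `dw -> 0` (the
magic-angle singularity), so points within a configurable window around a
super-Lorentzian pool center (default +/-0.3 ppm) are flagged and excluded
from evaluation and fitting. Nothing of value is lost: that region is
dominated by direct water saturation, which the water term models.

A comparison worth knowing (it is asserted in the tests): at matched
`(w1, T2)` the super-Lorentzian rate exceeds the Gaussian several-fold over
the broad band `|dw*T2| <~ 0.6`, but crosses *below* it further out --
the slowest-decaying orientation shares the Gaussian's exponential rate
with a `1/x^2`-damped amplitude. The practical discriminator between the
two models is therefore the mid-range curvature across B1 values, and the
fits separate them reliably at 0.5% noise.

Two typesetting decisions are deliberate. The Gaussian exponent is negative
(a growing saturation rate with offset would contradict every measured
profile). The super-Lorentzian's internal constant is kept as `sqrt(pi/2)`
to match the source formulation; the textbook normalization `sqrt(2/pi)`
is available via `normalization = "standard"` -- the choice rescales the
fitted `(T2, k)` pair jointly and is recorded with every fit.

## Fitting

`fit_system()` minimizes the unweighted SSE between model and all data
points (pooled across B1 amplitudes -- a single B1 cannot separate
population from saturation efficiency, hence the multi-B1 design) with a
Nelder-Mead simplex on log-transformed parameters (all four free parameters
are positive): `k_pool_to_water`, `k_water_to_pool`, `T2_pool`,
`R2_water`. Convergence tolerance 1e-10 on the SSE, at most 20,000
evaluations. Initial values default to `k_pool_to_water` 100 1/s,
`k_water_to_pool` 0.1 1/s, T2 10 us, `R2_water = 1.5 * R1_water`; these sit
inside the regimes the method can detect and are user-overridable. The
water R1 is never fitted -- it comes from inversion recovery
(`fit_t1_inversion_recovery()`, model `M0*(1 - 2a*exp(-t*R1))` with
inversion efficiency `a` in (0.5, 1]). The pool R1 is held at 1 1/s by
convention because the model is only weakly sensitive to it. Pool centers
are never free parameters: condensate pools default to the water reference
(their lines are tens of kHz wide, so small center errors are immaterial),
and an agarose-like center can be set explicitly (5.3 ppm in the presets).
The default fit window is -150 to 4.7 ppm: downfield offsets are excluded
to avoid contamination by liquid-state CEST pools of exchangeable NH/OH
protons.

Uncertainties: `sigma^2 (J'J)^{-1}` with `sigma^2 = SSE/(n-p)` and J the
central-finite-difference Jacobian (relative step 1e-5) at the optimum. The
system is solved in per-parameter relative scale -- the natural-scale `J'J`
mixes derivatives that differ by seven orders of magnitude (T2 in seconds
vs rates in 1/s) and is numerically singular -- and the covariance is
mapped back to natural units. A genuinely singular system (e.g. a
population degenerate at zero) yields NA uncertainties plus a diagnostic
naming the unconstrained directions. The derived pool population carries a
delta-method standard error.

`stepwise_fit()` encodes the two-step protocol: fit the reference meshwork
alone, freeze it, add the condensate pool, and fit only the condensate
parameters plus the sample's water R2. `select_lineshape()` fits both
lineshapes and flags the lower per-point RMS, reporting ties below 1%
relative RMS difference as indistinguishable ("fit deviation" is reported
both as SSE and as per-point RMS, since either convention is in use).

## The synthetic-data generator

`scenario_preset()` / `generate_profiles()` emulate the acquisition
geometry of the motivating study: 8 B1 amplitudes (100, 170, 250, 330, 500,
650, 780, 1000 Hz) and a 46-point one-sided (or 92-point two-sided) offset
schedule within 100 kHz of water. The exact experimental offset list is not
public, so the schedule is log-spaced from 10 Hz to the maximum offset --
dense near water where the profile curves, sparse far out. Noise is
additive i.i.d. Gaussian on Z with sigma = 0.5% (the measurement noise is
not published; this level makes recovery demanding but feasible), clipped
to [-0.05, 1.10]; all randomness flows through a single seed and the
pre-noise values equal `z_profile()` exactly.

Preset truths: `agarose_only` uses a Gaussian pool centered at 5.3 ppm with
population 3e-4, `k_pool_to_water` 60 1/s, T2 12 us and water R2 4.13 1/s;
`cag31_150uM` adds a super-Lorentzian pool with population 0.0012,
`k_pool_to_water` 215 1/s, T2 7.8 us and water R2 6.3 1/s (the fitted
values reported for the 150 uM 31-repeat CAG system, used here as generator
truths); `low_population` drops the pool population to 2e-4. The water R1
is 0.40 1/s throughout (T1 2.5 s, a typical buffered-water value at the
elevated working temperature).

What the generator does *not* emulate -- and what passing tests therefore
cannot certify about real data: drift and 1/f-like structured noise,
radiation damping residuals, B1 inhomogeneity, temperature gradients,
imperfect saturation steady state at finite saturation time, and any real
deviation of the condensate lineshape from the ideal super-Lorentzian.
Recovering generator truths demonstrates the estimator is correct and
well-conditioned under the stated noise model, not that the physical model
is complete.

## Derived analyses

* `expected_proton_population()`: the bookkeeping expectation
  `n*c/(c_w + n*c)` against 106 M water protons, for comparing a fitted
  population against "all protons condensed".
* `net_mt_effect()`: reference-minus-sample Z on strictly matching grids
  (mismatches are an error; interpolation would silently blur the physics).
* `partition_from_integrals()`: dilute fraction = biphasic/monophasic 1D
  integral ratio, condensed fraction its complement, partition coefficient
  their ratio; a fully condensed sample is reported capped at infinity with
  a flag.
* `hydration_bpp()`: fast-exchange two-site bound-water model with
  homonuclear dipolar relaxation and `J(w) = tau/(1+w^2 tau^2)`. The excess
  R2/R1 ratio is strictly increasing in tau_c (from 1 in extreme
  narrowing), so tau_c is solved from the ratio by root finding; the bound
  fraction follows from the excess R2, and the water-proton-per-biomolecule
  -proton ratio from bound fraction / pool population (water *molecules*
  are protons/2). The intramolecular H-H distance defaults to 1.59 A and is
  echoed, with every other constant, in the output -- the reference
  supplementary constants are not public, so the nanosecond/tens-of-protons
  anchor is reproduced only up to that choice. When only the excess R2 is
  available the problem is underdetermined and tau_c must be supplied.
* `tumbling_estimate()`: slow-motion dipolar relation `tau_c = 1/(M2*T2)`
  with a rigid-lattice second moment defaulting to `(2*pi*20 kHz)^2` (a
  typical rigid proton linewidth). The proportionality constant for the
  condensed material is not measurable here, so the result is flagged
  order-of-magnitude; a 7.8 us T2 maps to ~8 us tau_c, and a liquid-like
  1 ms T2 maps below 100 ns and is flagged as outside the semi-solid
  regime.
* `sensitivity_scan()`: a thin loop over `z_profile()` differencing that
  maps which (T2, k_ex) combinations produce a Z change above a noise
  floor (default 0.5%, matching the generator), and locates the offset band
  where only the water R2 moves Z.

## Problem sizes used in the shipped validation

The test-suite and acceptance-script simulations use the full 46x8
acquisition (368 points, 248 after windowing) with 5-20 seeded replicates
per claim, 100 replicates for the 1-sigma coverage check (on a reduced
20x3 grid), and a 64-combination sweep for the model-vs-solver comparison.
These sizes were chosen so that every claim is re-demonstrated from scratch
in minutes on one core while keeping the Monte-Carlo bands meaningful.

## Known limitations

* Steady-state only: shaped or short saturation pulses and transient
  effects are out of scope (the presets assume 5 s saturation, ample for
  steady state at these rates).
* At most two semi-solid pools; no liquid-state CEST pool (downfield data
  are excluded instead).
* The nominal 1-sigma intervals are covariance-based, not profile or
  bootstrap intervals; the coverage test holds them only to a loose
  0.55-0.80 band.
* Population and exchange become degenerate as the population tends to
  zero; the null-sample behavior (huge population uncertainty, tiny uptake
  flux) is the designed signature of "no condensate", not a defect.
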