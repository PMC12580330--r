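# condensemt

Quantification of NMR-invisible biomolecular condensates from
water-detected magnetization-transfer (MT) profiles.

## The problem

Condensates of repeat-expansion RNA (and many other dynamically arrested
biomolecular assemblies) tumble so slowly that their proton T2 collapses to
microseconds. Their resonances broaden over tens of kilohertz and vanish
from every conventional NMR experiment. What remains observable is bulk
water: continuous-wave saturation applied at an offset Δω burns into the
broad semi-solid line, proton exchange relays the saturation to the
solvent, and the water signal drops. Measuring the normalized water
intensity Z(Δω) over a range of offsets and saturation amplitudes B₁
("Z-profiles") therefore reports on material that is itself invisible.

`condensemt` is for spectroscopists and condensate biophysicists who want
to turn such multi-B₁ profile sets into physical numbers: the fraction of
protons in the condensed pool, the water↔condensate proton exchange rate
constants, the semi-solid T2 (a proxy for tumbling), and the water R2
(a proxy for condensate-bound water).

## The model

The steady-state water magnetization under saturation is

    Z(Δω) = Δω² R₁,H₂O / [(Δω² + ω₁²) · R₁ρ(Δω)],     ω₁ = 2π B₁

with the rotating-frame rate decomposed additively,

    R₁ρ(Δω) = R₁ρ,H₂O(Δω) + R_MT,agarose(Δω) + R_MT,condensate(Δω).

The isolated-water term mixes the water R₁ and R₂ with offset-dependent
weights. Each semi-solid pool contributes an exchange-relayed rate derived
from the two-site Bloch–McConnell steady state, driven by its saturation
rate R_rf: Gaussian for amorphous meshworks (agarose), super-Lorentzian
(orientation-averaged Gaussian, with the magic-angle singularity excluded
near resonance) for partially ordered condensates. Pool population obeys
detailed balance, P = k_{H₂O→MT}/(k_{H₂O→MT} + k_{MT→H₂O}).

Parameters are estimated by global Nelder–Mead least squares over all
(B₁, offset) points, stepwise: the agarose reference is fitted alone,
frozen, and the condensate pool is then fitted on top. Uncertainties come
from σ²(JᵀJ)⁻¹ at the optimum. A numerical ODE steady-state solver
(`z_profile_bm()`) ships as an independent cross-check of the closed form.
Derived layers add expected proton populations, partition coefficients
from 1D integrals, bound-water hydration via Bloembergen–Purcell–Pound
dipolar relaxation, tumbling estimates and detectability scans. A seeded
generator reproduces the acquisition geometry (8 B₁ values 100–1000 Hz,
46 offsets within 100 kHz of water) for end-to-end validation.

## Worked example

Simulate an agarose reference and a 150 µM CAG-condensate sample at 0.5%
noise, then run the stepwise fit:

```r
library(condensemt)

ref_preset <- scenario_preset("agarose_only")
smp_preset <- scenario_preset("cag31_150uM")
reference  <- generate_profiles(ref_preset, seed = 1)
sample     <- generate_profiles(smp_preset, seed = 2)

cfg <- fit_config(fixed = list(R1_water = 0.40, R1_pool = 1))
condensate <- semisolid_pool("condensate", 100, 0.1, 1e-5,
                             lineshape = "super_lorentzian")
stepwise_fit(reference, sample, ref_preset$system, condensate, cfg, cfg)
```

```
== step 1: reference pool ==
<mt_fit> n = 248 points, SSE = 0.006169, per-point RMS = 0.004987
  k_pool_to_water  61.86 +/- 8.8 1/s
  k_water_to_pool  0.01826 +/- 0.001 1/s
  T2_pool          11.64 +/- 0.51 us
  R2_water         4.118 +/- 0.014 1/s
  pool population  0.02951% +/- 0.0029% (k_ex = 61.88 1/s)
== step 2: sample (reference frozen) ==
<mt_fit> n = 248 points, SSE = 0.007164, per-point RMS = 0.005375
  k_pool_to_water  218.2 +/- 5.9 1/s
  k_water_to_pool  0.2589 +/- 0.0041 1/s
  T2_pool          7.806 +/- 0.077 us
  R2_water         6.303 +/- 0.035 1/s
  pool population  0.1185% +/- 0.0017% (k_ex = 218.5 1/s)
```

Step 2 recovers the generating condensate truths (population 0.12%,
k_pool→water 215 1/s, T2 7.8 µs, water R₂ 6.3 1/s) within the reported
uncertainties: 0.12% of all protons sit in the condensed pool, exchanging
with water at ~219 1/s overall; the 7.8 µs T2 marks deeply arrested
tumbling (`tumbling_estimate()` maps it to a ~8 µs rotational correlation
time, order of magnitude); and the water R₂ elevated from 4.12 to
6.30 1/s signals condensate-bound water. Feeding that excess
(6.3 − 4.13 1/s at population 0.12%) to `hydration_bpp()` with a 3.6 ns
bound-water correlation time yields ~32 water protons (16 water molecules)
per condensed-RNA proton.

The same workflow runs from a shell via the thin CLI:

```sh
Rscript inst/cli/condense-mt.R simulate --preset cag31_150uM --seed 2 --out out/
Rscript inst/cli/condense-mt.R hydration --delta-r2 2.17 --population 0.0012 --tau-c-ns 3.6 --out out/
```

Each command writes a JSON report (estimates, uncertainties, covariance,
fit deviation, frozen parameters, config echo) plus residual CSVs.

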