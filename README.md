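# flightpower

Tools for estimating how efficiently flying animals convert metabolic power
into aerodynamic work. The package implements, end to end, the measurement
chain used in wind-tunnel studies of small bats and birds:

* **Mechanical power output** — either modelled (a Pennycuick-style
  fixed-wing-theory model and a wingbeat-resolved flapping-flight model,
  with characteristic-speed solvers), or measured from the wake: gridded
  particle image velocimetry (PIV) velocity planes are background-corrected,
  vorticity-masked, streamfunction-reconstructed, and integrated into
  kinetic wake power, net drag and weight-supporting vertical force.
* **Metabolic power input** — from the ¹³C-labelled sodium bicarbonate
  washout method: exponential washout fits, an isotope-dilution estimate of
  flight CO₂ production, fuel-model energy conversion, and the
  flight-fraction / Z-score / individual selection filters.
* **Power curves** — mixed-effects fits of the U-shaped flight power model
  `P(U) = k₁U³ + k₂/U + k₃` with individual random intercepts, the
  two-step profile-power constraint (k₃ pinned at 50% of power at the
  minimum-power speed), weight-normalized speeds (`U* = U (Mg,ref/Mg)^(1/6)`)
  and analytic characteristic speeds (`U_mp = (k₂/3k₁)^(1/4)`; `U_mr` from
  the tangent through the origin).
* **Conversion efficiency** — `η = P_mech / P_met` by four estimators
  (speed-bin means, a median-based variant, fitted-model ratios, and
  within-individual ±0.5 m s⁻¹ pairing), flight-muscle efficiency
  `η_fm = 1.1 P_mech / (P_met − BMR)`, and the underestimation incurred by
  assuming the classic fixed η = 23%.
* **Cross-species meta-analysis** — per-species efficiency from literature
  metabolic data and modelled mechanical power, and the allometric scaling
  law `log₁₀η = a·log₁₀M + b` fitted as a mixed model with species random
  intercepts and speed slopes.

A synthetic-data module generates every input with known ground truth
(Lamb–Oseen vortex-pair wakes with closed-form lift and energy flux,
single-pool washout traces, power records and species tables), so the whole
pipeline is testable without any wind-tunnel data.

## Worked example

Characteristic speeds of an 8.9 g Nathusius' pipistrelle and its conversion
efficiency from the fitted power curves:

```r
library(flightpower)

bat <- pipistrelle_morphology()     # 8.9 g, 0.23 m span, 9.9 Hz, Cdb 0.4
flap <- flap_model(bat)
characteristic_speeds(flap)
#> # A tibble: 1 × 2
#>    u_mp  u_mr
#>   <dbl> <dbl>
#> 1  4.60  6.00

# minimum-power speed of the metabolic power curve (analytic)
minimum_power_speed(power_curve(3.73e-4, 2.52, 0.490))
#> [1] 6.888785

# whole-animal conversion efficiency from the fitted curves, 5-9 m/s
eff <- efficiency_model_ratio(power_curve(9.21e-5, 0.176, 0.0297),
                              power_curve(3.73e-4, 2.52, 0.490), 5:9)
round(100 * eff$efficiency, 2)
#> [1]  7.34  7.97  8.84  9.93 11.17
```

The flapping model puts the minimum-power and maximum-range speeds at 4.6
and 6.0 m s⁻¹; the metabolic curve's minimum sits higher, at 6.9 m s⁻¹, and
the efficiency ratio rises from about 7% to about 11% across the measured
speed range (mean ≈ 9%) — conversion efficiency is not a constant.

A full synthetic pipeline (wake processing → washout metabolics → curve
fits → efficiency → meta-analysis) runs from one seeded configuration:

```r
run <- run_pipeline(pipeline_config(seed = 1))
run$manifest          # stage-by-stage record counts and notes
glance(run$scaling_fit)  # efficiency-mass scaling exponent
```

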