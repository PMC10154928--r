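---
title: "Models and methods behind flightpower"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind flightpower}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flightpower)
```

flightpower estimates the conversion efficiency of animal flight — the
fraction of metabolic power input that reappears as aerodynamic work —
from the two halves of the measurement: mechanical power output (modelled,
or measured from the wake) and metabolic power input (from isotope washout
kinetics). This vignette explains the models, their assumptions, the
tunable parameters and their defaults, the synthetic-data generators used
for validation, and the numerical and design choices that were genuinely
open.

## Aerodynamic power models

Both models decompose flight power into induced power (the cost of
generating lift, falling as $1/U$), parasite power (body drag, rising as
$U^3$) and profile power (wing drag).

**Fixed-wing-theory model** (`pennycuick_power()`,
`pennycuick_model()`). Induced power is $k\,W^2 / (2\rho U S_d)$ with
induced factor $k = 1.2$ and disc area $S_d = \pi b^2/4$; parasite power is
$\tfrac12 \rho S_b C_{db} U^3$; profile power is speed-independent, equal
to $8.4/AR$ times the absolute minimum of the other two. When no measured
body frontal area is supplied, $S_b$ comes from a mass allometry. Two are
offered:

* `"hedenstrom_rosen"` (default): $S_b = 0.0129\,M^{0.614}$, the passerine
  frontal-area regression — appropriate for small-bodied fliers;
* `"pennycuick"`: $S_b = 0.00813\,M^{0.666}$, the older waterfowl/raptor
  regression.

For the 8.9 g study bat (span 0.23 m, area 0.0077 m², 9.9 Hz wingbeat,
$C_{db} = 0.4$, sea-level density), the default allometry puts the
minimum-power speed at 3.6 m s⁻¹; the waterfowl regression would put it at
4.3 m s⁻¹. The default was chosen because only the passerine allometry
reproduces the characteristic speeds published for this morphology by the
fixed-wing-theory flight program; both remain available because neither
allometry was derived from bats.

The model's **maximum-range speed** follows the fuel-economy convention of
that program: the tangent from the origin to the *chemical* power curve
$P_{chem}(U) = 1.1\,(P_{mech}(U)/\eta + BMR)$ with $\eta = 0.23$ and the
passerine basal-rate allometry $BMR = 6.25\,M^{0.724}$ W. Because range is
distance per unit fuel, the tangent belongs on the fuel-consumption curve;
a constant offset does not move the power minimum but does move the
tangent point (6.9 m s⁻¹ for the study bat versus 5.9 m s⁻¹ on the purely
mechanical curve). `maximum_range_speed(..., basis = "mechanical")`
overrides this.

**Flapping-flight model** (`flap_power()`, `flap_model()`). A
momentum-theory / blade-element hybrid that resolves the wingbeat:

* induced power uses the self-consistent actuator-disc induced velocity
  $v_i = W / (2\rho S_d\sqrt{U^2 + v_i^2})$ (finite in slow flight, unlike
  $1/U$), amplified by a flapping factor $k(1 + c_k k_f^2)$ with reduced
  frequency $k_f = \pi f b / U$ — flapping concentrates lift production in
  the downstroke, and at low speed the wingbeat is slow relative to its
  own induced flow, raising induced losses;
* profile power is the blade-element drag of the beating wing,
  $\tfrac12 \rho C_{D,pro} S (U^2 + V_f^2)^{3/2}$ with section drag
  coefficient $C_{D,pro} = 0.014$ and effective (tip-dominated) flapping
  speed $V_f = c_f f b$;
* parasite power as in the fixed-wing model, with the waterfowl/raptor
  frontal-area allometry.

The two dimensionless flapping constants, $c_k = 0.27864$ and
$c_f = 2.91064$, are calibration constants of this implementation: they
were set, once, so that the model reproduces the characteristic speeds
published for the study morphology by the reference flapping-flight
performance tool (minimum-power speed 4.6 m s⁻¹, maximum-range speed
6.0 m s⁻¹), and they are not adjusted per analysis. With these defaults
the model also predicts cruise powers (≈0.087 W at 6 m s⁻¹) close to
wake-measured values for this bat, a few hundredths of a watt above the
fixed-wing model.

The model reports four **red flags** marking conditions outside its
validated envelope: speed (airspeed below 2 m s⁻¹ or reduced frequency
outside 0.05–3), thrust (required thrust above 30% of weight), frequency
(wingbeat frequency outside 0.5–2× its allometric prediction), and their
union. Flagged speeds are excluded from the meta-analysis estimator.

## Wake-integral mechanical power

`wake_series` objects hold time-resolved $u,v,w$ velocity planes
perpendicular to the free stream (streamwise perturbation $u$ relative to
a free-stream field $U_\infty(y,z)$). The per-sequence chain
(`process_wake_sequence()`):

1. **Background homogenization** (`homogenize_background()`): the
   systematic spatial deviation of $u$ is the per-pixel median over all
   frames of all sequences, estimated outside the wake mask and subtracted
   (minus its spatial mean, so the mean free stream is preserved). The mask
   used here thresholds streamwise vorticity only, which is independent of
   $u$; together with a mean-fill at never-unmasked pixels this makes the
   operation an exact fixed point on second application.
2. **Vorticity and masking** (`streamwise_vorticity()`, `mask_wake()`):
   $\omega_x = \partial w/\partial y - \partial v/\partial z$ by
   fourth-order central differences (second-order near borders); the wake
   mask thresholds a vorticity-magnitude proxy at 3× the robust noise
   scale of the background (MAD of signed $\omega_x$, re-estimated outside
   a provisional mask), then applies one morphological closing plus two
   dilation passes. The margin keeps the low-vorticity fringe of each
   vortex — which still carries circulation — inside the mask; without
   it, either the fringe is clipped (high threshold) or the noise floor is
   admitted (low threshold), each biasing power by 10–25% at realistic
   noise levels.
3. **Flow reconstruction** (`reconstruct_flow()`): the streamfunction
   Poisson problem $\nabla^2\psi = -\omega_x$ is solved with a sparse
   five-point Cholesky factorization (zero-Dirichlet far-field boundaries,
   the only boundary information a finite plane offers), giving the
   solenoidal in-plane flow $v = \partial\psi/\partial z$,
   $w = -\partial\psi/\partial y$ and discarding the irrotational noise.
4. **Wake integrals**: kinetic power
   $P = \rho\sum \tfrac12(u^2+v^2+w^2)(U_\infty+u)\,\Delta y\,\Delta z$
   (pointwise local advection; a `"freestream"` switch exists for
   sensitivity checks) with masked $u$ and reconstructed $v,w$, integrated
   over the whole plane so the induced field around the masked cores is
   retained; net drag $D_{net} = \rho\sum u(U_\infty+u)$ over masked
   cells; drag-corrected power $P + D_{net}U$; and vertical force
   $F_v = \rho\sum U_\infty (y-y_0)\,\omega_x$ with $y_0$ the
   circulation-weighted centroid of $|\omega_x|$ per wingbeat (the centre
   plane is not otherwise observable). Frames are segmented into complete
   wingbeats from the wingbeat frequency; partial trailing wingbeats are
   discarded.
5. **Selection** (`select_sequences()`): retained sequences need more than
   one complete wingbeat and a wingbeat-averaged vertical force within
   ±20% of the animal's weight. Half-wake series are mirrored about the
   body centre plane before power estimation and their vertical force is
   doubled.

On synthetic Lamb–Oseen vortex-pair wakes these operators recover the
closed-form lift $\rho U_\infty \Gamma s$ within 1% and the fine-grid
energy flux within 3% at the default resolution (81×81 points over a
0.6 m plane; the largest remaining error terms are the $O(h^2)$–$O(h^4)$
stencil smoothing of the vortex cores and the zero-Dirichlet truncation of
the far-field dipole energy, which shrinks with domain size).

## Metabolic power from bicarbonate washout

The module implements an explicit single-pool isotope-dilution model,
used identically by estimator and generator: a well-mixed bicarbonate pool
of `pool_ml` (ml CO₂ equivalent) is labelled to enrichment $E_0$; CO₂
production $R(t)$ (ml min⁻¹) washes the label out as
$E(t) = E_0\exp(-\int R\,dt / pool)$, i.e. exponential decay at rate
$k = R/pool$ while $R$ is constant. A flight raises $R$ stepwise while the
animal is airborne. The estimator (`flight_vco2()`) fits exponentials to
the pre- and post-flight washout phases (`fit_washout()`, nonlinear least
squares), takes the resting rate as the mean decay rate times the pool,
and reads the flight's excess CO₂ from the gap between the two fitted
log-enrichment lines at the flight midpoint, attributed to a contiguous
airborne interval of length flight-fraction × trial duration. The pool
size is a calibration input for real data (from dose and equilibrium
enrichment); synthetic traces carry it as an attribute.

Conversions: 21.1 J ml⁻¹ CO₂ (glycogen oxidation, the default for short
flights), 23.7 J ml⁻¹ (80/20 carbohydrate/lipid mix, RQ 0.88) — switching
fuel multiplies every power by exactly 23.7/21.1 ≈ 1.123; basal rates use
20.1 J ml⁻¹ O₂.

Selection (`filter_flights()`), in protocol order: airborne fraction
≥ 60%; within 1 m s⁻¹ speed groups, drop flights whose Z-score strictly
exceeds 2 (Z uses the population, $n$-denominator, standard deviation;
singleton or constant groups leave Z undefined and the flights retained);
drop individuals left with fewer than four flights ("more than three").

## Power-curve fitting

`fit_power_curve()` fits $P = k_1U^3 + k_2/U + k_3 + b_{ind} +
\varepsilon$ by maximum likelihood with an individual random intercept
(nlme). The curve is linear in $(U^3, 1/U, 1)$, so the mixed fit is exact,
not iterative. In the two-step constrained mode the constant is pinned
first — profile power as 50% of the mean observed power in the 1 m s⁻¹
bin around a prior minimum-power speed (from aerodynamic theory), or at a
known value via `k3_value` — and only $k_1, k_2$ are estimated. The
two-step procedure mirrors field practice; note that pinning from binned
data transfers any bin-mean bias into $k_2$, which is why recovery
experiments pin at the true constant. Characteristic speeds follow
analytically: $U_{mp} = (k_2/3k_1)^{1/4}$, $U_{mr}$ from the tangent
through the origin. `compare_to_linear()` reports a likelihood-ratio
statistic against a linear mixed model; the two families are not nested,
so the $\chi^2$ p-value is flagged as heuristic and AICs are reported
alongside. Weight differences between individuals are removed before
pooling with $U^* = U\,(M_{g,ref}/M_g)^{1/6}$ (`normalize_speed()`).

## Conversion efficiency

Four estimators of $\eta = P_{mech}/P_{met}$ (`efficiency_mean()`,
`efficiency_median_vonbusse()`, `efficiency_model_ratio()`,
`efficiency_individual_pairs()`), which agree exactly on noiseless data
from a single curve pair and differ in their robustness to skew,
unbalanced designs and individual heterogeneity. The pairing estimator
matches mechanical and metabolic records of the same individual within
±0.5 m s⁻¹, reports medians and ranges per individual per half-m s⁻¹ bin,
and computes a Pearson correlation of efficiency against speed at pair
level; because records are reused across pairs the data are not
independent, and the duplication counts are reported with the correlation.

Muscle efficiency uses $\eta_{fm} = 1.1\,P_{mech}/(P_{met} - BMR)$. With
the study's mean powers (0.092 W mechanical, 1.0 W metabolic, 0.08 W
basal) this gives 11.0%; the exact algebraic inverse of the
mechanical-to-metabolic prediction, $1.1 P_{mech}/(P_{met} - 1.1 BMR)$,
gives 11.1% and is available as `convention = "strict_inverse"` — the
first is the default because it matches the convention the quantity is
usually reported under. `underestimation_stats()` quantifies how far the
classic fixed-efficiency prediction $P_{met} = 1.1(P_{mech}/0.23 + BMR)$
falls below measured metabolic power (≈47% at the study's mean values).

## Cross-species scaling

`species_efficiency()` models each species' mechanical power with the
flapping model built from its morphology and divides it into measured
metabolic power, keeping only speeds at or above the species' metabolic
minimum-power speed (from a least-squares fit of the cubic-plus-inverse
family to its metabolic series; with fewer than four speeds the constant
is dropped) and not red-flagged by the model. `fit_scaling_model()` fits
$\log_{10}\eta$ (percent) against $\log_{10}M$ (grams) with speed centred
within species as a fixed effect and a random intercept and speed slope
per species (glmmTMB); singular fits fall back to the random intercept
only, then to pooled least squares, each flagged. Units matter and are
deliberate: the published scaling law evaluates to ≈5% for a 7.6 g bat
only with mass in grams and efficiency in percent, which back-checks
against the mass-corrected species means it was reported with.
`mass_correct()` divides by $M^{0.24}$; `near_ump_comparison()` compares
taxa within ±1 m s⁻¹ of each species' minimum-power speed, centring log
mass so the taxon contrast is evaluated at the mean body mass rather than
extrapolated to 1 g.

## What the synthetic data do and do not show

The generators produce: vortex-pair wakes (Gaussian cores chosen for
closed-form circulation, lift and quadrature-exact energy flux; optional
deficit patch, background shear, white noise, half-wake cropping); washout
traces from the same single-pool model the estimator inverts; power
records from the cubic-plus-inverse family with random intercepts (defaults:
the published metabolic curve, eight ~8.9 g individuals, 4–9 m s⁻¹,
residual sd 0.1 W and intercept sd 0.05 W, chosen to match the dispersion
visible in study-scale data); and species tables whose metabolic power is
flapping-model power divided by a true efficiency on the scaling line
(defaults: slope 0.24, intercept 0.49, species intercept sd 0.29, speed
slope sd 0.03, 24 species log-uniform on 4 g–2.6 kg, a 2:1 bird:bat
label split).

Passing tests on these data show that the estimators invert their own
forward models at realistic noise levels and sample sizes — parameter
recovery, filter behaviour, coverage. They do not show that the forward
models capture real wakes or real washout kinetics: real bat wakes have
wingbeat-resolved three-dimensional structure, turbulence and measurement
dropout, none of which the steady vortex pair emulates; real washout
traces have chamber mixing kinetics and baseline drift. Pipeline results
on synthetic data are therefore validation of the arithmetic, not of the
biology.

## Numerical choices and problem sizes

Derivatives: fourth-order central stencils (second-order near borders,
one-sided at them) — vorticity from second-order stencils loses ~4% of a
resolved vortex core's circulation at the default resolution. Poisson
solves: sparse Cholesky, factorization cached per grid. Characteristic
speeds: golden-section minimization to 10⁻⁸ m s⁻¹ internally, reported at
0.1 m s⁻¹. Washout fits: Levenberg–Marquardt with log-linear starting
values. Test problem sizes were chosen to keep the full suite within a few
minutes: wake oracles on 61–181 point grids, recovery experiments at 200
replicates (curve and scaling) and 500 traces (washout), pipeline smoke
runs with 2 individuals × 5 speeds.

## Known limitations

* The flapping model is a two-constant calibration of a richer
  wingbeat-resolved theory; its absolute powers are plausible but its
  component split (induced versus profile) should not be over-interpreted.
* The wake operators collapse the measurement volume to a single plane and
  neglect streamwise gradients and pressure work.
* The washout estimator assumes a single well-mixed pool and symmetric
  pre/post kinetics; it errors out (rather than guessing) when the two
  decay rates disagree by more than 50%.
* The likelihood-ratio comparison of U-shaped versus linear power models
  is between non-nested families and is reported with that caveat.
* The scaling meta-analysis is not phylogenetically corrected; species are
  exchangeable given mass, taxon and speed.
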