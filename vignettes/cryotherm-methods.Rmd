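---
title: "Modelling and measuring tissue freezing during cryoablation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and measuring tissue freezing during cryoablation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryotherm)
```

## Scope

Cryoablation destroys target tissue — typically around the pulmonary veins,
to treat atrial fibrillation — by freezing it with a cold probe or balloon
held against the endocardium. Two families of questions arise. How does the
ice front and the temperature field propagate into the tissue from a probe
held at a constant ablative temperature? And how does tissue actually
freeze: at what supercooled temperature does ice nucleate, how much latent
heat is released, and over what temperature span?

`cryotherm` addresses both with three connected layers:

1. an **analytical freezing-front model** — the classical Neumann solution of
   the one-dimensional two-phase Stefan problem — plus an independent
   finite-difference verifier;
2. a **DSC processing pipeline** that turns a cooling thermogram into an
   ice-onset temperature, a sensible baseline, an equivalent specific latent
   heat capacity, a latent heat, and an end-transition temperature;
3. **statistical relations** across samples: mean latent heat with 95%
   confidence intervals, latent heat versus water mass fraction, and ice
   onset versus the logarithm of the cooling rate, with a slow-rate plateau
   check.

A seeded synthetic-data generator stands in for the calorimeter, so every
stage is testable end to end without instrument data.

Out of scope by design: cylindrical or spherical balloon geometry,
time-varying probe temperature, perfusion and metabolic (bioheat) source
terms, melting-branch analysis, and instrument calibration models.

## The freezing-front model

Semi-infinite tissue initially at body temperature $T_i$ has its surface
held at the ablative temperature $T_s$; freezing occurs at the ice-onset
temperature $T_f$ with $T_s < T_f < T_i$. With frozen-phase properties
$k_1, c_1, \alpha_1$ and unfrozen $k_2, c_2, \alpha_2$ (shared density
$\rho$, no volume change on freezing), the front advances as

$$s(t) = 2\lambda\sqrt{\alpha_1 t},$$

with erf/erfc temperature profiles in the two regions and $\lambda$ fixed by
the interface energy balance

$$\frac{k_1 (T_f - T_s)\, e^{-\lambda^2}}{\sqrt{\pi\alpha_1}\,\operatorname{erf}\lambda}
 - \frac{k_2 (T_i - T_f)\, e^{-\lambda^2 \alpha_1/\alpha_2}}
        {\sqrt{\pi\alpha_2}\,\operatorname{erfc}\!\left(\lambda\sqrt{\alpha_1/\alpha_2}\right)}
 = \lambda\,\rho L \sqrt{\alpha_1}.$$

Direct consequences, all exposed as functions and all tested: the front is
linear in $\sqrt{t}$; the interface gradients and the surface heat flux decay
as $1/\sqrt{t}$; the flux subtracted at the probe is proportional to the
front growth rate; and the thermal gradient at the frozen–unfrozen interface
falls steadily as the ablation proceeds — the physical reason why extending
an application with poor contact mostly endangers surrounding tissue rather
than deepening the lesion.

### Numerical choices

* **Residual scaling.** The balance above is solved as a dimensionless
  residual, divided by the frozen-phase conduction flux scale
  $k_1(T_f-T_s)/\sqrt{\pi\alpha_1}$. The latent term becomes
  $\lambda\sqrt{\pi}/\mathrm{Ste}$ with $\mathrm{Ste} = c_1(T_f-T_s)/L$.
  This keeps the residual $O(1)$ for any latent heat — including the
  pure-conduction limit $L \to 0$, where a scaling by $\rho L \sqrt{\alpha_1}$
  would diverge — so the advertised $|f(\lambda)| < 10^{-10}$ bound is robust
  in double precision.
* **Root finding.** Brent bracketing on $(10^{-8}, 5)$ with up to three
  bracket doublings (tolerance $10^{-12}$ on $\lambda$), then a few Newton
  polish steps to push the residual to machine precision.
* **Degenerate input.** $T_s \ge T_f$ means there is no driving force for a
  frozen layer; this is rejected as an error rather than returning
  $\lambda = 0$.
* **Units.** Temperatures in °C at all interfaces (differences are in K),
  depth in metres from the probe surface, time in seconds from cooling
  start.

### Default property set

The frozen/unfrozen property values are configurable; the defaults in
`liver_tissue_properties()` describe liver-like tissue —
$k_1 = 2.2$, $k_2 = 0.55$ W/(m·K), $c_1 = 2000$, $c_2 = 3600$ J/(kg·K),
$\rho = 1050$ kg/m³, and $L = 159$ kJ/kg, the mean latent heat measured for
the wettest liver cohort (water fraction 0.713). The canonical scenario used
in tests and examples pairs them with $T_s = -54$ °C, $T_f = -23$ °C,
$T_i = 37$ °C.

### The finite-difference verifier

`fd_solve()` is a deliberately transparent brute-force check, not a
production solver: an explicit, exactly conservative enthalpy-method march.
The latent heat is smeared over a mushy band of ±0.5 K (configurable) around
the onset temperature through a piecewise-linear enthalpy–temperature
relation; conductivity blends linearly across the band; the front is located
by linear interpolation of the onset isotherm. Because the scheme updates
enthalpies with face fluxes, the interior enthalpy change telescopes exactly
to the time-integrated boundary fluxes, and the energy-balance closure is
reported with every run (it sits at round-off, far below the 0.1% assertion
used in tests). The sweep is restricted to the active region behind the
thermal disturbance front, which an explicit scheme grows by at most one
cell per step.

Verification compares the analytic and finite-difference solutions with the
grid resolution matched to the self-similar scale of each time window
(domain about five times the final front depth, spacing fine enough that the
front at the earliest compared time spans tens of cells): 0.006 m/601 nodes
for $t \le 5$ s, 0.012 m/1201 nodes at 10 s, 0.030 m/1001 nodes out to
100 s. On these grids the front agrees with $2\lambda\sqrt{\alpha_1 t}$
within 1% over $t \in [1, 100]$ s, profiles within 0.15 K, and the error
contracts by well over 1.5× per grid halving.

## DSC processing

A cooling run records time, programmed and actual sample temperature, and
the differential heat rate per unit mass (W/g, exothermic-positive). The
apparent specific heat capacity is `signal / |rate|`, assembled on a uniform
0.1 K grid **parameterised by the programmed temperature**, which stays
monotone through the transition while the sample temperature recalesces;
samples in a bin are averaged, which also sets the effective noise floor of
the curve.

**Onset detection.** Ice nucleation shows up as a sustained excursion of the
signal above its sensible baseline. The running baseline is a trailing-window
linear fit (default 100 samples, 5-sample guard; an expanding window is used
before a full trailing window exists, since a fixed short fit extrapolated
tens of samples ahead drifts by several noise sd). The noise sd comes from
the detrended first 30 samples; an excursion must exceed 5 sd for 5
consecutive samples. The reported onset is the sample temperature at the
**departure point** — the last sample before the excursion — because
nucleation triggers a near-instantaneous recalescence jump (~3 K), so the
first exceeding sample is already several kelvin warmer than the supercooled
nucleation temperature the measurement is after. A cross-check against the
first sustained positive excursion of $dT_\mathrm{sample}/dt$ during
programmed cooling is attached to the result. The rule is baseline-relative,
hence invariant to constant signal offsets; an absolute threshold floor
($10^{-8}$ W/g) guards the noise-free case.

**Excursion end and window.** For the analysis window the end of the
excursion is found against the pre-onset baseline extrapolated over the
transition, with the noise sd re-estimated from the full pre-onset segment
and the deviations smoothed over half a kelvin of programme. The window
closes at the first stretch of sub-threshold smoothed deviations — isolated
later fluctuations in a long tail must not stretch the window. The window is
then padded by 2 K on each side.

**Baseline and excess.** Linear fits to the flanking segments (15 grid
points each, at least 5 required) are joined linearly in temperature across
the window (a logistic blend is available behind `shape = "sigmoid"`); the
baseline coincides with the measured curve outside the window. The
equivalent specific latent heat capacity is the clipped excess
$\max(c_p - \mathrm{baseline}, 0)$ inside the window, and the latent heat is
its trapezoidal integral over temperature.

**Energy bookkeeping.** The same enthalpy has two faces: the time integral
of the excess signal and the temperature integral of the excess heat
capacity. Both are computed per run at the same effective resolution (the
time-domain excess is smoothed over one grid step of programme before
clipping, mirroring the bin averaging of the cp curve — otherwise clipping
unsmoothed noise biases the time-domain area upward at slow rates) and agree
within 1% on every synthetic run.

**End-transition temperature.** Freezing proceeds downward in temperature
from the onset, so the endpoint is defined from the cumulative excess area
taken from the warm end: the temperature where it reaches 99% of the total
(configurable). A fixed cumulative threshold, however, systematically stops
short on a peak that decays gradually — for a triangular decay the 99% point
sits $\sqrt{0.01} = 10\%$ of the transition width above the true end, which
can exceed a kelvin for wide transitions. The estimate is therefore refined
by linearly extrapolating the final decay flank (the segment between 80% and
99% cumulative area) to its zero crossing; when the flank is flat or rising
the plain cumulative point is returned, which for a rectangular excess on
$[-22, -12]$ °C gives $-21.9$ °C at the 99% rule and $-22$ °C at 100%.

**Reference-ratio heat capacity.** With a sapphire-like reference run under
the same programme, $c_p^\mathrm{sample}(T) = c_p^\mathrm{ref}(T)\,
(m_\mathrm{ref}/m_\mathrm{sample})\,(q_\mathrm{sample}/q_\mathrm{ref})$ in
terms of raw heat rates; since the stored channels are already per unit
mass, the mass factors cancel and the per-gram ratio is used directly. An
empty-crucible channel is assumed to have been subtracted by the instrument;
the pipeline does not model crucibles.

**Water content.** Drying at ~80 °C evaporates water only, so the water and
dry-matter mass fractions referred to the initial mass are complementary:
`water_mass_fraction(100, 28.7)` gives 0.713.

## Statistical relations

* `mean_latent_ci()` — Student-t interval for the mean latent heat,
  half-width $t_{0.975,\,n-1}\, s/\sqrt{n}$, as reported per liver.
* `fit_latent_vs_water()` — unweighted OLS of latent heat on water mass
  fraction, **pooled across livers**. Each liver carries a single water
  fraction (drying measurements showed no size dependence, so one value per
  liver), which makes a per-liver regression rank-deficient by construction;
  pooling is therefore the only well-posed default, and the linearity
  reflects that essentially only the tissue water freezes.
* `fit_onset_vs_lograte()` — OLS of onset temperature on
  $\log_{10}(\text{rate})$ restricted to rates ≥ 5 K/min, slope in K per
  decade (the onset–rate diagram is a semi-log plot with decade ticks).
* `plateau_test()` — the same fit below 1 K/min; the onset is flagged as a
  plateau when the slope's 95% CI contains zero. With two points the fit is
  exact and the interval collapses onto the estimate.

Regressions are unweighted (no measurement-error model), and estimates match
a brute-force normal-equations solve to $10^{-10}$ in the tests.

## The synthetic-data generator

`generate_dsc_run()` emulates what the calorimeter records during a
constant-cooling-rate freezing run:

* programmed temperature ramping at the set rate (default 5 K/min from
  +40 °C to −60 °C, 10 Hz sampling);
* nucleation at the scenario onset (default −12.2 °C, the measured value for
  the wettest liver sample at 5 K/min), with a recalescence jump of 3 K
  relaxing exponentially (τ = 5 s) — the supercooled sample rewarms abruptly
  when latent heat is first released;
* an exothermic excess shaped as an asymmetric triangle in time — sharp rise
  at nucleation, linear decay ending where the programme reaches the end
  temperature (default −22 °C) — with peak height normalised so the discrete
  trapezoidal integral equals the scenario latent heat (default 150 J/g,
  inside the measured 135.6–161.1 J/g range) exactly; nucleation and end are
  snapped to the sampling grid and the snapped truth is recorded with the
  run;
* a sensible term $c_p^\mathrm{mix}(T)\,|\mathrm{rate}|$ from gently sloped
  linear fluid (≈4.2 J/(g·K)) and dry-matter (≈1.3 J/(g·K)) curves mixed by
  the water fraction (default 0.713). Linear sensible curves keep the
  generator's baseline exactly representable by the linear baseline
  construction, so round-trip tests probe the transition processing rather
  than baseline model mismatch;
* Gaussian signal noise (default sd 0.002 W/g), fully reproducible from the
  scenario seed without touching the caller's RNG stream.

`generate_cohort()` draws per-liver water fractions and per-sample records
obeying a latent-heat law linear in water fraction (default
$L = 220\,w$ J/g, noise 4 J/g — the default slope and water range reproduce
per-liver means of roughly 140–160 J/g) and an onset law linear in
$\log_{10}$ rate above the plateau cutoff (default −6.15 K/decade anchored
at −12.2 °C at 5 K/min, the slope implied by the measured 5→25 K/min pair)
and flat below it, with the plateau level fixed by continuity at the cutoff
so slow-rate onsets sit warmer than fast-rate ones.

What the generator does **not** emulate — and what passing round-trip tests
therefore do not establish about instrument data: curvature or steps in the
sensible baseline across the transition (real frozen tissue has a markedly
lower $c_p$ than unfrozen), vendor-specific baseline constructions,
calibration drift, crucible heat transfer, nucleation stochasticity, and
1/f or correlated noise. The recovery tolerances quoted in the tests are
statements about the pipeline's self-consistency under the stated noise
model.

## Problem sizes used in tests

The verification suite solves the canonical scenario on the three
scale-matched grids above (the largest being 1201 nodes to 10 s and 1001
nodes to 100 s), runs the round-trip grid over cooling rates
{0.1, 1, 5, 25} K/min × onsets {−6, −12.2, −20} °C × latent heats
{135, 150, 165} J/g (36 runs; slow-rate runs sampled at 2 Hz, others at
10 Hz), and evaluates 500 seeded cohort replicates plus 2000 Gaussian
triples for interval coverage. These sizes keep the full suite at a couple
of minutes on one core while leaving every tolerance with a comfortable
margin.

## Known limitations

* One-dimensional planar geometry with a constant probe temperature; no
  perfusion or metabolic heat. Real cryoballoon geometry is curved and
  clinical probe temperatures are time-varying.
* The onset, baseline and end-transition rules are detection conventions;
  instruments and vendor software use their own (generally undisclosed)
  rules, so absolute agreement with a specific instrument is not claimed.
* The property defaults are a documented liver-like set, not a fitted
  appendix of measured values; model outputs for other tissues require
  user-supplied properties.
* Latent-heat integration assumes the exothermic-positive sign convention
  and a cooling (negative-rate) programme; heating branches are not
  analysed.
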