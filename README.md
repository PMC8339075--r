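# cryotherm

Thermal analysis of tissue freezing during cryoablation: an analytical
freezing-front model, a differential scanning calorimetry (DSC) processing
pipeline, and the statistical relations that link what a calorimeter
measures to what happens at the probe–tissue interface.

## Who this is for

Cryoablation destroys target tissue (for example around the pulmonary veins,
to treat atrial fibrillation) by freezing it with a cold probe or balloon.
Two groups of users meet here: modellers who need the temperature field and
ice-front kinetics for a probe held at a constant ablative temperature, and
experimentalists who need to reduce DSC cooling thermograms of tissue to a
few physically meaningful numbers — the supercooled ice-onset temperature,
the latent heat, and the temperature at which the transition completes.

## The model at the core

For semi-infinite tissue initially at body temperature `T_i`, surface held
at the ablative temperature `T_s`, freezing at the ice-onset temperature
`T_f`, the Neumann solution of the two-phase Stefan problem gives a front

    s(t) = 2 λ √(α₁ t)

with erf/erfc profiles in the frozen and unfrozen regions, where λ solves

    k₁(T_f − T_s) e^(−λ²) / (√(πα₁) erf λ)
      − k₂(T_i − T_f) e^(−λ² α₁/α₂) / (√(πα₂) erfc(λ √(α₁/α₂)))
      = λ ρ L √α₁ .

The front is linear in √t; the interface gradients and the surface heat flux
decay as 1/√t, with the subtracted flux proportional to the front growth
rate. An explicit enthalpy-method finite-difference solver (`fd_solve`)
provides an independent brute-force check of all of this.

On the calorimetric side, the apparent heat capacity of a cooling run splits
at a constructed baseline into sensible heat (below) and an *equivalent
specific latent heat capacity* (the excess above); the latent heat is the
temperature integral of the excess and equals the time integral of the
excess DSC signal. Across samples, latent heat is linear in the water mass
fraction, and the ice onset falls linearly with log₁₀ of the cooling rate in
the fast-cooling regime while plateauing below about 1 K/min.

## Worked example

```r
library(cryotherm)

## freezing front under a -54 degC probe, onset -23 degC, body 37 degC
props <- liver_tissue_properties()
bc <- boundary_conditions(T_surface = -54, T_onset = -23, T_body = 37)
sol <- solve_front_constant(props, bc)
sol
#> Neumann two-phase freezing solution
#>   lambda      : 0.243813 (residual 2.22e-16)
#>   T_surface   : -54 degC, T_onset: -23 degC, T_body: 37 degC
#>   front depth : 1.578 mm at 10 s, 3.866 mm at 60 s

cbind(interface_gradients(sol, c(1, 10, 60)),
      flux_W_per_m2 = surface_heat_flux(sol, c(1, 10, 60)))
#>   time_s grad_frozen_K_per_m grad_unfrozen_K_per_m flux_W_per_m2
#> 1      1           59689.112             163006.66     139358.75
#> 2     10           18875.355              51547.23      44069.11
#> 3     60            7705.831              21044.07      17991.14

## a synthetic 5 K/min DSC run (onset -12.2 degC, L = 150 J/g) analysed blind
run <- generate_dsc_run(run_scenario(seed = 42))
analyze_transition(run)
#> DSC transition analysis: synth_r5
#>   ice onset        :   -12.19 degC
#>   end transition   :   -22.00 degC
#>   latent heat      :   150.02 J/g
#>   window           : [-24.2, -10.2] degC
#>   area check       : 150.03 (time) vs 150.02 (temperature) J/g

## cohort statistics: latent heat vs water content, onset vs cooling rate
cohort <- generate_cohort(cohort_scenario(seed = 1))
fit_latent_vs_water(cohort)
#> fit (n = 18, residual sd = 2.881)
#>   intercept        -3.238   95% CI [-45.48, 39]
#>   slope             225.2   95% CI [162.5, 288]
fit_onset_vs_lograte(cohort)   # K per decade, rates >= 5 K/min
#> fit (n = 9, residual sd = 0.3052)
#>   intercept        -8.598   95% CI [-9.498, -7.698]
#>   slope            -5.836   95% CI [-6.676, -4.995]
plateau_test(cohort)           # onset flat below 1 K/min?
#> fit (n = 6, residual sd = 0.5876)
#>   intercept        -7.196   95% CI [-8.603, -5.789]
#>   slope            0.5343   95% CI [-1.371, 2.44]
#>   plateau: TRUE
```

The freezing-front table reads: one minute into an application the front
sits 3.9 mm deep, while the gradient at the frozen–unfrozen interface has
fallen about eightfold from its 1 s value — prolonging delivery yields
diminishing lesion depth but keeps cooling the far side. The transition
analysis recovers the programmed onset (−12.2 °C), end (−22 °C) and latent
heat (150 J/g) of the simulated run, and the two area bookkeepings of the
same enthalpy agree to 0.01 J/g. The cohort fits recover the generating laws
(slope 220 J/g per unit water fraction; −6.15 K/decade) within their 95%
intervals, and the slow-rate onsets show no rate dependence.

Batch work goes through `run_pipeline()`, which takes a config (list or
YAML), analyses CSV or synthetic runs, fits a cohort, tabulates a
freezing-front scenario, and writes deterministic CSV/JSON outputs plus a
provenance manifest; re-running an identical config reproduces byte-identical
files.

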