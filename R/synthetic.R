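# Seeded generators of DSC runs and sample cohorts with the statistical
# structure the analysis assumes, so every pipeline stage is testable
# without instrument data.

#' Scenario for a synthetic DSC cooling run
#'
#' Defines the ground truth of a simulated constant-cooling-rate run with a
#' supercooled exothermic freezing transition: programmed ramp, nucleation
#' (ice-onset) temperature, recalescence jump, latent heat, end-transition
#' temperature, sensible heat capacities of the fluid and dry components,
#' noise level and sampling rate.
#'
#' Defaults emulate a liver-like sample cooled at 5 K/min: onset -12.2 degC,
#' transition complete near -22 degC, latent heat 150 J/g, recalescence jump
#' 3 K relaxing with a 5 s time constant, water fraction 0.713, Gaussian
#' signal noise of sd 0.002 W/g sampled at 10 Hz.
#'
#' @param mass Sample mass, mg.
#' @param water_fraction Water mass fraction of the sample.
#' @param cooling_rate Programme rate magnitude, K/min (> 0; the programme
#'   cools, so the signed nominal rate of the run is its negative).
#' @param T_start,T_stop Programme start / stop temperatures, degC.
#' @param T_onset_true Nucleation temperature, degC.
#' @param T_end_true Temperature at which latent-heat release is complete,
#'   degC (below `T_onset_true`).
#' @param L_true Latent heat, J/g (0 produces a pure sensible run with no
#'   transition).
#' @param recalescence_K Instantaneous sample-temperature jump at
#'   nucleation, K.
#' @param recalescence_tau Relaxation time constant of the jump, s.
#' @param cp_fluid,cp_solid Sensible heat capacity curves, J/(g K), of the
#'   fluid and dehydrated components ([cp_curve()]); mixed by
#'   `water_fraction` into the sensible baseline.
#' @param noise_sd Gaussian noise sd on the signal, W/g.
#' @param sample_hz Sampling rate, 1/s.
#' @param seed Integer RNG seed; the run is fully reproducible from it.
#' @param sample_id Label.
#' @return A `run_scenario` object.
#' @export
run_scenario <- function(mass = 20, water_fraction = 0.713, cooling_rate = 5,
                         T_start = 40, T_stop = -60,
                         T_onset_true = -12.2, T_end_true = -22,
                         L_true = 150, recalescence_K = 3, recalescence_tau = 5,
                         cp_fluid = default_cp_fluid(),
                         cp_solid = default_cp_solid(),
                         noise_sd = 0.002, sample_hz = 10, seed = 1,
                         sample_id = NULL) {
  if (cooling_rate <= 0) stopf("cooling_rate must be a positive magnitude in K/min")
  if (!(T_stop < T_end_true && T_end_true < T_onset_true && T_onset_true < T_start)) {
    stopf("scenario requires T_stop < T_end_true < T_onset_true < T_start")
  }
  if (L_true < 0 || recalescence_K < 0 || noise_sd < 0) {
    stopf("L_true, recalescence_K and noise_sd must be non-negative")
  }
  if (water_fraction < 0 || water_fraction > 1) stopf("water_fraction must be in [0, 1]")
  stopifnot(inherits(cp_fluid, "cp_curve"), inherits(cp_solid, "cp_curve"))
  structure(list(mass = mass, water_fraction = water_fraction,
                 cooling_rate = cooling_rate, T_start = T_start, T_stop = T_stop,
                 T_onset_true = T_onset_true, T_end_true = T_end_true,
                 L_true = L_true, recalescence_K = recalescence_K,
                 recalescence_tau = recalescence_tau,
                 cp_fluid = cp_fluid, cp_solid = cp_solid,
                 noise_sd = noise_sd, sample_hz = sample_hz, seed = seed,
                 sample_id = sample_id %||%
                   sprintf("synth_r%g", cooling_rate)),
            class = "run_scenario")
}

#' Default sensible heat capacity curves for synthetic runs
#'
#' Gently sloped linear curves: a water-like fluid component around
#' 4.2 J/(g K) and a dry-matter component around 1.3 J/(g K) at room
#' temperature. Linearity in temperature keeps the sensible baseline of a
#' generated run exactly representable by the linear baseline construction,
#' so round-trip tests probe the transition processing rather than baseline
#' model mismatch.
#'
#' @return A [cp_curve()] spanning -80 to 50 degC.
#' @export
default_cp_fluid <- function() {
  Tg <- seq(-80, 50, by = 5)
  cp_curve(Tg, 4.18 + 0.001 * Tg)
}

#' @rdname default_cp_fluid
#' @export
default_cp_solid <- function() {
  Tg <- seq(-80, 50, by = 5)
  cp_curve(Tg, 1.30 + 0.003 * Tg)
}

#' Generate a synthetic DSC cooling run
#'
#' Simulates the calorimeter output for a [run_scenario()]: the programmed
#' temperature ramps at the set rate; the sample temperature follows it
#' until nucleation, jumps by `recalescence_K` and relaxes back
#' exponentially; the signal is the sensible term `cp_mix(T) * |rate|` plus
#' an exothermic excess peak (asymmetric triangle in time: sharp rise at
#' nucleation, linear decay ending where the programme reaches
#' `T_end_true`) whose time integral equals `L_true`, plus Gaussian noise.
#'
#' The nucleation and end times are snapped to the sampling grid so the
#' discrete trapezoidal integral of the programmed excess equals `L_true`
#' exactly; the snapped ground truth is recorded in the run's `truth`
#' attribute (`T_onset`, `T_end`, `L`).
#'
#' @param sc A [run_scenario()].
#' @return A [dsc_run()] with attributes `truth` and `scenario`.
#' @export
#' @examples
#' run <- generate_dsc_run(run_scenario(seed = 42))
#' attr(run, "truth")
generate_dsc_run <- function(sc) {
  stopifnot(inherits(sc, "run_scenario"))
  rate <- -sc$cooling_rate / 60                 # K/s, negative
  dt <- 1 / sc$sample_hz
  t_total <- (sc$T_stop - sc$T_start) / rate
  tt <- seq(0, t_total, by = dt)
  Tp <- sc$T_start + rate * tt

  cp_mix <- sc$water_fraction * cp_at(sc$cp_fluid, Tp) +
    (1 - sc$water_fraction) * cp_at(sc$cp_solid, Tp)
  signal <- cp_mix * abs(rate)
  Ts <- Tp

  truth <- list(T_onset = NA_real_, T_end = NA_real_, L = sc$L_true)
  if (sc$L_true > 0) {
    i0 <- which.min(abs(Tp - sc$T_onset_true))   # snap nucleation to the grid
    i1 <- which.min(abs(Tp - sc$T_end_true))
    if (i1 <= i0 + 2) stopf("transition too short for the sampling rate")
    t0 <- tt[i0]
    t1 <- tt[i1]
    # peak height set so the discrete trapezoidal integral (including the
    # one-sample leading ramp) equals L_true exactly
    h <- 2 * sc$L_true / ((t1 - t0) + dt)
    ex <- numeric(length(tt))
    idx <- i0:i1
    ex[idx] <- h * (1 - (tt[idx] - t0) / (t1 - t0))
    signal <- signal + ex

    post <- tt >= t0
    Ts[post] <- Tp[post] + sc$recalescence_K *
      exp(-(tt[post] - t0) / sc$recalescence_tau)
    truth$T_onset <- Tp[i0]
    truth$T_end <- Tp[i1]
  }

  if (sc$noise_sd > 0) {
    signal <- signal + with_seed(sc$seed, rnorm(length(tt), sd = sc$noise_sd))
  }

  run <- dsc_run(tt, Tp, Ts, signal, mass = sc$mass,
                 cooling_rate = -sc$cooling_rate, sample_id = sc$sample_id)
  attr(run, "truth") <- truth
  attr(run, "scenario") <- sc
  run
}

#' Scenario for a synthetic sample cohort
#'
#' Parameterises the statistical laws obeyed by a cohort of liver samples:
#' latent heat linear in water fraction, and onset temperature flat below a
#' slow-rate cutoff, linear in `log10(rate)` above a fast-rate threshold,
#' with the plateau level set by continuity at the cutoff (so slow-rate
#' onsets sit warmer than fast-rate ones). Each liver gets a single water
#' fraction; cooling rates are cycled over `rate_grid` within each liver.
#'
#' Defaults: 3 livers x 6 rates (0.1-25 K/min), water fractions spread over
#' 0.60-0.78, latent law `L = 220 w` J/g with 4 J/g noise, onset slope
#' -6.15 K/decade above 5 K/min anchored at -12.2 degC at 5 K/min, plateau
#' below 1 K/min at the matching level, onset noise 0.5 K.
#'
#' @param n_livers Number of livers (groups sharing a water fraction).
#' @param rate_grid Cooling rates, K/min.
#' @param water_range Range the per-liver water fractions are drawn from.
#' @param latent_intercept,latent_slope,latent_noise_sd Latent-heat law
#'   `L = intercept + slope * w + N(0, sd)`, J/g.
#' @param onset_at_5,onset_slope Onset law above `rate_threshold`:
#'   `T_onset = onset_at_5 + onset_slope * log10(rate / 5)`, degC and
#'   K/decade.
#' @param rate_threshold Nominal start of the fast-rate regime, K/min
#'   (metadata used when fitting the generated cohort).
#' @param plateau_cutoff Rate below which the onset law is flat, K/min.
#' @param onset_noise_sd Gaussian noise on the onset, K.
#' @param seed Integer RNG seed.
#' @return A `cohort_scenario` object.
#' @export
cohort_scenario <- function(n_livers = 3, rate_grid = c(0.1, 0.5, 1, 5, 10, 25),
                            water_range = c(0.60, 0.78),
                            latent_intercept = 0, latent_slope = 220,
                            latent_noise_sd = 4,
                            onset_at_5 = -12.2, onset_slope = -6.15,
                            rate_threshold = 5, plateau_cutoff = 1,
                            onset_noise_sd = 0.5, seed = 1) {
  if (any(rate_grid <= 0)) stopf("rate grid must be positive")
  if (n_livers < 1 || n_livers * length(rate_grid) < 2) {
    stopf("cohort must contain at least 2 samples")
  }
  structure(as.list(environment()), class = "cohort_scenario")
}

# Deterministic onset law of the cohort scenario (noise-free part): linear
# in log10(rate) down to the plateau cutoff, constant (at the law's value at
# the cutoff, i.e. warmer than any fast-rate onset) below it.
onset_law <- function(sc, rate) {
  sc$onset_at_5 + sc$onset_slope * log10(pmax(rate, sc$plateau_cutoff) / 5)
}

#' Generate a synthetic sample cohort
#'
#' Draws per-liver water fractions and per-sample onset and latent-heat
#' records according to the laws of a [cohort_scenario()]; deterministic
#' under the scenario seed.
#'
#' @param sc A [cohort_scenario()].
#' @return A data.frame of sample records: `sample_id`, `liver_id`,
#'   `water_fraction`, `cooling_rate` (K/min, magnitude), `T_onset` (degC),
#'   `latent_heat` (J/g).
#' @export
#' @examples
#' head(generate_cohort(cohort_scenario(seed = 7)))
generate_cohort <- function(sc) {
  stopifnot(inherits(sc, "cohort_scenario"))
  with_seed(sc$seed, {
    nr <- length(sc$rate_grid)
    liver <- rep(seq_len(sc$n_livers), each = nr)
    rate <- rep(sc$rate_grid, times = sc$n_livers)
    w_liver <- sort(stats::runif(sc$n_livers, sc$water_range[1], sc$water_range[2]))
    w <- w_liver[liver]
    onset <- onset_law(sc, rate) + stats::rnorm(length(rate), sd = sc$onset_noise_sd)
    latent <- sc$latent_intercept + sc$latent_slope * w +
      stats::rnorm(length(rate), sd = sc$latent_noise_sd)
    data.frame(
      sample_id = sprintf("L%d_r%g", liver, rate),
      liver_id = sprintf("liver_%d", liver),
      water_fraction = w,
      cooling_rate = rate,
      T_onset = onset,
      latent_heat = latent
    )
  })
}
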