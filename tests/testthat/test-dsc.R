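test_that("cp curves validate their grid and support mixtures", {
  expect_error(cp_curve(c(0, 0, 1), c(1, 2, 3)), "monotone")
  expect_error(cp_curve(1:3, c(1, NA, 3)), "finite")
  Tg <- seq(-40, 20, by = 1)
  fl <- cp_curve(Tg, rep(4.0, length(Tg)))
  so <- cp_curve(Tg, rep(1.5, length(Tg)))
  expect_equal(mixture_cp(1, fl, so)$cp, fl$cp)
  expect_equal(mixture_cp(0, fl, so)$cp, so$cp)
  expect_equal(unique(mixture_cp(0.7, fl, so)$cp), 3.25)
  other <- cp_curve(seq(-40, 20, by = 2), rep(1, 31))
  expect_error(mixture_cp(0.5, fl, other), "grid mismatch")
})

test_that("water mass fraction is the complementary evaporated fraction", {
  expect_equal(water_mass_fraction(50, 50), 0)
  expect_equal(water_mass_fraction(50, 0), 1)
  expect_equal(water_mass_fraction(100, 28.7), 0.713)
  expect_error(water_mass_fraction(10, 11), "m_dry")
  expect_error(water_mass_fraction(0, 0), "positive")
})

test_that("reference-ratio cp recovers identity, linearity and a programmed curve", {
  Tg <- seq(-80, 50, by = 5)
  sapph <- cp_curve(Tg, 0.72 + 0.0012 * Tg)
  ref <- generate_dsc_run(run_scenario(water_fraction = 1, cp_fluid = sapph,
                                       L_true = 0, noise_sd = 0,
                                       recalescence_K = 0, seed = 2, mass = 25))
  # identical run as sample -> reference cp back
  ident <- cp_from_ratio(ref, ref, sapph)
  expect_equal(ident$cp, cp_at(sapph, ident$temperature), tolerance = 1e-12)
  # doubling the per-gram signal doubles the cp
  ref2 <- dsc_run(ref$time, ref$T_programmed, ref$T_sample, 2 * ref$dsc_signal,
                  mass = 25, cooling_rate = -5)
  twice <- cp_from_ratio(ref2, ref, sapph)
  expect_equal(twice$cp, 2 * cp_at(sapph, twice$temperature), tolerance = 1e-12)
  # round trip: mixture sensible curve recovered within 0.5% pointwise
  smp <- generate_dsc_run(run_scenario(L_true = 0, noise_sd = 0,
                                       recalescence_K = 0, seed = 3, mass = 18))
  cpr <- cp_from_ratio(smp, ref, sapph)
  truth <- 0.713 * cp_at(default_cp_fluid(), cpr$temperature) +
    0.287 * cp_at(default_cp_solid(), cpr$temperature)
  expect_lt(max(abs(cpr$cp / truth - 1)), 0.005)
  # non-overlapping ranges
  shifted <- dsc_run(ref$time, ref$T_programmed + 200, ref$T_sample + 200,
                     ref$dsc_signal, mass = 25, cooling_rate = -5)
  expect_error(cp_from_ratio(shifted, ref, sapph), "non-overlapping")
  # near-zero reference signal
  tiny <- dsc_run(ref$time, ref$T_programmed, ref$T_sample,
                  ref$dsc_signal * 1e-12 * (seq_along(ref$time) %% 2),
                  mass = 25, cooling_rate = -5)
  expect_error(cp_from_ratio(ref, tiny, sapph), "division guard")
})

test_that("onset detection finds the supercooled nucleation temperature", {
  # pure sensible cooling, no noise: nothing to detect
  quiet <- generate_dsc_run(quiet_scenario())
  expect_error(detect_onset(quiet), "no-transition-detected")
  # programmed onset -12.2 at 5 K/min with default noise: within 0.2 K
  run <- generate_dsc_run(run_scenario(seed = 42))
  truth <- attr(run, "truth")
  o <- detect_onset(run)
  expect_lt(abs(as.numeric(o) - truth$T_onset), 0.2)
  # invariant under a constant signal offset (baseline-relative rule)
  shifted <- dsc_run(run$time, run$T_programmed, run$T_sample,
                     run$dsc_signal + 0.37, mass = 20, cooling_rate = -5)
  expect_equal(as.numeric(detect_onset(shifted)), as.numeric(o))
})

test_that("baseline construction bridges the flanks linearly", {
  Tg <- seq(-40, 0, by = 0.1)
  lin <- cp_curve(Tg, 3 + 0.01 * Tg)
  b <- construct_baseline(lin, c(-10, -30))
  expect_equal(b$cp, lin$cp, tolerance = 1e-10)
  ex <- equivalent_latent_cp(lin, b)
  expect_true(all(ex$cp == 0))
  # triangular excess over a flat cp: baseline stays at the flat level
  flat <- 2 + numeric(length(Tg))
  tri <- pmax(0, 10 * (1 - abs(Tg + 20) / 5))
  withtri <- cp_curve(Tg, flat + tri)
  b2 <- construct_baseline(withtri, c(-12, -28))
  expect_equal(b2$cp, flat, tolerance = 1e-10)
  expect_error(construct_baseline(lin, c(-0.2, -39.8)), "insufficient-flank")
})

test_that("equivalent latent cp is the clipped excess and shift-invariant", {
  Tg <- seq(-40, 0, by = 0.1)
  flat <- cp_curve(Tg, rep(2, length(Tg)))
  b <- construct_baseline(flat, c(-10, -30))
  expect_true(all(equivalent_latent_cp(flat, b)$cp == 0))
  tri <- pmax(0, 20 * (1 - abs(Tg + 20) / 7.5))
  cpx <- cp_curve(Tg, 2 + tri)
  ex1 <- equivalent_latent_cp(cpx, construct_baseline(cpx, c(-10, -30)))
  cps <- cp_curve(Tg, 7 + tri)  # common vertical shift
  ex2 <- equivalent_latent_cp(cps, construct_baseline(cps, c(-10, -30)))
  expect_equal(ex1$cp, ex2$cp, tolerance = 1e-9)
  mis <- cp_curve(seq(-40, 0, by = 0.2), rep(2, 201))
  expect_error(equivalent_latent_cp(cpx, mis), "alignment")
})

test_that("latent heat integrates the excess curve", {
  Tg <- seq(-40, 0, by = 0.1)
  zero <- cp_curve(Tg, numeric(length(Tg)))
  expect_warning(L0 <- latent_heat(zero), "zero")
  expect_identical(L0, 0)
  # triangle of height 20 J/(g K) and base 15 K -> 150 J/g
  tri <- cp_curve(Tg, pmax(0, 20 * (1 - abs(Tg + 20) / 7.5)))
  expect_equal(latent_heat(tri), 150, tolerance = 1e-9)
})

test_that("end-transition temperature follows the cumulative rule with flank refinement", {
  Tg <- seq(-35, 0, by = 0.1)
  rect <- cp_curve(Tg, as.numeric(Tg >= -22 & Tg <= -12) * 10)
  e99 <- end_transition_temperature(rect, threshold = 0.99)
  expect_equal(as.numeric(e99), -21.9, tolerance = 0.06)
  e100 <- end_transition_temperature(rect, threshold = 1)
  expect_equal(as.numeric(e100), -22, tolerance = 0.06)
  # triangular decay: refinement lands on the true apex regardless of width
  tri <- cp_curve(Tg, pmax(0, (Tg + 22) * ((Tg + 22) <= 10) * ((Tg + 22) >= 0)))
  expect_equal(as.numeric(end_transition_temperature(tri)), -22, tolerance = 0.05)
  zero <- cp_curve(Tg, numeric(length(Tg)))
  expect_error(end_transition_temperature(zero), "no-transition")
})

test_that("full transition analysis recovers the programmed run", {
  run <- generate_dsc_run(run_scenario(seed = 42))
  truth <- attr(run, "truth")
  a <- analyze_transition(run)
  expect_lt(abs(a$T_onset - truth$T_onset), 0.2)
  expect_lt(abs(a$T_end - truth$T_end), 0.5)
  expect_lt(abs(a$latent_heat / truth$L - 1), 0.02)
  expect_lt(abs(a$excess_area_time / a$excess_area_temperature - 1), 0.01)
  expect_lt(a$T_end, a$T_onset)
  expect_true(all(a$equivalent_latent_cp$cp >= 0))
})

test_that("latent heat is insensitive to the sampling rate", {
  L10 <- analyze_transition(generate_dsc_run(run_scenario(seed = 9, sample_hz = 10)))$latent_heat
  L5 <- analyze_transition(generate_dsc_run(run_scenario(seed = 9, sample_hz = 5)))$latent_heat
  expect_lt(abs(L10 / L5 - 1), 0.005)
})
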