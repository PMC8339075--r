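test_that("generated runs are deterministic under seed and leave the RNG alone", {
  r1 <- generate_dsc_run(run_scenario(seed = 11))
  r2 <- generate_dsc_run(run_scenario(seed = 11))
  expect_identical(r1$dsc_signal, r2$dsc_signal)
  r3 <- generate_dsc_run(run_scenario(seed = 12))
  expect_false(identical(r1$dsc_signal, r3$dsc_signal))
  # global RNG stream is untouched
  set.seed(99)
  x1 <- rnorm(3)
  set.seed(99)
  invisible(generate_dsc_run(run_scenario(seed = 11)))
  x2 <- rnorm(3)
  expect_identical(x1, x2)
})

test_that("runs obey the DSC container invariants", {
  run <- generate_dsc_run(run_scenario(seed = 4))
  expect_s3_class(run, "dsc_run")
  med_rate <- median(diff(run$T_programmed) / diff(run$time)) * 60
  expect_lt(abs(med_rate - (-5)) / 5, 0.02)
  expect_true(all(diff(run$time) > 0))
})

test_that("the programmed excess integrates to the scenario latent heat", {
  for (rate in c(1, 5, 25)) {
    sc <- run_scenario(cooling_rate = rate, noise_sd = 0, seed = 1)
    run <- generate_dsc_run(sc)
    cpm <- sc$water_fraction * cp_at(sc$cp_fluid, run$T_programmed) +
      (1 - sc$water_fraction) * cp_at(sc$cp_solid, run$T_programmed)
    excess <- run$dsc_signal - cpm * abs(rate) / 60
    got <- pracma::trapz(run$time, excess)
    expect_lt(abs(got / sc$L_true - 1), 1e-3)
  }
})

test_that("recalescence lifts the sample temperature by about 3 K at nucleation", {
  run <- generate_dsc_run(run_scenario(seed = 7, noise_sd = 0))
  jump <- max(run$T_sample - run$T_programmed)
  expect_equal(jump, 3, tolerance = 1e-9)
  truth <- attr(run, "truth")
  i0 <- which.max(run$T_sample - run$T_programmed)
  expect_lt(abs(run$T_programmed[i0] - truth$T_onset), 0.05)
})

test_that("a zero-latent-heat scenario is pure sensible cooling", {
  sc <- quiet_scenario()
  run <- generate_dsc_run(sc)
  cpm <- sc$water_fraction * cp_at(sc$cp_fluid, run$T_programmed) +
    (1 - sc$water_fraction) * cp_at(sc$cp_solid, run$T_programmed)
  expect_equal(run$dsc_signal, cpm * 5 / 60, tolerance = 1e-12)
  expect_identical(run$T_sample, run$T_programmed)
})

test_that("cohorts are seeded-deterministic and follow the programmed laws exactly at zero noise", {
  c1 <- generate_cohort(cohort_scenario(seed = 21))
  c2 <- generate_cohort(cohort_scenario(seed = 21))
  expect_identical(c1, c2)
  c0 <- generate_cohort(cohort_scenario(seed = 3, latent_noise_sd = 0,
                                        onset_noise_sd = 0))
  expect_equal(c0$latent_heat, 220 * c0$water_fraction, tolerance = 1e-12)
  fast <- c0$cooling_rate >= 5
  expect_equal(c0$T_onset[fast], -12.2 - 6.15 * log10(c0$cooling_rate[fast] / 5),
               tolerance = 1e-12)
  slow <- c0$cooling_rate <= 1
  expect_equal(unique(round(c0$T_onset[c0$cooling_rate < 1], 9)),
               round(-12.2 - 6.15 * log10(1 / 5), 9))
})

test_that("scenario invariants are enforced", {
  expect_error(run_scenario(T_onset_true = -25), "T_stop < T_end_true")
  expect_error(run_scenario(cooling_rate = -5), "positive magnitude")
  expect_error(cohort_scenario(rate_grid = c(-1, 5)), "positive")
})
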