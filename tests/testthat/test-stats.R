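test_that("mean latent heat CI uses the t distribution", {
  r <- mean_latent_ci(c(150, 150, 150))
  expect_equal(unname(r$estimates["mean"]), 150)
  expect_equal(unname(r$ci95[1, 2] - r$estimates["mean"]), 0)
  r2 <- mean_latent_ci(c(1, 2, 3))
  expect_equal(unname(r2$estimates["mean"]), 2)
  expect_equal(unname(r2$ci95[1, 2] - 2), qt(0.975, 2) / sqrt(3), tolerance = 1e-12)
  expect_error(mean_latent_ci(150), "insufficient-data")
})

test_that("CI coverage is near nominal for Gaussian triples", {
  set.seed(2024)
  hits <- replicate(2000, {
    ci <- mean_latent_ci(rnorm(3, 150, 5))$ci95
    ci[1, 1] <= 150 && 150 <= ci[1, 2]
  })
  expect_gt(mean(hits), 0.93)
  expect_lt(mean(hits), 0.97)
})

test_that("latent vs water regression matches exact data and normal equations", {
  w <- c(0.6, 0.65, 0.7, 0.75)
  rec <- make_records(w, 5, -12, 220 * w)
  f <- fit_latent_vs_water(rec)
  expect_equal(unname(f$estimates["slope"]), 220, tolerance = 1e-9)
  expect_equal(unname(f$estimates["intercept"]), 0, tolerance = 1e-9)
  expect_equal(f$residual_sd, 0, tolerance = 1e-9)
  # brute-force normal equations on a noisy fixture
  set.seed(5)
  recn <- make_records(runif(12, 0.6, 0.8), 5, -12,
                       10 + 200 * runif(12, 0.6, 0.8) + rnorm(12))
  fn <- fit_latent_vs_water(recn)
  X <- cbind(1, recn$water_fraction)
  beta <- solve(t(X) %*% X, t(X) %*% recn$latent_heat)
  expect_equal(unname(fn$estimates), as.numeric(beta), tolerance = 1e-10)
  expect_error(fit_latent_vs_water(make_records(rep(0.7, 3), 5, -12, c(1, 2, 3))),
               "rank-deficiency")
})

test_that("onset vs log-rate slope reproduces the two-point fast-cooling fit", {
  rec <- make_records(0.7, c(5, 25), c(-12.2, -16.5), 150)
  f <- fit_onset_vs_lograte(rec)
  expect_equal(unname(f$estimates["slope"]), -4.3 / log10(5), tolerance = 1e-9)
  flat <- make_records(0.7, c(5, 10, 25), rep(-14, 3), 150)
  expect_equal(unname(fit_onset_vs_lograte(flat)$estimates["slope"]), 0,
               tolerance = 1e-12)
  slow <- make_records(0.7, c(0.1, 0.5), c(-7, -7.5), 150)
  expect_error(fit_onset_vs_lograte(slow), "insufficient-data")
})

test_that("plateau flag reflects whether the low-rate slope CI contains zero", {
  const <- make_records(0.7, rep(c(0.1, 0.3, 0.6), 2), rep(-7.9, 6), 150)
  p <- plateau_test(const)
  expect_equal(unname(p$estimates["slope"]), 0, tolerance = 1e-12)
  expect_true(p$plateau)
  sloped <- make_records(0.7, rep(c(0.1, 0.5), 3),
                         -6 * log10(rep(c(0.1, 0.5), 3)) - 10 +
                           c(0.01, -0.01, 0.02, -0.02, 0, 0.01), 150)
  expect_false(plateau_test(sloped)$plateau)
  expect_error(plateau_test(make_records(0.7, 0.5, -8, 150)), "insufficient-data")
})

test_that("cohort fits recover the programmed laws within their CIs", {
  hits <- vapply(1:200, function(s) {
    ch <- generate_cohort(cohort_scenario(seed = s))
    fw <- fit_latent_vs_water(ch)
    fo <- fit_onset_vs_lograte(ch)
    pl <- plateau_test(ch)
    c(fw$ci95["slope", 1] <= 220 && 220 <= fw$ci95["slope", 2],
      fo$ci95["slope", 1] <= -6.15 && -6.15 <= fo$ci95["slope", 2],
      pl$plateau)
  }, logical(3))
  expect_gt(mean(hits[1, ]), 0.9)
  expect_gt(mean(hits[2, ]), 0.9)
  expect_gt(mean(hits[3, ]), 0.9)
})
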