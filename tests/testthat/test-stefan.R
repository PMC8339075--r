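test_that("boundary conditions enforce the physical ordering", {
  expect_error(boundary_conditions(-23, -23, 37), "degenerate-no-frozen-phase")
  expect_error(boundary_conditions(-10, -23, 37), "degenerate-no-frozen-phase")
  expect_error(boundary_conditions(-54, 40, 37), "below T_body")
})

test_that("tissue properties must be positive and diffusivities consistent", {
  expect_error(liver_tissue_properties(L = -1), "strictly positive")
  p <- liver_tissue_properties()
  expect_equal(p$alpha_frozen, p$k_frozen / (p$rho * p$c_frozen))
  expect_equal(p$alpha_unfrozen, p$k_unfrozen / (p$rho * p$c_unfrozen))
})

test_that("front constant zeroes the transcendental residual", {
  expect_lt(abs(default_sol$residual), 1e-10)
  expect_lt(abs(stefan_residual(default_sol$lam, default_props, default_bc)), 1e-10)
  # across a parameter grid
  for (Ts in c(-80, -54, -30)) {
    for (L in c(5e4, 1.59e5, 3.3e5)) {
      sol <- solve_front_constant(liver_tissue_properties(L = L),
                                  boundary_conditions(Ts, -23, 37))
      expect_lt(abs(sol$residual), 1e-10)
    }
  }
})

test_that("pure-conduction limit reproduces the single-phase erf solution", {
  pc <- tissue_properties(0.55, 0.55, 1050, 3600, 3600, 1e-6)
  sol <- solve_front_constant(pc, default_bc)
  # lambda = inverse-erf((T_f - T_s)/(T_i - T_s)); frozen value of erfinv(31/91)
  expect_equal(sol$lam, pracma::erfinv(31 / 91), tolerance = 1e-6)
  xs <- seq(0, 0.02, length.out = 200)
  erf_profile <- -54 + 91 * pracma::erf(xs / (2 * sqrt(pc$alpha_unfrozen * 10)))
  expect_lt(max(abs(temperature_profile(sol, xs, 10) - erf_profile)), 1e-6)
})

test_that("lambda is monotone in probe temperature and latent heat", {
  lams_Ts <- sapply(seq(-90, -30, by = 10), function(Ts) {
    solve_front_constant(default_props, boundary_conditions(Ts, -23, 37))$lam
  })
  expect_true(all(diff(lams_Ts) < 0))  # colder probe (first entries) -> larger lambda
  lams_L <- sapply(seq(5e4, 4e5, length.out = 8), function(L) {
    solve_front_constant(liver_tissue_properties(L = L), default_bc)$lam
  })
  expect_true(all(diff(lams_L) < 0))
})

test_that("front position follows the square-root-of-time law", {
  expect_identical(front_position(default_sol, 0), 0)
  tset <- c(0.5, 3, 12, 77)
  expect_equal(front_position(default_sol, 4 * tset),
               2 * front_position(default_sol, tset))
  tt <- 1:100
  slope <- coef(lm(log(front_position(default_sol, tt)) ~ log(tt)))[2]
  expect_equal(unname(slope), 0.5, tolerance = 1e-9)
  expect_error(front_position(default_sol, -1), "non-negative")
})

test_that("temperature profile honours boundary, interface and far field", {
  s <- front_position(default_sol, 10)
  expect_equal(temperature_profile(default_sol, 0, 10), -54)
  # both branches meet at the front at the onset temperature
  eps <- 1e-12
  expect_equal(temperature_profile(default_sol, s - eps, 10), -23, tolerance = 1e-6)
  expect_equal(temperature_profile(default_sol, s + eps, 10), -23, tolerance = 1e-6)
  expect_equal(temperature_profile(default_sol, 0.5, 10), 37, tolerance = 1e-6)
  expect_equal(temperature_profile(default_sol, c(0.001, 0.01), 0), c(37, 37))
  expect_error(temperature_profile(default_sol, -0.001, 10), "non-negative")
})

test_that("interface gradients scale as 1/sqrt(t) and satisfy the Stefan balance", {
  tset <- 10^seq(-1, 2, length.out = 13)
  g <- interface_gradients(default_sol, tset)
  g4 <- interface_gradients(default_sol, 4 * tset)
  expect_equal(g4$grad_frozen_K_per_m, g$grad_frozen_K_per_m / 2)
  expect_equal(g4$grad_unfrozen_K_per_m, g$grad_unfrozen_K_per_m / 2)
  lhs <- default_props$k_frozen * g$grad_frozen_K_per_m -
    default_props$k_unfrozen * g$grad_unfrozen_K_per_m
  rhs <- default_props$rho * default_props$L * front_velocity(default_sol, tset)
  expect_lt(max(abs(lhs / rhs - 1)), 1e-9)
  # gradient falls off monotonically as the front advances
  expect_true(all(diff(g$grad_frozen_K_per_m) < 0))
  expect_true(all(diff(g$grad_unfrozen_K_per_m) < 0))
  expect_error(interface_gradients(default_sol, 0), "strictly positive")
})

test_that("surface heat flux is proportional to the front growth rate", {
  tset <- c(0.1, 1, 7, 30, 100)
  q <- surface_heat_flux(default_sol, tset)
  expect_equal(surface_heat_flux(default_sol, 4 * tset), q / 2)
  ratio <- q / front_velocity(default_sol, tset)
  expect_lt(max(abs(ratio / ratio[1] - 1)), 1e-9)
  expect_error(surface_heat_flux(default_sol, -2), "strictly positive")
})

test_that("no-physical-root is reported when the bracket cannot close", {
  # enormous latent heat with a barely-subcooled probe keeps lambda tiny but
  # solvable; a genuinely impossible case needs a residual that cannot change
  # sign, which the physics forbids - so check the error path via the bracket
  # by direct construction
  expect_error(solve_front_constant(liver_tissue_properties(),
                                    list(T_surface = -23, T_onset = -23, T_body = 37)),
               "degenerate-no-frozen-phase")
})
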