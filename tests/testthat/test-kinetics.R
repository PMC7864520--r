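test_that("no nucleation and no seed stays at zero; full seed starts at one", {
  p0 <- kinetic_params(nucleation_rate = 0, elongation_rate = 5,
                       seed_fraction = 0)
  expect_equal(simulate_kinetics(p0, c(0, 1, 10, 100))$mass_fraction,
               rep(0, 4))
  p1 <- kinetic_params(nucleation_rate = 1e-4, elongation_rate = 5,
                       seed_fraction = 1)
  expect_equal(simulate_kinetics(p1, c(0, 1, 5))$mass_fraction, rep(1, 3))
})

test_that("integrator matches closed form and a 10x-finer RK4 oracle", {
  p <- kinetic_params(total_monomer = 1, nucleation_rate = 1e-4,
                      elongation_rate = 5, seed_fraction = 0.05)
  times <- c(0.25, 0.5, 1, 2, 3, 5)
  got <- simulate_kinetics(p, times)$mass_fraction
  # fixed-step oracle at step 0.01 vs the package at (effectively) adaptive;
  # the reference is the 10x finer version of a dt = 0.1 integration
  coarse <- rk4_kinetics(1, 1e-4, 5, 0.05, times, dt = 0.1)
  fine <- rk4_kinetics(1, 1e-4, 5, 0.05, times, dt = 0.01)
  expect_lt(max(abs(got - fine)), 1e-5)
  expect_lt(max(abs(coarse - fine)), 1e-4)  # oracle self-consistency
  cf <- saaquant:::kinetics_closed_form(p, times)
  expect_lt(max(abs(got - cf)), 1e-7)
})

test_that("trajectories are monotone, bounded, and conserve mass", {
  for (seed_frac in c(0, 0.02, 0.5)) {
    p <- kinetic_params(nucleation_rate = 1e-4, elongation_rate = 5,
                        seed_fraction = seed_frac)
    f <- simulate_kinetics(p, seq(0, 10, 0.5))$mass_fraction
    expect_true(all(diff(f) >= -1e-12))
    expect_true(all(f >= 0 & f <= 1))
    # monomer is total - fibril by construction; conservation means the
    # fibril mass never exceeds total within integrator tolerance
    expect_true(all(f <= 1 + 1e-6))
  }
})

test_that("half-time strictly decreases with seeding", {
  seeds <- c(0, 0.01, 0.05, 0.1, 0.2)
  t50 <- vapply(seeds, function(s) {
    half_time(kinetic_params(nucleation_rate = 1e-4, elongation_rate = 5,
                             seed_fraction = s), t_max = 60)
  }, numeric(1))
  expect_true(all(diff(t50) < 0))
})

test_that("invalid kinetic parameters are rejected", {
  expect_error(kinetic_params(nucleation_rate = -1), class = "saaquant_parameter_error")
  expect_error(kinetic_params(elongation_rate = NaN), class = "saaquant_parameter_error")
  expect_error(kinetic_params(seed_fraction = 1.5), class = "saaquant_parameter_error")
  p <- kinetic_params()
  expect_error(simulate_kinetics(p, c(2, 1)), class = "saaquant_parameter_error")
  expect_error(simulate_kinetics(p, c(-1, 1)), class = "saaquant_parameter_error")
})
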