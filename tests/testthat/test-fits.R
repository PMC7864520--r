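test_that("Boltzmann fit recovers its own noise-free curve to 1e-6", {
  tt <- seq(0, 168, 12)
  y <- 0.5 + (4 - 0.5) / (1 + exp(-0.1 * (tt - 72)))
  f <- fit_sigmoid(data.frame(time_h = tt, sd_mean = y))
  rel <- abs(c(f$baseline - 0.5, f$plateau - 4, f$t50 - 72, f$slope - 0.1) /
               c(0.5, 4, 72, 0.1))
  expect_lt(max(rel), 1e-6)
  expect_equal(f$lag_time, 72 - 2 / 0.1, tolerance = 1e-5)
  expect_false(f$extrapolated)
})

test_that("a flat series yields plateau == baseline and an extrapolated t50", {
  tt <- seq(0, 168, 24)
  f <- fit_sigmoid(data.frame(time_h = tt, sd_mean = rep(2, length(tt))))
  expect_equal(f$plateau, f$baseline)
  expect_true(f$extrapolated)
})

test_that("fitted t50 decreases with seeding on simulated time courses", {
  tt <- seq(0, 168, 12)
  t50s <- vapply(c(0.01, 0.05, 0.2), function(s) {
    mf <- simulate_kinetics(kinetic_params(nucleation_rate = 1e-10,
                                           elongation_rate = 0.08,
                                           seed_fraction = s), tt)$mass_fraction
    fit_sigmoid(data.frame(time_h = tt, sd_mean = 5 + 6 * mf))$t50
  }, numeric(1))
  expect_true(all(diff(t50s) < 0))
})

test_that("4PL fit recovers its own curve, incl. the zero-dose anchor", {
  x <- rep(c(0, 0.1, 0.2, 0.3, 0.5, 0.8, 1), each = 3)
  y <- 0.5 + (4 - 0.5) * ifelse(x > 0, 1 / (1 + (0.3 / x)^2), 0)
  h <- fit_half_max(data.frame(aef_fraction = x, sd_value = y))
  rel <- abs(c(h$bottom - 0.5, h$top - 4, h$half_max_fraction - 0.3,
               h$hill - 2) / c(0.5, 4, 0.3, 2))
  expect_lt(max(rel), 1e-6)
})

test_that("the operational half-max matches the parameter on saturating curves", {
  x <- rep(c(0, 0.02, 0.05, 0.1, 0.2, 0.5, 1), each = 2)
  y <- 1 + (6 - 1) * ifelse(x > 0, 1 / (1 + (0.05 / x)^2), 0)
  f <- fit_half_max(data.frame(aef_fraction = x, sd_value = y))
  # top is reached within range, so crossing and parameter agree closely
  expect_equal(half_max_dose(f), f$half_max_fraction, tolerance = 5e-3)
  # the crossing really is the half-way response
  xs <- half_max_dose(f)
  ends <- predict(f, data.frame(aef_fraction = c(0, 1)))
  expect_equal(predict(f, data.frame(aef_fraction = xs)), mean(ends),
               tolerance = 1e-8)
})

test_that("constant dose response is flagged unidentifiable", {
  x <- c(0.1, 0.2, 0.4, 0.8)
  h <- fit_half_max(data.frame(aef_fraction = x, sd_value = rep(3, 4)))
  expect_true(h$unidentifiable)
  expect_true(is.na(h$half_max_fraction))
})

test_that("fits demand enough distinct doses / time points", {
  expect_error(fit_sigmoid(data.frame(time_h = 1:4, sd_mean = 1:4)),
               class = "saaquant_input_error")
  expect_error(fit_half_max(data.frame(aef_fraction = c(0.1, 0.2, 0.3),
                                       sd_value = 1:3)),
               class = "saaquant_input_error")
})

test_that("tidy and glance methods return the broom-style shapes", {
  tt <- seq(0, 168, 24)
  y <- 1 + 3 / (1 + exp(-0.08 * (tt - 60)))
  f <- fit_sigmoid(data.frame(time_h = tt, sd_mean = y))
  td <- tidy(f)
  expect_named(td, c("term", "estimate"))
  expect_equal(nrow(glance(f)), 1L)
  x <- rep(c(0, 0.15, 0.3, 0.6, 1), each = 2)
  h <- fit_half_max(data.frame(aef_fraction = x,
                               sd_value = 1 + 2 * ifelse(x > 0, 1 / (1 + 0.3 / x), 0)))
  expect_true(all(c("half_max_fraction", "hill") %in% tidy(h)$term))
  expect_equal(nrow(glance(h)), 1L)
})
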