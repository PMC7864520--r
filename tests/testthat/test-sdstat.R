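test_that("SD statistic handles the canonical closed-form cases", {
  expect_equal(sd_statistic(matrix(7, 10, 10)), 0)
  chk <- matrix(c(2, 8), 8, 8)  # equal counts of 2 and 8
  expect_equal(sd_statistic(chk), 3)  # (b - a) / 2
  arr <- array(c(matrix(1, 4, 4), matrix(3, 4, 4)), dim = c(4, 4, 2))
  expect_equal(sd_statistic(arr), 0)  # channel mean collapses to constant 2
})

test_that("SD statistic equals the brute-force definition on random grids", {
  set.seed(42)
  for (k in 1:100) {
    nr <- sample(1:8, 1); nc <- sample(1:8, 1)
    m <- matrix(sample(0:255, nr * nc, replace = TRUE), nrow = nr)
    expect_lt(abs(sd_statistic(m) - brute_sd(m)) / max(brute_sd(m), 1e-9),
              1e-12)
  }
})

test_that("SD statistic is shift invariant and scale equivariant", {
  set.seed(1)
  m <- matrix(runif(400, 0, 100), 20, 20)
  expect_equal(sd_statistic(m + 17.3), sd_statistic(m))
  expect_equal(sd_statistic(3.5 * m), 3.5 * sd_statistic(m))
})

test_that("invalid grids are rejected", {
  expect_error(sd_statistic(matrix(numeric(0), 0, 0)), class = "saaquant_input_error")
  expect_error(sd_statistic(matrix(c(1, NA), 1)), class = "saaquant_input_error")
})

test_that("time-course summary computes mean and SEM per time point", {
  df <- data.frame(time_h = rep(c(0, 24), each = 3), replicate_id = rep(1:3, 2),
                   sd_value = c(1, 2, 3, 4, 5, 6))
  tc <- summarize_timecourse(df)
  expect_equal(tc$sd_mean, c(2, 5))
  expect_equal(tc$sd_sem, rep(1 / sqrt(3), 2))
  expect_equal(tc$n_replicates, c(3L, 3L))
  one <- summarize_timecourse(data.frame(time_h = c(0, 24), replicate_id = 1,
                                         sd_value = c(1, 2)))
  expect_true(all(is.na(one$sd_sem)))  # SEM undefined for n = 1
})

test_that("activity ranking orders by mean endpoint SD and flags ties", {
  df <- data.frame(
    species = rep(c("cat", "mouse", "goat", "cattle", "camel"), each = 2),
    sd_value = rep(c(5, 4.5, 2, 1.9, 1.8), each = 2))
  rk <- rank_activity(df)
  expect_equal(rk$species, c("cat", "mouse", "goat", "cattle", "camel"))
  expect_false(any(rk$tied))
  tied <- rank_activity(data.frame(species = c("a", "b"), sd_value = c(1, 1)))
  expect_equal(tied$species, c("a", "b"))  # lexicographic tie-break
  expect_true(all(tied$tied))
})
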