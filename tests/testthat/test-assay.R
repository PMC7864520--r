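test_that("the frame count is the full panel product", {
  a <- generate_assay(render = FALSE, rng_seed = 1)
  expect_equal(nrow(a), 5 * 5 * 8 * 3)
  small <- generate_assay(panel = default_panel()[1:2, ], times = c(0, 84, 168),
                          n_replicates = 2, render = FALSE, rng_seed = 1)
  expect_equal(nrow(small), 2 * 3 * 2)
})

test_that("an unseeded series shows no SD increase", {
  ctrl <- generate_assay(panel = data.frame(species = "mouse", aef_fraction = 0),
                         imaging = imaging_params(height = 96, width = 96),
                         rng_seed = 5)
  tc <- summarize_timecourse(quantify_images(ctrl))
  expect_lt(max(tc$sd_mean) - min(tc$sd_mean), 0.5)
})

test_that("a faster-elongating species reaches plateau earlier", {
  sp <- species_defaults()
  t50 <- vapply(c("cat", "goat"), function(s) {
    row <- sp[sp$species == s, ]
    half_time(kinetic_params(nucleation_rate = row$nucleation_rate,
                             elongation_rate = row$elongation_rate,
                             seed_fraction = row$seed_ceiling))
  }, numeric(1))
  expect_lt(t50[["cat"]], t50[["goat"]])
  a <- generate_assay(panel = data.frame(species = c("cat", "goat"),
                                         aef_fraction = 1),
                      times = c(0, 84, 168), render = FALSE, rng_seed = 2)
  mid <- dplyr::filter(a, time_h == 84)
  expect_gt(mean(mid$mass_fraction_true[mid$species == "cat"]),
            mean(mid$mass_fraction_true[mid$species == "goat"]))
})

test_that("assay generation is deterministic and validates the panel", {
  a1 <- generate_assay(panel = default_panel()[1, ], times = c(0, 168),
                       n_replicates = 1, rng_seed = 3,
                       imaging = imaging_params(height = 64, width = 64))
  a2 <- generate_assay(panel = default_panel()[1, ], times = c(0, 168),
                       n_replicates = 1, rng_seed = 3,
                       imaging = imaging_params(height = 64, width = 64))
  expect_identical(a1$image[[2]]$pixels, a2$image[[2]]$pixels)
  expect_error(generate_assay(panel = data.frame()), class = "saaquant_parameter_error")
  expect_error(generate_assay(panel = data.frame(species = "yeti",
                                                 aef_fraction = 0.5)),
               class = "saaquant_parameter_error")
})

test_that("expected endpoint SD is non-decreasing in seed fraction", {
  fracs <- c(0.2, 0.5, 1.0)
  means <- vapply(seq_along(fracs), function(i) {
    a <- generate_assay(panel = data.frame(species = "goat",
                                           aef_fraction = fracs[i]),
                        times = c(0, 168), n_replicates = 20, rng_seed = 60 + i,
                        imaging = imaging_params(height = 96, width = 96))
    ep <- dplyr::filter(quantify_images(a), time_h == 168)
    mean(ep$sd_value)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})
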