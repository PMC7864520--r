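test_that("a mass-free frame is pure background with SD near background_sd", {
  img <- render_micrograph(0, tiny_imaging(rng_seed = 11))
  expect_s3_class(img, "micrograph")
  expect_true(abs(sd_statistic(img) - 5) < 1.5)
  expect_true(all(img$pixels >= 0 & img$pixels <= 255))
})

test_that("rendering is deterministic in the seed and varies across seeds", {
  a1 <- render_micrograph(0.4, tiny_imaging(rng_seed = 7))
  a2 <- render_micrograph(0.4, tiny_imaging(rng_seed = 7))
  b <- render_micrograph(0.4, tiny_imaging(rng_seed = 8))
  expect_identical(a1$pixels, a2$pixels)
  expect_false(identical(a1$pixels, b$pixels))
})

test_that("mean SD grows strictly along a mass-fraction grid", {
  for (morph in c("dotted", "mesh")) {
    mean_sd <- vapply(seq(0.1, 0.9, 0.2), function(mf) {
      mean(vapply(1:20, function(s) {
        sd_statistic(render_micrograph(mf, imaging_params(morphology = morph,
                                                          rng_seed = 100 + s)))
      }, numeric(1)))
    }, numeric(1))
    expect_true(all(diff(mean_sd) > 0))
  }
})

test_that("rendered intensities respect the bit range at both depths", {
  img8 <- render_micrograph(1, tiny_imaging(rng_seed = 2, bit_depth = 8))
  expect_true(max(img8$pixels) <= 255)
  img16 <- render_micrograph(
    1, imaging_params(height = 64, width = 64, bit_depth = 16,
                      background_mean = 30 * 257, background_sd = 5 * 257,
                      rng_seed = 2))
  expect_true(max(img16$pixels) <= 65535 && max(img16$pixels) > 255)
})

test_that("degenerate imaging parameters are rejected", {
  expect_error(imaging_params(height = 0), class = "saaquant_parameter_error")
  expect_error(imaging_params(bit_depth = 12), class = "saaquant_parameter_error")
  expect_error(render_micrograph(1.2, tiny_imaging()), class = "saaquant_parameter_error")
})

test_that("z-stacks: empty at mass 0, thicker at higher mass, reproducible", {
  zp <- function(s) imaging_params(height = 64, width = 64, z_slices = 16,
                                   z_step = 2, rng_seed = s)
  expect_equal(thickness_profile(render_zstack(0, zp(3)))$mean_thickness_um, 0)
  th <- vapply(1:6, function(s) {
    c(thickness_profile(render_zstack(0.2, zp(s)))$mean_thickness_um,
      thickness_profile(render_zstack(0.8, zp(s)))$mean_thickness_um)
  }, numeric(2))
  expect_lt(mean(th[1, ]), mean(th[2, ]))
  z1 <- render_zstack(0.5, zp(9)); z2 <- render_zstack(0.5, zp(9))
  expect_identical(z1$slices, z2$slices)
  expect_error(render_zstack(0.5, tiny_imaging(z_slices = 1)),
               class = "saaquant_parameter_error")
})
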