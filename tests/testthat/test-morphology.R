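test_that("component labelling uses 8-connectivity", {
  m <- matrix(0, 5, 5)
  m[1, 1] <- 1; m[2, 2] <- 1  # touch only diagonally
  lab <- label_components(m)
  expect_equal(max(lab), 1L)
  m[5, 5] <- 1
  expect_equal(max(label_components(m)), 2L)
})

test_that("skeletonization thins a thick bar to a unit-width curve", {
  m <- matrix(0, 30, 30)
  m[14:17, 3:28] <- 1  # 4-pixel-thick horizontal bar
  sk <- skeletonize(m)
  expect_true(sum(sk) < sum(m) / 2)
  expect_true(sum(sk) >= 20)           # length preserved
  expect_true(all(colSums(sk[, 5:26]) <= 2))  # essentially one pixel wide
})

test_that("a single blob is dotted; a drawn line grid is mesh", {
  m <- matrix(0, 64, 64)
  d2 <- outer((1:64 - 32)^2, (1:64 - 32)^2, "+")
  m <- 200 * exp(-d2 / 50)
  blob <- classify_morphology(m)
  expect_equal(blob$label, "dotted")
  expect_equal(blob$n_components, 1L)

  g <- matrix(0, 64, 64)
  g[seq(8, 64, 8), ] <- 200; g[, seq(8, 64, 8)] <- 200
  grid <- classify_morphology(g)
  expect_equal(grid$label, "mesh")
  expect_gt(grid$largest_component_fraction, 0.99)
})

test_that("a structure-free frame is labelled none with zeroed descriptors", {
  set.seed(5)
  noise <- matrix(rnorm(64 * 64, 30, 5), 64, 64)
  r <- classify_morphology(noise)
  expect_equal(r$label, "none")
  expect_equal(r$n_components, 0L)
  expect_equal(r$largest_component_fraction, 0)
})

test_that("rendered morphologies are classified by their generator label", {
  labs_d <- vapply(1:25, function(s) {
    classify_morphology(render_micrograph(0.5, imaging_params(rng_seed = 600 + s)))$label
  }, character(1))
  labs_m <- vapply(1:25, function(s) {
    classify_morphology(render_micrograph(0.5, imaging_params(
      morphology = "mesh", rng_seed = 700 + s)))$label
  }, character(1))
  expect_gte(mean(labs_d == "dotted"), 0.95)
  expect_gte(mean(labs_m == "mesh"), 0.95)
})

test_that("thickness profile: constructed block and symmetry", {
  bg <- matrix(0, 32, 32)
  hot <- bg; hot[10:20, 10:20] <- 200
  slices <- c(rep(list(bg), 5), rep(list(hot), 10), rep(list(bg), 5))
  tp <- thickness_profile(slices, z_step = 2)
  expect_equal(tp$mean_thickness_um, 20)  # 10 slices x 2 um over the block
  rev_tp <- thickness_profile(rev(slices), z_step = 2)
  expect_equal(rev_tp$thickness_map, tp$thickness_map)
  expect_error(thickness_profile(list(bg), z_step = 1), class = "saaquant_input_error")
})
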