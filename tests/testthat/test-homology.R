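test_that("percent identity covers the hand-built cases", {
  rows <- list(a = "ACDEFGHK", b = "ACDEFGHK")
  expect_equal(percent_identity(rows, "a", "b"), 100)
  # 8 columns: 6 matches, 1 mismatch, 1 gap column -> 600/7
  rows <- list(a = "ACDEFGH-", b = "ACDEFGYK")
  expect_equal(percent_identity(rows, "a", "b"), 600 / 7)
  # disjoint non-gap columns: undefined
  rows <- list(a = "AC--", b = "--DE")
  expect_true(is.na(percent_identity(rows, "a", "b")))
})

test_that("overall homology is the minimum pairwise identity", {
  sq <- setNames(rep("MKVLDAAYKG", 3), c("a", "b", "c"))
  aln <- progressive_msa(sq)
  expect_equal(overall_homology(aln)$min_identity, 100)
  expect_equal(overall_homology(aln)$conserved_column_fraction, 1)

  set.seed(5)
  fam <- simulate_sequence_family(sequence_sim_params(
    ancestor_length = 60, planted_sites = list(), rng_seed = 5))
  aln <- progressive_msa(fam$sequences)
  pid <- pairwise_identity(aln)
  expect_equal(nrow(pid), choose(6, 2))
  # brute-force min over all pairs
  ids <- names(aln$rows)
  brute <- min(apply(utils::combn(ids, 2), 2, function(p) {
    percent_identity(aln, p[1], p[2])
  }))
  expect_equal(overall_homology(aln)$min_identity, brute)
})

test_that("adding a row never increases the homology minimum", {
  set.seed(9)
  fam <- simulate_sequence_family(sequence_sim_params(
    ancestor_length = 60, planted_sites = list(), rng_seed = 9))
  aln_all <- progressive_msa(fam$sequences)
  aln_sub <- progressive_msa(fam$sequences[1:4, ])
  expect_lte(overall_homology(aln_all)$min_identity,
             overall_homology(aln_sub)$min_identity + 1e-9)
})

test_that("conservation classes follow the band boundaries", {
  rows <- list(a = "AAAD", b = "AAAD", c = "AABD", d = "AABA", e = "ABBA")
  cc <- conservation_classes(saaquant:::msa_new(unlist(rows)))
  # col1: 5/5 full; col2: 4/5 high; col3: 3/5 mid; col4: modal D 3/5 mid
  expect_equal(cc$class, c("full", "high", "mid", "mid"))
  # exact 75% boundary falls in the lower class
  rows <- list(a = "A", b = "A", c = "A", d = "B")
  cc <- conservation_classes(saaquant:::msa_new(unlist(rows)))
  expect_equal(cc$class, "mid")
  # 50% boundary falls to low
  rows <- list(a = "A", b = "A", c = "B", d = "B")
  cc <- conservation_classes(saaquant:::msa_new(unlist(rows)))
  expect_equal(cc$class, "low")
})
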