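test_that("the residue property table is the fixed five-class map", {
  expect_equal(residue_property(c("D", "E")), c("acidic", "acidic"))
  expect_equal(residue_property(c("K", "R", "H")), rep("basic", 3))
  expect_equal(residue_property("A"), "hydrophobic")
  expect_equal(residue_property(c("G", "P")), rep("special", 2))
  expect_equal(residue_property("Q", scheme = "charge"), "neutral")
  expect_error(residue_property("B"), class = "saaquant_input_error")
})

test_that("a constructed charge contrast is found exactly once", {
  rows <- c(m1 = "AAAAEAA", m2 = "AAAAEAA",
            l1 = "AAAAKAA", l2 = "AAAAKAA", l3 = "AAAAKAA")
  aln <- saaquant:::msa_new(rows)
  hits <- discriminative_site_scan(aln, c("m1", "m2"), c("l1", "l2", "l3"))
  expect_equal(hits$column, 5L)
  expect_equal(hits$group_a_class, "acidic")
  expect_equal(hits$group_b_class, "basic")
  # identical rows: nothing discriminates
  same <- saaquant:::msa_new(setNames(rep("AAKAA", 4), c("a", "b", "c", "d")))
  expect_equal(nrow(discriminative_site_scan(same, c("a", "b"), c("c", "d"))), 0L)
})

test_that("mixed-property neutral group vs uniform basic group discriminates", {
  # the Gln/Ile-versus-Lys pattern: fine-grained classes differ inside the
  # first group, but the charge partition is uniform (neutral vs basic)
  rows <- c(mouse = "AAQA", cat = "AAIA",
            camel = "AAKA", cattle = "AAKA", goat = "AAKA")
  aln <- saaquant:::msa_new(rows)
  hits <- discriminative_site_scan(aln, c("mouse", "cat"),
                                   c("camel", "cattle", "goat"))
  expect_equal(hits$column, 3L)
  expect_equal(hits$group_a_class, "neutral")
  # under the five-class partition that column is not group-uniform
  hits5 <- discriminative_site_scan(aln, c("mouse", "cat"),
                                    c("camel", "cattle", "goat"),
                                    scheme = "property")
  expect_equal(nrow(hits5), 0L)
})

test_that("gaps exclude a column and the scan is order/label symmetric", {
  rows <- c(a1 = "AE-A", a2 = "AEAA", b1 = "AKAA", b2 = "AKAA")
  aln <- saaquant:::msa_new(rows)
  hits <- discriminative_site_scan(aln, c("a1", "a2"), c("b1", "b2"))
  expect_equal(hits$column, 2L)  # column 3 excluded by the gap
  # row reordering
  aln2 <- saaquant:::msa_new(rows[c(3, 1, 4, 2)])
  hits2 <- discriminative_site_scan(aln2, c("a1", "a2"), c("b1", "b2"))
  expect_equal(hits2, hits)
  # group swap mirrors the classes
  sw <- discriminative_site_scan(aln, c("b1", "b2"), c("a1", "a2"))
  expect_equal(sw$column, hits$column)
  expect_equal(sw$group_a_class, hits$group_b_class)
  expect_equal(sw$group_b_class, hits$group_a_class)
})

test_that("invalid groups are rejected", {
  aln <- saaquant:::msa_new(c(a = "AA", b = "AA"))
  expect_error(discriminative_site_scan(aln, character(0), "b"),
               class = "saaquant_input_error")
  expect_error(discriminative_site_scan(aln, "a", "a"),
               class = "saaquant_input_error")
  expect_error(discriminative_site_scan(aln, "a", "zz"),
               class = "saaquant_input_error")
})
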