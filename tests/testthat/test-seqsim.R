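test_that("zero branch lengths with no planted sites give identical sequences", {
  tree <- "((mouse:0,cat:0):0,(cattle:0,goat:0):0);"
  fam <- simulate_sequence_family(sequence_sim_params(
    ancestor_length = 40, tree = tree, planted_sites = list(), rng_seed = 3))
  expect_length(unique(fam$sequences$residues), 1L)
  expect_true(all(strsplit(fam$sequences$residues[1], "")[[1]] %in%
                    saaquant:::AA20))
})

test_that("the mouse-cat pair has the highest expected identity", {
  direct_identity <- function(a, b) {
    mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
  }
  acc <- NULL
  wins <- 0
  for (k in 1:50) {
    fam <- simulate_sequence_family(sequence_sim_params(
      ancestor_length = 60, planted_sites = list(), rng_seed = 2000 + k))
    sq <- setNames(fam$sequences$residues, fam$sequences$id)
    pairs <- utils::combn(names(sq), 2)
    ids <- apply(pairs, 2, function(p) direct_identity(sq[[p[1]]], sq[[p[2]]]))
    acc <- if (is.null(acc)) ids else acc + ids
    best <- pairs[, which.max(ids)]
    wins <- wins + setequal(best, c("mouse", "cat"))
  }
  key <- apply(utils::combn(names(setNames(
    fam$sequences$residues, fam$sequences$id)), 2), 2, paste, collapse = "-")
  # averaged over replicates the mouse-cat pair ranks strictly first, and it
  # wins most individual families outright
  expect_equal(key[which.max(acc)], "mouse-cat")
  expect_gte(wins / 50, 0.6)
})

test_that("identity decreases with path length on the tree", {
  tree <- ape::read.tree(text = default_family_tree())
  paths <- ape::cophenetic.phylo(tree)
  acc <- matrix(0, nrow(paths), ncol(paths), dimnames = dimnames(paths))
  for (k in 1:50) {
    fam <- simulate_sequence_family(sequence_sim_params(
      ancestor_length = 60, planted_sites = list(), rng_seed = 4000 + k))
    sq <- setNames(fam$sequences$residues, fam$sequences$id)
    for (i in rownames(acc)) for (j in colnames(acc)) {
      acc[i, j] <- acc[i, j] +
        mean(strsplit(sq[[i]], "")[[1]] == strsplit(sq[[j]], "")[[1]])
    }
  }
  acc <- acc / 50
  labs <- rownames(paths)
  ut <- upper.tri(paths)
  # expected identity must decrease monotonically in tree distance
  ord <- order(paths[ut])
  ids_sorted <- acc[ut][ord]
  expect_lt(cor(paths[ut], acc[ut]), -0.9)
  expect_gt(ids_sorted[1], ids_sorted[length(ids_sorted)])
})

test_that("planted sites carry the requested pattern exactly and verbatim", {
  fam <- simulate_sequence_family(sequence_sim_params(rng_seed = 5))
  sq <- setNames(fam$sequences$residues, fam$sequences$id)
  expect_equal(substr(sq[["mouse"]], 48, 48), "Q")
  expect_equal(substr(sq[["cat"]], 48, 48), "I")
  for (s in c("camel", "cattle", "goat")) {
    expect_equal(substr(sq[[s]], 48, 48), "K")
    expect_equal(substr(sq[[s]], 125, 125), "A")
  }
  expect_equal(substr(sq[["mouse"]], 125, 125), "E")
  # class-valued plants draw a residue of that class
  fam2 <- simulate_sequence_family(sequence_sim_params(
    ancestor_length = 20, tree = "((a:0.01,b:0.01):0.01,c:0.02);",
    planted_sites = list(list(column = 5L,
                              assign = c(a = "basic", b = "basic", c = "acidic"))),
    rng_seed = 11))
  sq2 <- setNames(fam2$sequences$residues, fam2$sequences$id)
  expect_true(substr(sq2[["a"]], 5, 5) %in% c("K", "R", "H"))
  expect_true(substr(sq2[["c"]], 5, 5) %in% c("D", "E"))
})

test_that("family simulation is seed-deterministic and validates input", {
  f1 <- simulate_sequence_family(sequence_sim_params(rng_seed = 8))
  f2 <- simulate_sequence_family(sequence_sim_params(rng_seed = 8))
  expect_identical(f1$sequences, f2$sequences)
  expect_error(sequence_sim_params(ancestor_length = 100),
               class = "saaquant_parameter_error")  # default plant at 125
  expect_error(sequence_sim_params(
    planted_sites = list(list(column = 5L, assign = c(mouse = "Z1")))),
    class = "saaquant_parameter_error")
})
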