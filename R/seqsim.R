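#' Default species tree for the synthetic SAA family
#'
#' A six-leaf rooted ultrametric-ish topology in which mouse and cat are the
#' closest pair (with human just outside their clade) and camel, cattle and
#' goat form the other side. Branch lengths are in expected substitutions
#' per site and are sized so that the most distant pairs sit near 78-80%
#' identity — the "highly conserved family" regime.
#'
#' @return A Newick string.
#' @export
default_family_tree <- function() {
  paste0("(((mouse:0.03,cat:0.03):0.06,human:0.09):0.03,",
         "(camel:0.10,(cattle:0.05,goat:0.05):0.05):0.02);")
}

#' Default planted discriminative sites
#'
#' Two alignment columns carrying the charge contrast between the
#' high-activity (mouse, cat) and low-activity (camel, cattle, goat)
#' groups: column 48 is neutral (Gln in mouse, Ile in cat) versus basic
#' (Lys), and column 125 is acidic (Glu; Asp in human) versus Ala.
#'
#' @return A list of planted-site specifications
#'   (`list(column =, assign = named character)`), the format accepted by
#'   [sequence_sim_params()]. Assignment values may be residue letters or
#'   five-class property names (a residue of that class is then drawn per
#'   leaf).
#' @export
default_planted_sites <- function() {
  list(
    list(column = 48L,
         assign = c(mouse = "Q", cat = "I", human = "N",
                    camel = "K", cattle = "K", goat = "K")),
    list(column = 125L,
         assign = c(mouse = "E", cat = "E", human = "D",
                    camel = "A", cattle = "A", goat = "A"))
  )
}

#' Parameters of the sequence-family simulator
#'
#' @param ancestor_length Length of the ancestral protein in residues
#'   (default 130, the size class of mature SAA with signal peptide).
#' @param tree Newick string or `phylo` object with non-negative branch
#'   lengths (substitutions/site).
#' @param planted_sites List of planted sites as in
#'   [default_planted_sites()]; planted columns are excluded from random
#'   substitution so their pattern is exact. Use `list()` for none.
#' @param rng_seed Integer seed.
#' @return An object of class `sequence_sim_params`.
#' @export
sequence_sim_params <- function(ancestor_length = 130L,
                                tree = default_family_tree(),
                                planted_sites = default_planted_sites(),
                                rng_seed = 1L) {
  phy <- if (inherits(tree, "phylo")) tree else ape::read.tree(text = tree)
  if (is.null(phy) || is.null(phy$edge.length)) {
    stop_param("`tree` must parse to a phylo object with branch lengths")
  }
  if (any(phy$edge.length < 0)) stop_param("branch lengths must be >= 0")
  check_number(ancestor_length, "ancestor_length", lower = 1)
  valid_values <- c(names(PROPERTY_TABLE), unique(unname(PROPERTY_TABLE)))
  for (ps in planted_sites) {
    if (is.null(ps$column) || is.null(ps$assign)) {
      stop_param("each planted site needs `column` and `assign`")
    }
    if (ps$column < 1 || ps$column > ancestor_length) {
      stop_param("planted column %d outside 1..%d", ps$column, ancestor_length)
    }
    bad <- setdiff(ps$assign, valid_values)
    if (length(bad) > 0) {
      stop_param("planted value(s) not realizable by any residue: %s",
                 paste(bad, collapse = ", "))
    }
    if (!all(names(ps$assign) %in% phy$tip.label)) {
      stop_param("planted assignment names must be tree leaves")
    }
  }
  structure(
    list(ancestor_length = as.integer(ancestor_length), tree = phy,
         planted_sites = planted_sites, rng_seed = as.integer(rng_seed)),
    class = "sequence_sim_params"
  )
}

# amino-acid Jukes-Cantor: probability that a site differs after branch
# length b (20 states, uniform exchange)
aa_subst_prob <- function(b) (19 / 20) * (1 - exp(-b * 20 / 19))

#' Simulate an SAA-like protein family along a tree
#'
#' Draws a random ancestral sequence and evolves it along the supplied tree
#' under an i.i.d. uniform-exchange (Jukes-Cantor type) amino-acid
#' substitution process, no indels. Planted columns are frozen during
#' evolution and then set per leaf from the planted assignment, so the
#' ground-truth discriminative pattern is exact. Identical seeds give
#' identical families.
#'
#' @param params A [sequence_sim_params()] object.
#' @return A list with `sequences` (tibble: `id`, `species`, `residues`),
#'   `tree` (the true `phylo`), and `planted` (tibble: `column`, `leaf`,
#'   `residue`, `class`).
#' @examples
#' fam <- simulate_sequence_family(sequence_sim_params(rng_seed = 42))
#' fam$sequences
#' @export
simulate_sequence_family <- function(params) {
  if (!inherits(params, "sequence_sim_params")) {
    stop_param("`params` must be a sequence_sim_params object")
  }
  phy <- ape::reorder.phylo(params$tree, "cladewise")
  L <- params$ancestor_length
  planted_cols <- vapply(params$planted_sites, function(p) as.integer(p$column),
                         integer(1))
  free <- setdiff(seq_len(L), planted_cols)
  n_tip <- length(phy$tip.label)
  root <- n_tip + 1L

  with_seed(params$rng_seed, {
    seqs_at <- vector("list", n_tip + phy$Nnode)
    seqs_at[[root]] <- sample(AA20, L, replace = TRUE)
    for (e in seq_len(nrow(phy$edge))) {
      parent <- phy$edge[e, 1]; child <- phy$edge[e, 2]
      s <- seqs_at[[parent]]
      p <- aa_subst_prob(phy$edge.length[e])
      if (p > 0 && length(free) > 0) {
        hit <- free[runif(length(free)) < p]
        for (pos in hit) {
          s[pos] <- sample(setdiff(AA20, s[pos]), 1L)
        }
      }
      seqs_at[[child]] <- s
    }
    planted_rows <- list()
    for (ps in params$planted_sites) {
      for (leaf in names(ps$assign)) {
        val <- ps$assign[[leaf]]
        res <- if (val %in% AA20) {
          val
        } else {
          sample(names(PROPERTY_TABLE)[PROPERTY_TABLE == val], 1L)
        }
        tip_idx <- match(leaf, phy$tip.label)
        seqs_at[[tip_idx]][ps$column] <- res
        planted_rows[[length(planted_rows) + 1L]] <- tibble::tibble(
          column = as.integer(ps$column), leaf = leaf, residue = res,
          class = unname(PROPERTY_TABLE[res])
        )
      }
    }
    list(
      sequences = tibble::tibble(
        id = phy$tip.label,
        species = phy$tip.label,
        residues = vapply(seq_len(n_tip),
                          function(i) paste(seqs_at[[i]], collapse = ""),
                          character(1))
      ),
      tree = params$tree,
      planted = dplyr::bind_rows(planted_rows)
    )
  })
}
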