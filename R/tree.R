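# UPGMA agglomeration over a labelled distance matrix. Deterministic: among
# tied minimum-distance pairs the pair whose smallest leaf labels sort first
# is merged. Returns the merge sequence (cluster keys as used by
# progressive_msa) and the per-merge ultrametric heights (half the merge
# distance).
upgma_agglomerate <- function(dm) {
  labels <- rownames(dm)
  if (is.null(labels) || !identical(labels, colnames(dm))) {
    stop_input("distance matrix must have matching row/column labels")
  }
  if (nrow(dm) < 2L) stop_input("need at least two labels")
  if (any(dm < 0) || any(abs(diag(dm)) > 1e-12) || any(abs(dm - t(dm)) > 1e-9)) {
    stop_input("distance matrix must be symmetric, non-negative, zero-diagonal")
  }
  keys <- labels
  members <- setNames(as.list(labels), labels)
  reps <- setNames(labels, labels)   # smallest leaf label per cluster
  sizes <- setNames(rep(1, length(labels)), labels)
  D <- dm
  merges <- list()
  while (length(keys) > 1L) {
    best <- NULL
    for (ii in seq_len(length(keys) - 1L)) {
      for (jj in (ii + 1L):length(keys)) {
        ki <- keys[ii]; kj <- keys[jj]
        d <- D[ki, kj]
        pr <- sort(c(reps[ki], reps[kj]))
        cand <- list(ki = ki, kj = kj, d = d, pr = pr)
        if (is.null(best) || d < best$d - 1e-12 ||
            (abs(d - best$d) <= 1e-12 &&
             (pr[1] < best$pr[1] ||
              (pr[1] == best$pr[1] && pr[2] < best$pr[2])))) {
          best <- cand
        }
      }
    }
    a <- best$ki; b <- best$kj
    if (reps[b] < reps[a]) { tmp <- a; a <- b; b <- tmp }
    new_key <- paste(a, b, sep = "|")
    merges[[length(merges) + 1L]] <- list(
      a_key = a, b_key = b, key = new_key, height = best$d / 2,
      members = c(members[[a]], members[[b]])
    )
    na <- sizes[a]; nb <- sizes[b]
    others <- setdiff(keys, c(a, b))
    newd <- setNames(numeric(length(others)), others)
    for (k in others) newd[k] <- (na * D[a, k] + nb * D[b, k]) / (na + nb)
    keys <- c(others, new_key)
    D2 <- matrix(0, length(keys), length(keys), dimnames = list(keys, keys))
    if (length(others) > 0) {
      D2[others, others] <- D[others, others]
      D2[new_key, others] <- newd
      D2[others, new_key] <- newd
    }
    D <- D2
    members[[new_key]] <- c(members[[a]], members[[b]])
    reps[new_key] <- min(reps[a], reps[b])
    sizes[new_key] <- na + nb
  }
  list(merges = merges)
}

#' Build a UPGMA tree from a distance matrix
#'
#' Agglomerates with average linkage (UPGMA) and returns a rooted,
#' ultrametric [ape] `phylo` tree whose node heights are half the merge
#' distances. Ties in the minimum distance are broken deterministically by
#' the lexicographically lowest leaf-label pair.
#'
#' @param dm Symmetric numeric matrix with zero diagonal and matching
#'   row/column labels (or a `dist` object with labels).
#' @return A rooted `phylo` object.
#' @examples
#' d <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' build_tree(d)
#' @export
build_tree <- function(dm) {
  if (inherits(dm, "dist")) dm <- as.matrix(dm)
  agg <- upgma_agglomerate(dm)
  heights <- setNames(rep(0, nrow(dm)), rownames(dm))
  newick <- setNames(rownames(dm), rownames(dm))
  for (mg in agg$merges) {
    la <- mg$height - heights[mg$a_key]
    lb <- mg$height - heights[mg$b_key]
    newick[mg$key] <- sprintf("(%s:%.10g,%s:%.10g)",
                              newick[mg$a_key], la, newick[mg$b_key], lb)
    heights[mg$key] <- mg$height
  }
  txt <- paste0(newick[[length(newick)]], ";")
  ape::read.tree(text = txt)
}

#' Test whether a label set forms a clade
#'
#' TRUE iff `labels` are exactly the leaves of one monophyletic group of the
#' rooted tree.
#'
#' @param tree A rooted `phylo` object (e.g. from [build_tree()]).
#' @param labels Character vector of tip labels.
#' @return Logical scalar.
#' @export
clade_check <- function(tree, labels) {
  if (!inherits(tree, "phylo")) stop_input("`tree` must be a phylo object")
  labels <- unique(labels)
  if (!all(labels %in% tree$tip.label)) {
    stop_input("labels absent from the tree: %s",
               paste(setdiff(labels, tree$tip.label), collapse = ", "))
  }
  if (length(labels) == length(tree$tip.label)) return(TRUE)
  ape::is.monophyletic(tree, labels)
}
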