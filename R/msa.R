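msa_new <- function(rows) {
  lens <- unique(nchar(rows))
  if (length(lens) != 1L) stop_input("alignment rows must share one length")
  structure(list(rows = rows), class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<alignment: %d rows x %d columns>\n",
              length(x$rows), nchar(x$rows[[1]])))
  for (id in names(x$rows)) {
    cat(sprintf("  %-12s %s\n", id, substr(x$rows[[id]], 1, 60)))
  }
  invisible(x)
}

#' @export
as.matrix.msa <- function(x, ...) {
  do.call(rbind, lapply(x$rows, function(s) strsplit(s, "", fixed = TRUE)[[1]]))
}

coerce_seqs <- function(seqs) {
  if (is.data.frame(seqs)) {
    idcol <- intersect(c("id", "species"), names(seqs))[1]
    if (is.na(idcol) || !"residues" %in% names(seqs)) {
      stop_input("sequence table needs an id/species column and `residues`")
    }
    setNames(as.character(seqs$residues), as.character(seqs[[idcol]]))
  } else if (is.character(seqs) && !is.null(names(seqs))) {
    seqs
  } else {
    stop_input("`seqs` must be a named character vector or a sequence table")
  }
}

# column composition counts over the alphabet + gap, rows = symbols
profile_counts <- function(mat, symbols) {
  apply(mat, 2, function(col) tabulate(match(col, symbols), length(symbols)))
}

# Align two profiles (character matrices) with the same affine-gap scheme as
# global_align; column-column score is the average pairwise residue score,
# residue-vs-gap scored gap_extend, gap-vs-gap 0.
align_profiles <- function(A, B, sub, gap_open, gap_extend) {
  symbols <- c(rownames(sub), "-")
  S <- matrix(0, length(symbols), length(symbols),
              dimnames = list(symbols, symbols))
  S[rownames(sub), colnames(sub)] <- sub
  S["-", ] <- gap_extend; S[, "-"] <- gap_extend; S["-", "-"] <- 0
  CA <- profile_counts(A, symbols); CB <- profile_counts(B, symbols)
  SC <- crossprod(CA, S %*% CB) / (nrow(A) * nrow(B))
  n <- ncol(A); m <- ncol(B)
  NEG <- -Inf
  M <- matrix(NEG, n + 1, m + 1); X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  pM <- matrix(0L, n + 1, m + 1); pX <- matrix(0L, n + 1, m + 1)
  pY <- matrix(0L, n + 1, m + 1)
  gap_cost <- function(L) if (L == 0) 0 else gap_open + (L - 1) * gap_extend
  M[1, 1] <- 0
  if (n > 0) { X[2:(n + 1), 1] <- sapply(1:n, gap_cost); pX[, 1] <- 2L; pX[2, 1] <- 1L }
  if (m > 0) { Y[1, 2:(m + 1)] <- sapply(1:m, gap_cost); pY[1, ] <- 3L; pY[1, 2] <- 1L }
  for (i in seq_len(n) + 1L) {
    for (j in seq_len(m) + 1L) {
      cand <- c(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      k <- which.max(cand)
      M[i, j] <- SC[i - 1, j - 1] + cand[k]; pM[i, j] <- k
      cand <- c(M[i - 1, j] + gap_open, X[i - 1, j] + gap_extend,
                Y[i - 1, j] + gap_open)
      k <- which.max(cand)
      X[i, j] <- cand[k]; pX[i, j] <- k
      cand <- c(M[i, j - 1] + gap_open, X[i, j - 1] + gap_open,
                Y[i, j - 1] + gap_extend)
      k <- which.max(cand)
      Y[i, j] <- cand[k]; pY[i, j] <- k
    }
  }
  finals <- c(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
  state <- which.max(finals)
  pathA <- integer(0); pathB <- integer(0)  # 0 marks an inserted gap column
  i <- n + 1; j <- m + 1
  while (i > 1 || j > 1) {
    if (state == 1L) {
      pathA <- c(i - 1, pathA); pathB <- c(j - 1, pathB)
      state <- pM[i, j]; i <- i - 1; j <- j - 1
    } else if (state == 2L) {
      pathA <- c(i - 1, pathA); pathB <- c(0L, pathB)
      state <- pX[i, j]; i <- i - 1
    } else {
      pathA <- c(0L, pathA); pathB <- c(j - 1, pathB)
      state <- pY[i, j]; j <- j - 1
    }
  }
  take <- function(P, path) {
    out <- matrix("-", nrow(P), length(path))
    out[, path > 0] <- P[, path[path > 0], drop = FALSE]
    out
  }
  rbind(take(A, pathA), take(B, pathB))
}

#' Progressive multiple sequence alignment
#'
#' Classic progressive MSA: all pairwise global alignments give a
#' percent-identity distance matrix, a UPGMA guide tree orders the merges,
#' and profiles are merged bottom-up with profile-profile affine-gap
#' alignment. Gap-only columns are never introduced, and de-gapping any row
#' reproduces the input sequence exactly.
#'
#' @param seqs Named character vector of sequences, or a data frame with an
#'   `id` (or `species`) column and a `residues` column.
#' @param substitution,gap_open,gap_extend Scoring scheme, as in
#'   [global_align()].
#' @return An object of class `msa` (named gapped rows, input order).
#' @export
progressive_msa <- function(seqs, substitution = "BLOSUM62",
                            gap_open = -10, gap_extend = -1) {
  sq <- coerce_seqs(seqs)
  if (length(sq) == 0L) stop_input("no sequences supplied")
  if (anyDuplicated(names(sq))) stop_input("sequence ids must be unique")
  sub <- resolve_substitution(substitution)
  for (s in sq) check_residues(strsplit(s, "")[[1]], rownames(sub))
  ids <- names(sq)
  if (length(sq) == 1L) return(msa_new(sq))
  if (length(sq) == 2L) {
    al <- global_align(sq[[1]], sq[[2]], substitution = substitution,
                       gap_open = gap_open, gap_extend = gap_extend)
    return(msa_new(setNames(c(al$a_aligned, al$b_aligned), ids)))
  }
  n <- length(sq)
  dm <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      al <- global_align(sq[[i]], sq[[j]], substitution = substitution,
                         gap_open = gap_open, gap_extend = gap_extend)
      pid <- pair_identity_strings(al$a_aligned, al$b_aligned)
      dm[i, j] <- dm[j, i] <- 1 - (if (is.na(pid)) 0 else pid) / 100
    }
  }
  merges <- upgma_agglomerate(dm)$merges
  profiles <- lapply(sq, function(s) matrix(strsplit(s, "")[[1]], nrow = 1,
                                            dimnames = list(NULL, NULL)))
  names(profiles) <- ids
  prof_ids <- lapply(ids, identity)
  names(prof_ids) <- ids
  for (mg in merges) {
    a <- mg$a_key; b <- mg$b_key
    merged <- align_profiles(profiles[[a]], profiles[[b]], sub,
                             gap_open, gap_extend)
    key <- paste(a, b, sep = "|")
    profiles[[key]] <- merged
    prof_ids[[key]] <- c(prof_ids[[a]], prof_ids[[b]])
    profiles[[a]] <- profiles[[b]] <- NULL
    prof_ids[[a]] <- prof_ids[[b]] <- NULL
  }
  final <- profiles[[length(profiles)]]
  rows_ids <- prof_ids[[length(prof_ids)]]
  rows <- setNames(apply(final, 1, paste, collapse = ""), rows_ids)
  msa_new(rows[ids])
}
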