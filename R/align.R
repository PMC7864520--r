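AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Resolve a substitution table specification to a full score matrix over the
# amino-acid alphabet plus X (unknown, scored 0 against everything).
resolve_substitution <- function(substitution) {
  if (is.matrix(substitution)) {
    tab <- substitution
  } else if (identical(substitution, "BLOSUM62")) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    tab <- e$BLOSUM62
  } else if (identical(substitution, "identity")) {
    tab <- matrix(-1, 20, 20, dimnames = list(AA20, AA20))
    diag(tab) <- 1
  } else {
    stop_param("unknown substitution table specification")
  }
  # restrict to the 20 standard residues; X is tolerated and scores 0
  letters_all <- c(intersect(rownames(tab), AA20), "X")
  full <- matrix(0, length(letters_all), length(letters_all),
                 dimnames = list(letters_all, letters_all))
  keep <- setdiff(letters_all, "X")
  full[keep, keep] <- tab[keep, keep]
  full["X", ] <- 0
  full[, "X"] <- 0
  full
}

check_residues <- function(x, allowed) {
  bad <- setdiff(unique(x), allowed)
  if (length(bad) > 0) {
    stop_input("unknown residue letter(s): %s", paste(bad, collapse = ", "))
  }
}

#' Global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch global alignment under an affine gap model, computed
#' with the Gotoh three-state recurrences. A gap run of length L costs
#' `gap_open + (L - 1) * gap_extend` (penalties are negative scores; the
#' first gap position pays the opening cost). Terminal gaps are charged like
#' internal ones. Traceback tie-breaking is deterministic: diagonal is
#' preferred, then up (gap in `b`), then left (gap in `a`).
#'
#' @param a,b Character strings of amino-acid residues (the letter `X` is
#'   allowed and scores 0 against everything).
#' @param substitution `"BLOSUM62"` (default), `"identity"` (+1/-1), or a
#'   numeric score matrix with residue dimnames.
#' @param gap_open,gap_extend Gap scores (non-positive; defaults -10 / -1).
#' @return A list of class `pairwise_alignment`: `a_aligned`, `b_aligned`
#'   (gapped strings), `score`.
#' @examples
#' global_align("ACDE", "ACDE", substitution = "identity",
#'              gap_open = -2, gap_extend = -2)
#' @export
global_align <- function(a, b, substitution = "BLOSUM62",
                         gap_open = -10, gap_extend = -1) {
  if (!is.character(a) || !is.character(b) || length(a) != 1 || length(b) != 1) {
    stop_input("`a` and `b` must be single strings")
  }
  if (!is.finite(gap_open) || !is.finite(gap_extend) ||
      gap_open > 0 || gap_extend > 0) {
    stop_param("gap penalties must be finite and non-positive")
  }
  sub <- resolve_substitution(substitution)
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  check_residues(av, rownames(sub))
  check_residues(bv, rownames(sub))
  n <- length(av); m <- length(bv)
  gap_cost <- function(L) if (L == 0) 0 else gap_open + (L - 1) * gap_extend
  if (n == 0L || m == 0L) {
    return(structure(list(
      a_aligned = paste(c(av, rep("-", m)), collapse = ""),
      b_aligned = paste(c(rep("-", n), bv), collapse = ""),
      score = gap_cost(n + m)
    ), class = "pairwise_alignment"))
  }
  NEG <- -Inf
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # gap in b (consumes a; "up")
  Y <- matrix(NEG, n + 1, m + 1)  # gap in a ("left")
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- gap_cost(i - 1)
  for (j in 2:(m + 1)) Y[1, j] <- gap_cost(j - 1)
  # traceback pointers: which predecessor state (1=M, 2=X, 3=Y) was used
  pM <- matrix(0L, n + 1, m + 1)
  pX <- matrix(0L, n + 1, m + 1)
  pY <- matrix(0L, n + 1, m + 1)
  pX[, 1] <- 2L; pX[2, 1] <- 1L
  pY[1, ] <- 3L; pY[1, 2] <- 1L
  srow <- sub[av, , drop = FALSE]
  for (i in 2:(n + 1)) {
    si <- srow[i - 1, bv]
    for (j in 2:(m + 1)) {
      cand <- c(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      k <- which.max(cand)  # ties: M, then X, then Y
      M[i, j] <- si[j - 1] + cand[k]
      pM[i, j] <- k
      cand <- c(M[i - 1, j] + gap_open, X[i - 1, j] + gap_extend,
                Y[i - 1, j] + gap_open)
      k <- which.max(cand)
      X[i, j] <- cand[k]
      pX[i, j] <- k
      cand <- c(M[i, j - 1] + gap_open, X[i, j - 1] + gap_open,
                Y[i, j - 1] + gap_extend)
      k <- which.max(cand)
      Y[i, j] <- cand[k]
      pY[i, j] <- k
    }
  }
  finals <- c(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
  state <- which.max(finals)
  score <- finals[state]
  ra <- character(0); rb <- character(0)
  i <- n + 1; j <- m + 1
  while (i > 1 || j > 1) {
    if (state == 1L) {
      ra <- c(av[i - 1], ra); rb <- c(bv[j - 1], rb)
      state <- pM[i, j]; i <- i - 1; j <- j - 1
    } else if (state == 2L) {
      ra <- c(av[i - 1], ra); rb <- c("-", rb)
      state <- pX[i, j]; i <- i - 1
    } else {
      ra <- c("-", ra); rb <- c(bv[j - 1], rb)
      state <- pY[i, j]; j <- j - 1
    }
  }
  structure(list(a_aligned = paste(ra, collapse = ""),
                 b_aligned = paste(rb, collapse = ""),
                 score = score),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("Global alignment, score", format(x$score), "\n")
  cat(" ", x$a_aligned, "\n ", x$b_aligned, "\n")
  invisible(x)
}
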