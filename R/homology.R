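# identity between two gapped rows: matches over columns where neither row
# has a gap (pairwise-deletion convention); NA when no such column exists
pair_identity_strings <- function(a, b) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  if (length(av) != length(bv)) stop_input("rows differ in length")
  keep <- av != "-" & bv != "-"
  if (!any(keep)) return(NA_real_)
  100 * sum(av[keep] == bv[keep]) / sum(keep)
}

#' Percent identity between two alignment rows
#'
#' 100 x matches / number of columns where neither row carries a gap.
#' Symmetric; `NA` (degenerate, no shared residue columns) when the rows
#' never overlap.
#'
#' @param aln An `msa` object (or any named list of equal-length gapped
#'   strings under `$rows`).
#' @param i,j Row names or indices.
#' @return A number in \[0, 100\], or `NA` for non-overlapping rows.
#' @export
percent_identity <- function(aln, i, j) {
  rows <- if (inherits(aln, "msa")) aln$rows else aln
  pair_identity_strings(rows[[i]], rows[[j]])
}

#' All pairwise percent identities of an alignment
#'
#' @param aln An `msa` object.
#' @return A tibble with columns `id_a`, `id_b`, `identity`.
#' @export
pairwise_identity <- function(aln) {
  rows <- if (inherits(aln, "msa")) aln$rows else aln
  ids <- names(rows)
  if (length(ids) < 2L) stop_input("need at least two rows")
  pairs <- utils::combn(ids, 2)
  tibble::tibble(
    id_a = pairs[1, ], id_b = pairs[2, ],
    identity = purrr::map2_dbl(pairs[1, ], pairs[2, ],
                               ~ pair_identity_strings(rows[[.x]], rows[[.y]]))
  )
}

#' Overall homology of an alignment
#'
#' Headline summary in the "at least X%" sense: the *minimum* pairwise
#' percent identity over all row pairs, plus the fraction of fully conserved
#' (gap-free, single-residue) columns as a secondary measure.
#'
#' @param aln An `msa` object.
#' @return A one-row tibble: `min_identity`, `mean_identity`,
#'   `conserved_column_fraction`, `n_sequences`.
#' @export
overall_homology <- function(aln) {
  pid <- pairwise_identity(aln)
  mat <- as.matrix(aln)
  conserved <- mean(apply(mat, 2, function(col) {
    all(col != "-") && length(unique(col)) == 1L
  }))
  tibble::tibble(
    min_identity = min(pid$identity, na.rm = TRUE),
    mean_identity = mean(pid$identity, na.rm = TRUE),
    conserved_column_fraction = conserved,
    n_sequences = length(aln$rows)
  )
}

#' Per-column conservation classes
#'
#' Column similarity is the fraction of rows sharing the column's modal
#' residue (gaps never match). Classes follow the conventional colouring
#' bands: `full` = 100%, `high` = (75%, 100%), `mid` = (50%, 75%],
#' `low` = at most 50%. Values falling exactly on a band edge are assigned
#' to the lower class.
#'
#' @param aln An `msa` object.
#' @return A tibble with `column`, `similarity` (0-1), `class`.
#' @export
conservation_classes <- function(aln) {
  mat <- as.matrix(aln)
  n <- nrow(mat)
  sim <- apply(mat, 2, function(col) {
    res <- col[col != "-"]
    if (length(res) == 0L) return(0)
    max(table(res)) / n
  })
  cls <- dplyr::case_when(
    sim == 1 ~ "full",
    sim > 0.75 ~ "high",
    sim > 0.5 ~ "mid",
    TRUE ~ "low"
  )
  tibble::tibble(column = seq_along(sim), similarity = as.numeric(sim),
                 class = cls)
}
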