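PROPERTY_TABLE <- c(
  D = "acidic", E = "acidic",
  K = "basic", R = "basic", H = "basic",
  S = "polar", T = "polar", N = "polar", Q = "polar", C = "polar", Y = "polar",
  A = "hydrophobic", V = "hydrophobic", L = "hydrophobic", I = "hydrophobic",
  M = "hydrophobic", F = "hydrophobic", W = "hydrophobic",
  G = "special", P = "special"
)

#' Physicochemical class of an amino acid
#'
#' Fixed five-class side-chain table: D,E acidic; K,R,H basic; S,T,N,Q,C,Y
#' polar; A,V,L,I,M,F,W hydrophobic; G,P special. The coarser `scheme =
#' "charge"` collapses the three uncharged classes to `"neutral"`, which is
#' the partition relevant to charge-mediated protein-protein contacts.
#'
#' @param aa Character vector of one-letter residue codes.
#' @param scheme `"property"` (five classes) or `"charge"` (acidic / basic /
#'   neutral).
#' @return Character vector of classes.
#' @examples
#' residue_property(c("K", "E", "A"))
#' residue_property("Q", scheme = "charge")
#' @export
residue_property <- function(aa, scheme = c("property", "charge")) {
  scheme <- match.arg(scheme)
  aa <- toupper(aa)
  bad <- setdiff(unique(aa), names(PROPERTY_TABLE))
  if (length(bad) > 0) {
    stop_input("not standard amino-acid letters: %s", paste(bad, collapse = ", "))
  }
  cls <- unname(PROPERTY_TABLE[aa])
  if (scheme == "charge") {
    cls[!cls %in% c("acidic", "basic")] <- "neutral"
  }
  cls
}

#' Scan an alignment for group-discriminative sites
#'
#' Finds alignment columns whose physicochemical class cleanly separates two
#' predefined groups of rows (e.g. high- versus low-seeding-activity
#' species): within each group the class (under `scheme`) must be uniform,
#' and the two groups' classes must differ. Columns where any group member
#' carries a gap are excluded. Under the default `"charge"` scheme a column
#' such as Gln/Ile (neutral) versus Lys (basic) is discriminative even
#' though the neutral residues span different fine-grained property
#' classes. With `strictness = "residue"` each group must additionally be
#' uniform in residue identity.
#'
#' @param aln An `msa` object.
#' @param group_a,group_b Disjoint, non-empty character vectors of row
#'   names. Rows in neither group are ignored.
#' @param scheme Class partition for the test: `"charge"` (default) or
#'   `"property"` (see [residue_property()]).
#' @param strictness `"class"` (default) or `"residue"`.
#' @return A tibble with one row per discriminative column: `column`
#'   (1-based alignment position), `group_a_residues`, `group_b_residues`
#'   (comma-joined multisets), `group_a_class`, `group_b_class`,
#'   `discriminating` (all `TRUE`).
#' @export
discriminative_site_scan <- function(aln, group_a, group_b,
                                     scheme = c("charge", "property"),
                                     strictness = c("class", "residue")) {
  scheme <- match.arg(scheme)
  strictness <- match.arg(strictness)
  rows <- if (inherits(aln, "msa")) aln$rows else aln
  if (length(group_a) == 0L || length(group_b) == 0L) {
    stop_input("both groups must be non-empty")
  }
  if (length(intersect(group_a, group_b)) > 0L) {
    stop_input("groups must be disjoint")
  }
  missing <- setdiff(c(group_a, group_b), names(rows))
  if (length(missing) > 0L) {
    stop_input("group labels absent from alignment: %s",
               paste(missing, collapse = ", "))
  }
  mat <- do.call(rbind, lapply(rows, function(s) strsplit(s, "")[[1]]))
  A <- mat[group_a, , drop = FALSE]
  B <- mat[group_b, , drop = FALSE]
  reports <- purrr::map(seq_len(ncol(mat)), function(col) {
    ra <- A[, col]; rb <- B[, col]
    if (any(ra == "-") || any(rb == "-")) return(NULL)
    ca <- unique(residue_property(ra, scheme = scheme))
    cb <- unique(residue_property(rb, scheme = scheme))
    uniform <- length(ca) == 1L && length(cb) == 1L
    if (strictness == "residue") {
      uniform <- uniform && length(unique(ra)) == 1L && length(unique(rb)) == 1L
    }
    if (!uniform || ca[1] == cb[1]) return(NULL)
    tibble::tibble(
      column = col,
      group_a_residues = paste(ra, collapse = ","),
      group_b_residues = paste(rb, collapse = ","),
      group_a_class = ca[1], group_b_class = cb[1],
      discriminating = TRUE
    )
  })
  out <- dplyr::bind_rows(reports)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(column = integer(0), group_a_residues = character(0),
                          group_b_residues = character(0),
                          group_a_class = character(0),
                          group_b_class = character(0),
                          discriminating = logical(0))
  }
  out
}
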