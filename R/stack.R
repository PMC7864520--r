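#' Aggregate thickness from a confocal z-stack
#'
#' For every xy position, counts the slices whose intensity exceeds a global
#' automatic threshold and converts the count to micrometres via the axial
#' step. The threshold is Otsu's, computed on the pooled stack histogram,
#' with a structure check on the split (foreground-background separation
#' must exceed what Gaussian noise alone produces) so that a stack
#' containing nothing but camera noise — which
#' Otsu would happily split down the middle — yields an empty footprint and
#' zero thickness. The summary thickness is the mean over the above-threshold
#' footprint; slice order does not matter.
#'
#' @param zs A `zstack` from [render_zstack()], or a list of equally sized
#'   numeric matrices.
#' @param z_step Axial step in micrometres (taken from the object when
#'   available).
#' @return A list with `mean_thickness_um` (0 when no voxel is above
#'   threshold), `thickness_map` (matrix, micrometres), `threshold_used`,
#'   and `footprint_fraction`.
#' @export
thickness_profile <- function(zs, z_step = NULL) {
  slices <- if (inherits(zs, "zstack")) zs$slices else zs
  z_step <- z_step %||% (if (inherits(zs, "zstack")) zs$z_step else 1)
  if (!is.list(slices) || length(slices) < 2L) {
    stop_input("a z-stack needs at least 2 slices")
  }
  dims <- unique(lapply(slices, dim))
  if (length(dims) != 1L) stop_input("all slices must share one shape")
  pooled <- unlist(slices, use.names = FALSE)
  if (any(!is.finite(pooled))) stop_input("stack contains non-finite values")
  det <- detect_threshold(pooled)
  thr <- det$threshold
  counts <- if (det$structured) {
    Reduce(`+`, lapply(slices, function(s) s > thr))
  } else {
    matrix(0L, nrow(slices[[1]]), ncol(slices[[1]]))
  }
  tmap <- counts * z_step
  fg <- counts > 0
  list(
    mean_thickness_um = if (any(fg)) mean(tmap[fg]) else 0,
    thickness_map = tmap,
    threshold_used = thr,
    footprint_fraction = mean(fg)
  )
}
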