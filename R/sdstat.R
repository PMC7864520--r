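#' Per-pixel brightness SD statistic
#'
#' The aggregate readout of the pipeline: the standard deviation of the
#' brightness of every pixel in a fluorescence micrograph. A frame with no
#' aggregates has SD close to the camera background SD; bound fluorophore
#' clustered into aggregates spreads the brightness distribution and raises
#' the SD, which tracks aggregate amount. The *population* SD (denominator
#' N) is used, computed on the raw grid with no background subtraction;
#' colour arrays are first collapsed to grayscale by channel mean.
#'
#' @param img A [micrograph()], a numeric matrix, or a 3D array
#'   (height x width x channels).
#' @return A single non-negative number in intensity units.
#' @examples
#' sd_statistic(matrix(c(1, 3, 1, 3), 2))  # two-point distribution: 1
#' @export
sd_statistic <- function(img) {
  x <- if (inherits(img, "micrograph")) img$pixels else img
  if (is.array(x) && length(dim(x)) == 3L) {
    x <- apply(x, c(1, 2), mean)
  }
  if (!is.numeric(x) || length(x) == 0L) {
    stop_input("`img` must be a non-empty numeric grid")
  }
  if (any(!is.finite(x))) stop_input("`img` contains non-finite values")
  mu <- mean(x)
  sqrt(mean((x - mu)^2))
}

#' Attach the SD statistic to a table of micrographs
#'
#' Convenience verb for assay tables: computes [sd_statistic()] for every
#' image in a list-column and returns the table with an `sd_value` column,
#' ready for [summarize_timecourse()] / [rank_activity()].
#'
#' @param df A data frame with a list-column of [micrograph()] objects (or
#'   plain matrices).
#' @param image_col Name of the list-column (default `"image"`).
#' @return The input as a tibble with an added numeric `sd_value` column.
#' @export
quantify_images <- function(df, image_col = "image") {
  if (!is.data.frame(df) || !image_col %in% names(df)) {
    stop_input("`df` must contain an image list-column `%s`", image_col)
  }
  dplyr::mutate(tibble::as_tibble(df),
                sd_value = purrr::map_dbl(.data[[image_col]], sd_statistic))
}

#' Replicate time-course summary of the SD statistic
#'
#' Collapses per-replicate SD values to `mean +/- SEM` at each time point,
#' the standard presentation of aggregation time courses. SEM is the sample
#' SD over replicates (denominator n - 1) divided by sqrt(n); with a single
#' replicate it is `NA` (undefined).
#'
#' @param df A data frame with columns `time_h`, `replicate_id`, `sd_value`,
#'   plus any condition columns named in `...`.
#' @param ... Optional grouping columns (e.g. `species`, `aef_fraction`);
#'   when omitted, any of `species` / `aef_fraction` present are used.
#' @return A tibble with columns `time_h`, `sd_mean`, `sd_sem`,
#'   `n_replicates` (plus the grouping columns), times strictly increasing
#'   within each group.
#' @export
summarize_timecourse <- function(df, ...) {
  if (!is.data.frame(df) || !all(c("time_h", "sd_value") %in% names(df))) {
    stop_input("`df` must contain time_h and sd_value columns")
  }
  groups <- rlang::enquos(...)
  if (length(groups) == 0L) {
    auto <- intersect(c("species", "aef_fraction"), names(df))
    groups <- rlang::syms(auto)
  }
  out <- df |>
    dplyr::group_by(!!!groups, .data$time_h) |>
    dplyr::summarise(
      sd_mean = mean(.data$sd_value),
      sd_sem = ifelse(dplyr::n() > 1,
                      sd(.data$sd_value) / sqrt(dplyr::n()), NA_real_),
      n_replicates = dplyr::n(),
      .groups = "drop_last"
    ) |>
    dplyr::arrange(.data$time_h, .by_group = TRUE) |>
    dplyr::ungroup()
  out
}

#' Endpoint dose-response table
#'
#' Extracts the endpoint (latest time by default) per-replicate SD values
#' versus AEF fraction, the input of [fit_half_max()].
#'
#' @param df A data frame with `aef_fraction`, `time_h`, `replicate_id`,
#'   `sd_value` (and optionally `species`).
#' @param endpoint_time Time to slice at; default the maximum present.
#' @return A tibble with `aef_fraction`, `replicate_id`, `sd_value` (plus
#'   `species` when present).
#' @export
dose_response <- function(df, endpoint_time = NULL) {
  if (!is.data.frame(df) ||
      !all(c("aef_fraction", "time_h", "sd_value") %in% names(df))) {
    stop_input("`df` must contain aef_fraction, time_h and sd_value")
  }
  endpoint_time <- endpoint_time %||% max(df$time_h)
  keep <- intersect(c("species", "aef_fraction", "replicate_id", "sd_value"),
                    names(df))
  df |>
    dplyr::filter(.data$time_h == endpoint_time) |>
    dplyr::select(dplyr::all_of(keep)) |>
    tibble::as_tibble()
}

#' Rank species by seeding activity
#'
#' Orders species by mean endpoint SD (descending). Exact ties are broken
#' lexicographically by species name and flagged.
#'
#' @param df A data frame with columns `species` and `sd_value` (one row per
#'   replicate) at a fixed AEF fraction and time.
#' @return A tibble with `species`, `mean_sd`, `n`, `rank`, `tied`.
#' @export
rank_activity <- function(df) {
  if (!is.data.frame(df) || !all(c("species", "sd_value") %in% names(df))) {
    stop_input("`df` must contain species and sd_value columns")
  }
  out <- df |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(mean_sd = mean(.data$sd_value), n = dplyr::n(),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$mean_sd), .data$species) |>
    dplyr::mutate(
      rank = dplyr::row_number(),
      tied = duplicated(.data$mean_sd) | duplicated(.data$mean_sd, fromLast = TRUE)
    )
  out
}
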