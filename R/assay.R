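#' Default per-species kinetic and imaging settings
#'
#' One row per AEF donor species with the kinetic rate constants and the
#' aggregate morphology used by [generate_assay()]. The defaults encode the
#' qualitative biology the pipeline is built around: cat and mouse seeds are
#' strong promoters of mouse SAA aggregation (cat slightly ahead of mouse in
#' endpoint signal), while camel, cattle and goat seeds are weak and mutually
#' similar; mouse-seeded aggregates form a connected mesh whereas the other
#' species give dotted deposits. Species differences are carried entirely by
#' these parameters; edit the returned tibble to define other scenarios.
#'
#' @return A tibble with columns `species`, `total_monomer`,
#'   `nucleation_rate`, `elongation_rate`, `seed_ceiling`, `noise_sd`,
#'   `morphology`.
#' @export
species_defaults <- function() {
  tibble::tibble(
    species         = c("cat", "mouse", "camel", "cattle", "goat"),
    total_monomer   = 1,
    nucleation_rate = 1e-12,
    elongation_rate = c(0.090, 0.080, 0.0195, 0.0190, 0.0185),
    seed_ceiling    = 0.05,
    noise_sd        = 0.05,
    morphology      = c("dotted", "mesh", "dotted", "dotted", "dotted")
  )
}

#' Default assay panel
#'
#' The species-by-dose grid of the standard experiment: five donor species
#' crossed with AEF at 20, 40, 60, 80 and 100 percent of the mouse SAA
#' amount.
#'
#' @return A tibble with columns `species` and `aef_fraction`.
#' @export
default_panel <- function() {
  tidyr::expand_grid(
    species = c("cat", "mouse", "camel", "cattle", "goat"),
    aef_fraction = c(0.2, 0.4, 0.6, 0.8, 1.0)
  )
}

#' Default observation times
#'
#' Hours at which frames are captured: every 24 h from 0 to 168 h.
#' @return Numeric vector of hours.
#' @export
default_times <- function() seq(0, 168, by = 24)

#' Generate a full synthetic seeding assay
#'
#' Simulates seeded nucleation-elongation kinetics for every
#' (species, AEF fraction) combination, perturbs each replicate trajectory
#' with observation noise, and renders one micrograph per
#' (species, fraction, time, replicate). The AEF fraction maps linearly onto
#' the kinetic seed: `seed_fraction = aef_fraction * seed_ceiling`.
#'
#' @param panel Tibble with columns `species`, `aef_fraction`
#'   (default [default_panel()]).
#' @param times Observation times in hours (default [default_times()]).
#' @param species_params Tibble as returned by [species_defaults()].
#' @param n_replicates Replicates per condition (default 3, the usual
#'   "n = 3 separate experiments").
#' @param imaging Base [imaging_params()]; morphology and seed are overridden
#'   per species / frame.
#' @param rng_seed Integer master seed. Identical seeds give an identical
#'   assay.
#' @param render Set `FALSE` to skip rendering and return only the noisy
#'   ground-truth mass fractions (fast path for kinetic-level work).
#' @return A tibble with one row per frame: `species`, `aef_fraction`,
#'   `time_h`, `replicate_id`, `mass_fraction` (noisy ground truth),
#'   `mass_fraction_true` (noise-free), `morphology`, and (when
#'   `render = TRUE`) a list-column `image` of [micrograph()] objects.
#' @examples
#' assay <- generate_assay(panel = default_panel()[1:2, ],
#'                         times = c(0, 84, 168), n_replicates = 2,
#'                         rng_seed = 1)
#' @export
generate_assay <- function(panel = default_panel(), times = default_times(),
                           species_params = species_defaults(),
                           n_replicates = 3, imaging = imaging_params(),
                           rng_seed = 1L, render = TRUE) {
  if (!is.data.frame(panel) || nrow(panel) == 0L ||
      !all(c("species", "aef_fraction") %in% names(panel))) {
    stop_param("`panel` must be a non-empty data frame with species and aef_fraction")
  }
  if (any(panel$aef_fraction < 0 | panel$aef_fraction > 1)) {
    stop_param("aef_fraction must lie in [0, 1]")
  }
  if (!all(panel$species %in% species_params$species)) {
    stop_param("panel species missing from `species_params`")
  }
  check_number(n_replicates, "n_replicates", lower = 1)

  conditions <- dplyr::left_join(panel, species_params, by = "species")
  grid <- tidyr::expand_grid(
    conditions,
    replicate_id = seq_len(n_replicates)
  )

  out <- with_seed(rng_seed, {
    rows <- purrr::pmap(grid, function(species, aef_fraction, total_monomer,
                                       nucleation_rate, elongation_rate,
                                       seed_ceiling, noise_sd, morphology,
                                       replicate_id, ...) {
      kp <- kinetic_params(total_monomer = total_monomer,
                           nucleation_rate = nucleation_rate,
                           elongation_rate = elongation_rate,
                           seed_fraction = aef_fraction * seed_ceiling,
                           noise_sd = noise_sd)
      mf_true <- simulate_kinetics(kp, times)$mass_fraction
      # replicate-level variability is multiplicative (pipetting / seeding
      # variation scales with the amount present); a no-seed series stays
      # exactly at zero
      mf_obs <- pmin(pmax(mf_true * (1 + rnorm(length(times), 0, noise_sd)), 0), 1)
      tibble::tibble(species = species, aef_fraction = aef_fraction,
                     time_h = times, replicate_id = replicate_id,
                     mass_fraction = mf_obs, mass_fraction_true = mf_true,
                     morphology = morphology)
    })
    frames <- dplyr::bind_rows(rows)
    if (render) {
      frames$image <- purrr::pmap(
        list(frames$mass_fraction, frames$morphology, seq_len(nrow(frames)),
             frames$species, frames$aef_fraction, frames$time_h,
             frames$replicate_id),
        function(mf, morph, i, sp, aef, t, rep) {
          ip <- imaging
          ip$morphology <- morph
          ip$rng_seed <- derive_seed(rng_seed, i)
          render_micrograph(mf, ip, species = sp, aef_fraction = aef,
                            time_h = t, replicate_id = rep)
        })
    }
    frames
  })
  out
}
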