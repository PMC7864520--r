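#' Imaging parameters for synthetic micrograph rendering
#'
#' Describes the virtual fluorescence microscope used by [render_micrograph()]
#' and [render_zstack()]: frame geometry, camera background statistics, the
#' aggregate morphology to draw, the point-spread blur, and the bit depth of
#' the stored image. All intensities are in raw camera units on the
#' `[0, 2^bit_depth - 1]` scale.
#'
#' @param height,width Frame size in pixels (>= 8).
#' @param z_slices Number of z slices (1 for a 2D frame).
#' @param z_step Axial step between slices, micrometres.
#' @param background_mean,background_sd Mean and standard deviation of the
#'   additive Gaussian camera background (intensity units).
#' @param morphology `"dotted"` (isolated blurred point clusters, the
#'   aggregate form seen with cat, camel, cattle and goat seeds) or `"mesh"`
#'   (a single connected blurred filament network, the mouse-seed form).
#' @param psf_sigma Gaussian point-spread sigma in pixels.
#' @param bit_depth Either 8 or 16.
#' @param dot_density Expected number of dots at mass fraction 1 (dotted mode).
#' @param mesh_length Total filament path length in pixels at mass fraction 1
#'   (mesh mode).
#' @param amplitude Peak signal amplitude as a fraction of full scale.
#' @param rng_seed Integer seed; identical seeds give bit-identical images.
#' @return An object of class `imaging_params`.
#' @export
imaging_params <- function(height = 128, width = 128, z_slices = 1,
                           z_step = 2, background_mean = 30,
                           background_sd = 5, morphology = c("dotted", "mesh"),
                           psf_sigma = 1.5, bit_depth = 8,
                           dot_density = 70, mesh_length = 6000,
                           amplitude = 0.55, rng_seed = 1L) {
  morphology <- match.arg(morphology)
  if (!is.numeric(height) || !is.numeric(width) || height < 8 || width < 8) {
    stop_param("image must be at least 8 x 8 pixels")
  }
  check_number(z_slices, "z_slices", lower = 1)
  check_number(z_step, "z_step", lower = .Machine$double.eps)
  check_number(background_mean, "background_mean", lower = 0)
  check_number(background_sd, "background_sd", lower = 0)
  check_number(psf_sigma, "psf_sigma", lower = 0)
  if (!bit_depth %in% c(8, 16)) stop_param("bit_depth must be 8 or 16")
  check_number(dot_density, "dot_density", lower = 0)
  check_number(mesh_length, "mesh_length", lower = 0)
  check_number(amplitude, "amplitude", lower = 0, upper = 1)
  structure(
    list(height = as.integer(height), width = as.integer(width),
         z_slices = as.integer(z_slices), z_step = z_step,
         background_mean = background_mean, background_sd = background_sd,
         morphology = morphology, psf_sigma = psf_sigma,
         bit_depth = as.integer(bit_depth), dot_density = dot_density,
         mesh_length = mesh_length, amplitude = amplitude,
         rng_seed = as.integer(rng_seed)),
    class = "imaging_params"
  )
}

#' Construct a micrograph object
#'
#' A micrograph is a 2D matrix of non-negative finite intensities plus assay
#' metadata (species label, AEF fraction, time, replicate).
#'
#' @param pixels Numeric matrix of intensities.
#' @param bit_depth 8 or 16.
#' @param species,aef_fraction,time_h,replicate_id Assay metadata.
#' @return An object of class `micrograph`.
#' @export
micrograph <- function(pixels, bit_depth = 8, species = NA_character_,
                       aef_fraction = NA_real_, time_h = NA_real_,
                       replicate_id = NA_integer_) {
  if (!is.matrix(pixels) || length(pixels) == 0L) {
    stop_input("`pixels` must be a non-empty matrix")
  }
  if (any(!is.finite(pixels))) stop_input("micrograph contains non-finite pixels")
  if (any(pixels < 0) || any(pixels > 2^bit_depth - 1)) {
    stop_input("pixel intensities outside [0, 2^bit_depth - 1]")
  }
  structure(
    list(pixels = pixels, bit_depth = as.integer(bit_depth),
         meta = list(species = species, aef_fraction = aef_fraction,
                     time_h = time_h, replicate_id = replicate_id)),
    class = "micrograph"
  )
}

#' @export
print.micrograph <- function(x, ...) {
  cat(sprintf("<micrograph %d x %d, %d-bit> species=%s aef=%s t=%sh rep=%s\n",
              nrow(x$pixels), ncol(x$pixels), x$bit_depth,
              x$meta$species, format(x$meta$aef_fraction),
              format(x$meta$time_h), format(x$meta$replicate_id)))
  invisible(x)
}

gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  out <- EBImage::gblur(m, sigma = sigma)
  matrix(as.numeric(out), nrow = nrow(m), ncol = ncol(m))
}

# Draw the noise-free structural signal (before PSF blur) for one frame.
# Returns a height x width matrix on the [0, 1] amplitude scale.
draw_structure <- function(mass_fraction, params) {
  h <- params$height; w <- params$width
  sig <- matrix(0, h, w)
  if (mass_fraction <= 0) return(sig)
  if (params$morphology == "dotted") {
    n_dots <- rpois(1, lambda = mass_fraction * params$dot_density)
    if (n_dots > 0) {
      cx <- runif(n_dots, 2, h - 1)
      cy <- runif(n_dots, 2, w - 1)
      rad <- runif(n_dots, 0.8, 2.2)
      amp <- runif(n_dots, 0.7, 1.3)
      for (k in seq_len(n_dots)) {
        ri <- max(1L, floor(cx[k] - rad[k])):min(h, ceiling(cx[k] + rad[k]))
        ci <- max(1L, floor(cy[k] - rad[k])):min(w, ceiling(cy[k] + rad[k]))
        d2 <- outer((ri - cx[k])^2, (ci - cy[k])^2, "+")
        patch <- amp[k] * exp(-d2 / (2 * (rad[k] / 1.6)^2))
        sig[ri, ci] <- sig[ri, ci] + patch
      }
    }
  } else {
    # mesh: persistent random-walk filaments; every filament after the first
    # starts on an already-drawn pixel so the network is one connected piece
    total_len <- round(mass_fraction * params$mesh_length)
    drawn <- NULL
    laid <- 0L
    while (laid < total_len) {
      seg <- min(200L, total_len - laid)
      if (is.null(drawn)) {
        x <- runif(1, h * 0.2, h * 0.8); y <- runif(1, w * 0.2, w * 0.8)
      } else {
        at <- drawn[sample.int(nrow(drawn), 1L), ]
        x <- at[1]; y <- at[2]
      }
      ang <- runif(1, 0, 2 * pi)
      px <- numeric(seg); py <- numeric(seg)
      for (s in seq_len(seg)) {
        ang <- ang + rnorm(1, 0, 0.35)
        x <- x + cos(ang); y <- y + sin(ang)
        # reflect at frame borders
        if (x < 2) { x <- 4 - x; ang <- pi - ang }
        if (x > h - 1) { x <- 2 * (h - 1) - x; ang <- pi - ang }
        if (y < 2) { y <- 4 - y; ang <- -ang }
        if (y > w - 1) { y <- 2 * (w - 1) - y; ang <- -ang }
        px[s] <- x; py[s] <- y
      }
      # stamp a 2-pixel-thick filament so it stays well above the camera
      # noise floor after PSF blurring
      ij <- cbind(round(px), round(py))
      ij2 <- cbind(pmin(ij[, 1] + 1L, h), ij[, 2])
      sig[ij] <- sig[ij] + 0.6
      sig[ij2] <- sig[ij2] + 0.6
      drawn <- rbind(drawn, ij)
      laid <- laid + seg
    }
  }
  pmin(sig, 1.5)
}

#' Render a synthetic fluorescence micrograph
#'
#' Converts a fibril mass fraction into a 2D image: aggregate structure is
#' drawn in the requested morphology, blurred with a Gaussian point-spread
#' function, superimposed on Gaussian camera background, clipped to the bit
#' range and quantised. Total above-background fluorescence grows
#' monotonically (in expectation) with `mass_fraction`, which is what makes
#' the per-pixel brightness SD a usable aggregate readout.
#'
#' @param mass_fraction Fibril mass fraction in \[0, 1\].
#' @param params An [imaging_params()] object.
#' @param species,aef_fraction,time_h,replicate_id Metadata stored on the
#'   returned micrograph.
#' @return A [micrograph()] object.
#' @examples
#' img <- render_micrograph(0.5, imaging_params(rng_seed = 7))
#' sd_statistic(img)
#' @export
render_micrograph <- function(mass_fraction, params = imaging_params(),
                              species = NA_character_, aef_fraction = NA_real_,
                              time_h = NA_real_, replicate_id = NA_integer_) {
  if (!inherits(params, "imaging_params")) {
    stop_param("`params` must be an imaging_params object")
  }
  check_number(mass_fraction, "mass_fraction", lower = 0, upper = 1)
  maxI <- 2^params$bit_depth - 1
  px <- with_seed(params$rng_seed, {
    sig <- draw_structure(mass_fraction, params)
    sig <- gaussian_blur(sig * params$amplitude * maxI, params$psf_sigma)
    noise <- matrix(rnorm(params$height * params$width,
                          mean = params$background_mean,
                          sd = params$background_sd),
                    params$height, params$width)
    round(pmin(pmax(sig + noise, 0), maxI))
  })
  micrograph(px, bit_depth = params$bit_depth, species = species,
             aef_fraction = aef_fraction, time_h = time_h,
             replicate_id = replicate_id)
}

#' Render a synthetic confocal z-stack
#'
#' Renders the same structural signal as [render_micrograph()] into an
#' axial stack: each xy position is occupied over a centred run of slices
#' whose length (the local aggregate thickness) scales with `mass_fraction`
#' and the local structure density, so the z-extent of the occupancy
#' envelope grows monotonically with aggregate load.
#'
#' @inheritParams render_micrograph
#' @return An object of class `zstack`: a list with `slices` (list of
#'   matrices), `z_step` (micrometres) and `bit_depth`.
#' @export
render_zstack <- function(mass_fraction, params,
                          species = NA_character_, aef_fraction = NA_real_,
                          time_h = NA_real_, replicate_id = NA_integer_) {
  if (!inherits(params, "imaging_params")) {
    stop_param("`params` must be an imaging_params object")
  }
  if (params$z_slices < 2) stop_param("z_slices must be >= 2 for a z-stack")
  check_number(mass_fraction, "mass_fraction", lower = 0, upper = 1)
  maxI <- 2^params$bit_depth - 1
  nz <- params$z_slices
  slices <- with_seed(params$rng_seed, {
    sig <- gaussian_blur(draw_structure(mass_fraction, params) *
                           params$amplitude * maxI, params$psf_sigma)
    smax <- max(sig)
    occ <- if (smax > 0) {
      round(nz * mass_fraction * sig / smax)
    } else {
      matrix(0L, params$height, params$width)
    }
    mid <- (nz + 1) / 2
    lapply(seq_len(nz), function(k) {
      inside <- abs(k - mid) < occ / 2
      noise <- matrix(rnorm(params$height * params$width,
                            mean = params$background_mean,
                            sd = params$background_sd),
                      params$height, params$width)
      round(pmin(pmax(sig * inside + noise, 0), maxI))
    })
  })
  structure(
    list(slices = slices, z_step = params$z_step,
         bit_depth = params$bit_depth,
         meta = list(species = species, aef_fraction = aef_fraction,
                     time_h = time_h, replicate_id = replicate_id)),
    class = "zstack"
  )
}

#' @export
print.zstack <- function(x, ...) {
  cat(sprintf("<zstack %d slices of %d x %d, z step %g um>\n",
              length(x$slices), nrow(x$slices[[1]]), ncol(x$slices[[1]]),
              x$z_step))
  invisible(x)
}
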