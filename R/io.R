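#' Write a micrograph to disk
#'
#' Single-page TIFF (or PNG by extension) at the micrograph's bit depth.
#'
#' @param img A [micrograph()].
#' @param path Output path ending in `.tif`, `.tiff` or `.png`.
#' @return `path`, invisibly.
#' @export
write_micrograph <- function(img, path) {
  if (!inherits(img, "micrograph")) stop_input("`img` must be a micrograph")
  maxI <- 2^img$bit_depth - 1
  norm <- img$pixels / maxI
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(norm, path, bits.per.sample = img$bit_depth)
  } else if (ext == "png") {
    png::writePNG(norm, path)
  } else {
    stop_input("unsupported image extension: .%s", ext)
  }
  invisible(path)
}

#' Read a micrograph from disk
#'
#' Reads TIFF or PNG, rescales to raw intensity units on the
#' `[0, 2^bit_depth - 1]` scale, collapses colour channels by mean, and
#' attaches the supplied metadata.
#'
#' @param path Image path.
#' @param bit_depth Bit depth of the stored data (default 8).
#' @param species,aef_fraction,time_h,replicate_id Metadata.
#' @return A [micrograph()].
#' @export
read_micrograph <- function(path, bit_depth = 8, species = NA_character_,
                            aef_fraction = NA_real_, time_h = NA_real_,
                            replicate_id = NA_integer_) {
  ext <- tolower(tools::file_ext(path))
  arr <- if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path)
  } else if (ext == "png") {
    png::readPNG(path)
  } else {
    stop_input("unsupported image extension: .%s", ext)
  }
  if (length(dim(arr)) == 3L) arr <- apply(arr, c(1, 2), mean)
  px <- round(arr * (2^bit_depth - 1))
  micrograph(px, bit_depth = bit_depth, species = species,
             aef_fraction = aef_fraction, time_h = time_h,
             replicate_id = replicate_id)
}

#' Write a z-stack as a multi-page TIFF
#'
#' @param zs A `zstack` from [render_zstack()].
#' @param path Output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_zstack <- function(zs, path) {
  if (!inherits(zs, "zstack")) stop_input("`zs` must be a zstack")
  maxI <- 2^zs$bit_depth - 1
  tiff::writeTIFF(lapply(zs$slices, function(s) s / maxI), path,
                  bits.per.sample = zs$bit_depth)
  invisible(path)
}

#' Read and write FASTA sequence tables
#'
#' Thin wrappers over Biostrings keeping the package's tabular sequence
#' representation (`id`, `residues`).
#'
#' @param df A data frame with `id` and `residues` columns.
#' @param path FASTA file path.
#' @return `read_fasta()` returns a tibble with `id`, `residues`;
#'   `write_fasta()` returns `path` invisibly.
#' @export
write_fasta <- function(df, path) {
  sq <- coerce_seqs(df)
  set <- Biostrings::AAStringSet(sq)
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  tibble::tibble(id = names(set), residues = as.character(set))
}
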