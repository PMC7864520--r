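CONFIG_KEYS <- list(
  top = c("seed", "outdir", "panel", "times", "n_replicates", "image",
          "species_params", "alignment", "morphology", "family", "groups",
          "endpoint"),
  panel = c("species", "aef_fractions"),
  image = c("height", "width", "background_mean", "background_sd",
            "psf_sigma", "bit_depth", "dot_density", "mesh_length",
            "amplitude"),
  alignment = c("substitution", "gap_open", "gap_extend"),
  morphology = c("largest_component_min", "skeleton_density_min"),
  family = c("ancestor_length", "tree", "planted_sites"),
  groups = c("high", "low"),
  species_entry = c("total_monomer", "nucleation_rate", "elongation_rate",
                    "seed_ceiling", "noise_sd", "morphology")
)

#' Default pipeline configuration
#'
#' A single, fully explicit description of an end-to-end run: panel
#' definition, times, replicate count, imaging settings, per-species
#' kinetics, alignment scoring, morphology cutoffs, the synthetic sequence
#' family, and the activity groups for the site scan. Every stochastic step
#' derives its stream from `seed`. The list round-trips losslessly through
#' YAML via [write_run_config()] / [read_run_config()].
#'
#' @param outdir Output directory of the run.
#' @param seed Master integer seed.
#' @return A named list of class `run_config`.
#' @export
default_config <- function(outdir = "saaquant_run", seed = 1L) {
  sp <- species_defaults()
  species_params <- setNames(
    lapply(seq_len(nrow(sp)), function(i) {
      as.list(sp[i, setdiff(names(sp), "species")])
    }),
    sp$species
  )
  planted <- lapply(default_planted_sites(), function(p) {
    list(column = p$column, assign = as.list(p$assign))
  })
  structure(list(
    seed = as.integer(seed),
    outdir = outdir,
    panel = list(species = sp$species,
                 aef_fractions = c(0.2, 0.4, 0.6, 0.8, 1.0)),
    times = default_times(),
    n_replicates = 3L,
    image = list(height = 128L, width = 128L, background_mean = 30,
                 background_sd = 5, psf_sigma = 1.5, bit_depth = 8L,
                 dot_density = 70, mesh_length = 6000, amplitude = 0.55),
    species_params = species_params,
    alignment = list(substitution = "BLOSUM62", gap_open = -10,
                     gap_extend = -1),
    morphology = list(largest_component_min = 0.2,
                      skeleton_density_min = 0.012),
    family = list(ancestor_length = 130L, tree = default_family_tree(),
                  planted_sites = planted),
    groups = list(high = c("mouse", "cat"),
                  low = c("camel", "cattle", "goat")),
    endpoint = list(aef_fraction = 1.0, time_h = 168)
  ), class = "run_config")
}

#' Validate a run configuration
#'
#' Rejects unknown keys at every level (typo safety) and checks the panel,
#' times and seed. Returns the config invisibly on success.
#'
#' @param cfg A `run_config` list.
#' @export
validate_config <- function(cfg) {
  check_keys <- function(x, allowed, where) {
    extra <- setdiff(names(x), allowed)
    if (length(extra) > 0) {
      stop_param("unknown config key(s) in %s: %s", where,
                 paste(extra, collapse = ", "))
    }
  }
  if (!is.list(cfg)) stop_param("config must be a list")
  check_keys(cfg, CONFIG_KEYS$top, "top level")
  req <- c("seed", "outdir", "panel", "times", "n_replicates")
  miss <- setdiff(req, names(cfg))
  if (length(miss) > 0) {
    stop_param("missing config key(s): %s", paste(miss, collapse = ", "))
  }
  check_number(cfg$seed, "seed")
  check_keys(cfg$panel, CONFIG_KEYS$panel, "panel")
  if (length(cfg$panel$species) == 0L || length(cfg$panel$aef_fractions) == 0L) {
    stop_param("panel must name at least one species and one AEF fraction")
  }
  if (any(cfg$panel$aef_fractions < 0 | cfg$panel$aef_fractions > 1)) {
    stop_param("aef_fractions must lie in [0, 1]")
  }
  if (length(cfg$times) < 1L || any(diff(cfg$times) <= 0)) {
    stop_param("times must be strictly increasing")
  }
  for (key in c("image", "alignment", "morphology", "family", "groups")) {
    if (!is.null(cfg[[key]])) check_keys(cfg[[key]], CONFIG_KEYS[[key]], key)
  }
  if (!is.null(cfg$species_params)) {
    for (spn in names(cfg$species_params)) {
      check_keys(cfg$species_params[[spn]], CONFIG_KEYS$species_entry,
                 paste0("species_params$", spn))
    }
    miss <- setdiff(cfg$panel$species, names(cfg$species_params))
    if (length(miss) > 0) {
      stop_param("species_params missing entries for: %s",
                 paste(miss, collapse = ", "))
    }
  }
  invisible(cfg)
}

#' Read / write a run configuration as YAML
#'
#' @param cfg A `run_config` list.
#' @param path YAML file path.
#' @return `read_run_config()` returns a validated `run_config`;
#'   `write_run_config()` returns `path` invisibly.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$times <- as.numeric(unlist(cfg$times))
  cfg$panel$species <- as.character(unlist(cfg$panel$species))
  cfg$panel$aef_fractions <- as.numeric(unlist(cfg$panel$aef_fractions))
  validate_config(structure(cfg, class = "run_config"))
  structure(cfg, class = "run_config")
}

cfg_species_tbl <- function(cfg) {
  if (is.null(cfg$species_params)) return(species_defaults())
  dplyr::bind_rows(lapply(names(cfg$species_params), function(spn) {
    c(list(species = spn), cfg$species_params[[spn]])
  }))
}

cfg_imaging <- function(cfg) {
  im <- cfg$image %||% list()
  do.call(imaging_params, im)
}

cfg_family_params <- function(cfg, seed) {
  fam <- cfg$family
  planted <- lapply(fam$planted_sites %||% list(), function(p) {
    list(column = p$column, assign = unlist(p$assign))
  })
  sequence_sim_params(ancestor_length = fam$ancestor_length %||% 130L,
                      tree = fam$tree %||% default_family_tree(),
                      planted_sites = planted, rng_seed = seed)
}

log_line <- function(cfg, msg, ...) {
  line <- sprintf(msg, ...)
  message("[saaquant] ", line)
  logf <- file.path(cfg$outdir, "run.log")
  if (dir.exists(cfg$outdir)) cat(line, "\n", file = logf, append = TRUE)
  invisible(NULL)
}

#' Simulate a full synthetic dataset onto disk
#'
#' Generates the configured assay, writes every micrograph as
#' `{species}_{aef%}_{time}h_{rep}.tif` plus a CSV manifest and the
#' ground-truth mass fractions, and writes the synthetic sequence family
#' (FASTA), its true tree (Newick) and the planted sites (CSV).
#' Deterministic under a fixed config.
#'
#' @param cfg A `run_config` (validated here).
#' @return Invisibly, a list with `manifest` (tibble) and `family`.
#' @export
run_simulate <- function(cfg = default_config()) {
  validate_config(cfg)
  dir.create(file.path(cfg$outdir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  write_run_config(cfg, file.path(cfg$outdir, "config.yaml"))
  log_line(cfg, "simulate: seed %d, %d species x %d fractions x %d times x %d reps",
           cfg$seed, length(cfg$panel$species),
           length(cfg$panel$aef_fractions), length(cfg$times),
           cfg$n_replicates)
  panel <- tidyr::expand_grid(species = cfg$panel$species,
                              aef_fraction = cfg$panel$aef_fractions)
  assay <- generate_assay(panel = panel, times = cfg$times,
                          species_params = cfg_species_tbl(cfg),
                          n_replicates = cfg$n_replicates,
                          imaging = cfg_imaging(cfg),
                          rng_seed = cfg$seed)
  fname <- sprintf("%s_%03d_%03dh_%d.tif", assay$species,
                   round(assay$aef_fraction * 100), assay$time_h,
                   assay$replicate_id)
  manifest <- tibble::tibble(
    path = file.path("images", fname),
    species = assay$species, aef_fraction = assay$aef_fraction,
    time_h = assay$time_h, replicate_id = assay$replicate_id
  )
  purrr::walk2(assay$image, manifest$path, function(img, p) {
    write_micrograph(img, file.path(cfg$outdir, p))
  })
  readr::write_csv(manifest, file.path(cfg$outdir, "manifest.csv"))
  truth <- dplyr::select(assay, "species", "aef_fraction", "time_h",
                         "replicate_id", "mass_fraction",
                         "mass_fraction_true")
  readr::write_csv(truth, file.path(cfg$outdir, "truth_mass.csv"))

  fam <- simulate_sequence_family(cfg_family_params(cfg, cfg$seed))
  write_fasta(fam$sequences, file.path(cfg$outdir, "sequences.fasta"))
  ape::write.tree(fam$tree, file.path(cfg$outdir, "truth_tree.nwk"))
  readr::write_csv(fam$planted, file.path(cfg$outdir, "truth_planted.csv"))
  log_line(cfg, "simulate: wrote %d micrographs", nrow(manifest))
  invisible(list(manifest = manifest, family = fam))
}

#' Quantify a simulated (or real) dataset
#'
#' Reads every manifest image, computes the SD statistic and the morphology
#' descriptors, and writes tidy tables: `images.csv` (one row per readable
#' image), `timecourse.csv` (mean +/- SEM per species x fraction x time),
#' `doseresponse.csv` (endpoint replicates), `fits.csv` (per-species
#' sigmoid at the endpoint fraction and half-max dose fits),
#' `morphology.csv` and `ranking.csv`. Unreadable images are logged and
#' skipped, never aborting the batch.
#'
#' @param cfg A `run_config`.
#' @param manifest Manifest tibble; default reads `manifest.csv` from the
#'   run directory.
#' @return Invisibly, a named list of the output tibbles.
#' @export
run_quantify <- function(cfg = default_config(), manifest = NULL) {
  validate_config(cfg)
  if (is.null(manifest)) {
    manifest <- readr::read_csv(file.path(cfg$outdir, "manifest.csv"),
                                show_col_types = FALSE)
  }
  cuts <- do.call(morphology_cutoffs, cfg$morphology %||% list())
  bit_depth <- cfg$image$bit_depth %||% 8
  rows <- purrr::pmap(manifest, function(path, species, aef_fraction, time_h,
                                         replicate_id, ...) {
    img <- tryCatch(
      read_micrograph(file.path(cfg$outdir, path), bit_depth = bit_depth),
      error = function(e) {
        log_line(cfg, "quantify: FAILED %s (%s)", path, conditionMessage(e))
        NULL
      })
    if (is.null(img)) return(NULL)
    morph <- classify_morphology(img, cutoffs = cuts)
    tibble::tibble(path = path, species = species,
                   aef_fraction = aef_fraction, time_h = time_h,
                   replicate_id = replicate_id,
                   sd_value = sd_statistic(img),
                   morphology_label = morph$label,
                   n_components = morph$n_components,
                   largest_component_fraction = morph$largest_component_fraction,
                   skeleton_length_per_area = morph$skeleton_length_per_area)
  })
  images <- dplyr::bind_rows(rows)
  if (nrow(images) == 0L) stop_input("no readable images in manifest")
  tc <- summarize_timecourse(images, .data$species, .data$aef_fraction)
  ep <- cfg$endpoint %||% list()
  ep_time <- ep$time_h %||% max(images$time_h)
  ep_frac <- ep$aef_fraction %||% max(images$aef_fraction)
  dr <- dose_response(images, endpoint_time = ep_time)
  endpoint <- dplyr::filter(images, .data$time_h == ep_time,
                            .data$aef_fraction == ep_frac)
  ranking <- rank_activity(endpoint)

  fits <- dplyr::bind_rows(lapply(sort(unique(images$species)), function(sp) {
    tc_sp <- dplyr::filter(tc, .data$species == sp,
                           .data$aef_fraction == ep_frac)
    sig <- tryCatch(fit_sigmoid(tc_sp), error = function(e) NULL)
    dr_sp <- dplyr::filter(dr, .data$species == sp)
    hm <- tryCatch(fit_half_max(dr_sp), error = function(e) NULL)
    tibble::tibble(
      species = sp,
      sigmoid_baseline = sig$baseline %||% NA_real_,
      sigmoid_plateau = sig$plateau %||% NA_real_,
      sigmoid_t50 = sig$t50 %||% NA_real_,
      sigmoid_slope = sig$slope %||% NA_real_,
      sigmoid_lag = sig$lag_time %||% NA_real_,
      sigmoid_extrapolated = sig$extrapolated %||% NA,
      half_max_fraction = hm$half_max_fraction %||% NA_real_,
      hill = hm$hill %||% NA_real_,
      half_max_unidentifiable = hm$unidentifiable %||% NA
    )
  }))
  morph_tbl <- dplyr::count(images, .data$species, .data$time_h,
                            .data$morphology_label)

  out <- list(images = images, timecourse = tc, doseresponse = dr,
              fits = fits, morphology = morph_tbl, ranking = ranking)
  for (nm in names(out)) {
    readr::write_csv(out[[nm]],
                     file.path(cfg$outdir, paste0(
                       switch(nm, images = "images", timecourse = "timecourse",
                              doseresponse = "doseresponse", fits = "fits",
                              morphology = "morphology", ranking = "ranking"),
                       ".csv")))
  }
  log_line(cfg, "quantify: %d/%d images quantified", nrow(images),
           nrow(manifest))
  invisible(out)
}

#' Run the sequence-homology analysis of a dataset
#'
#' Reads the run's FASTA family, aligns it progressively, writes the gapped
#' alignment (FASTA), pairwise identities and overall homology (CSV), the
#' per-column conservation classes (TSV), the UPGMA tree (Newick), the
#' high/low-group clade check and the discriminative-site scan (CSV).
#'
#' @param cfg A `run_config`.
#' @return Invisibly, a named list of the homology results.
#' @export
run_homology <- function(cfg = default_config()) {
  validate_config(cfg)
  seqs <- read_fasta(file.path(cfg$outdir, "sequences.fasta"))
  al_cfg <- cfg$alignment %||% list()
  aln <- progressive_msa(seqs,
                         substitution = al_cfg$substitution %||% "BLOSUM62",
                         gap_open = al_cfg$gap_open %||% -10,
                         gap_extend = al_cfg$gap_extend %||% -1)
  writeLines(
    unlist(lapply(names(aln$rows), function(id) c(paste0(">", id), aln$rows[[id]]))),
    file.path(cfg$outdir, "alignment.fasta"))
  pid <- pairwise_identity(aln)
  hom <- overall_homology(aln)
  cons <- conservation_classes(aln)
  dmat <- matrix(0, length(aln$rows), length(aln$rows),
                 dimnames = list(names(aln$rows), names(aln$rows)))
  for (k in seq_len(nrow(pid))) {
    d <- 1 - (pid$identity[k] %||% 0) / 100
    if (is.na(d)) d <- 1
    dmat[pid$id_a[k], pid$id_b[k]] <- dmat[pid$id_b[k], pid$id_a[k]] <- d
  }
  tree <- build_tree(dmat)
  ape::write.tree(tree, file.path(cfg$outdir, "upgma_tree.nwk"))
  groups <- cfg$groups %||% list(high = character(0), low = character(0))
  high_clade <- length(groups$high) > 1 &&
    all(groups$high %in% tree$tip.label) &&
    clade_check(tree, groups$high)
  sites <- discriminative_site_scan(aln, groups$high, groups$low)
  readr::write_csv(pid, file.path(cfg$outdir, "pairwise_identity.csv"))
  readr::write_csv(hom, file.path(cfg$outdir, "homology.csv"))
  readr::write_tsv(cons, file.path(cfg$outdir, "conservation.tsv"))
  readr::write_csv(sites, file.path(cfg$outdir, "sites.csv"))
  readr::write_csv(tibble::tibble(group = "high",
                                  labels = paste(groups$high, collapse = "+"),
                                  monophyletic = high_clade),
                   file.path(cfg$outdir, "clade.csv"))
  log_line(cfg, "homology: min identity %.2f%%, %d discriminative site(s)",
           hom$min_identity, nrow(sites))
  invisible(list(alignment = aln, identity = pid, homology = hom,
                 conservation = cons, tree = tree, clade_high = high_clade,
                 sites = sites))
}

#' Render the summary report of a run
#'
#' Writes a self-contained `report/` directory: a Markdown summary, the
#' time-course and dose-response figures (PNG) with their plotted data as
#' CSV, the tree figure, and the discriminative-site table. Missing inputs
#' produce explicit "no data" sections rather than errors; regeneration is
#' idempotent.
#'
#' @param cfg A `run_config`.
#' @return Invisibly, the report directory path.
#' @export
run_report <- function(cfg = default_config()) {
  validate_config(cfg)
  rep_dir <- file.path(cfg$outdir, "report")
  dir.create(rep_dir, recursive = TRUE, showWarnings = FALSE)
  md <- c("# Seeded SAA aggregation: run report", "")
  read_if <- function(name) {
    p <- file.path(cfg$outdir, name)
    if (file.exists(p)) readr::read_csv(p, show_col_types = FALSE) else NULL
  }
  tc <- read_if("timecourse.csv")
  if (!is.null(tc) && nrow(tc) > 0) {
    readr::write_csv(tc, file.path(rep_dir, "timecourse_plotdata.csv"))
    p <- plot_timecourse(tc)
    ggplot2::ggsave(file.path(rep_dir, "timecourse.png"), p,
                    width = 8, height = 5, dpi = 120)
    md <- c(md, "## Time courses", "",
            "SD value versus time (mean +/- SEM); see timecourse.png.", "")
  } else {
    md <- c(md, "## Time courses", "", "No data.", "")
  }
  dr <- read_if("doseresponse.csv")
  if (!is.null(dr) && nrow(dr) > 0) {
    readr::write_csv(dr, file.path(rep_dir, "doseresponse_plotdata.csv"))
    p <- plot_doseresponse(dr)
    ggplot2::ggsave(file.path(rep_dir, "doseresponse.png"), p,
                    width = 7, height = 5, dpi = 120)
    md <- c(md, "## Dose response", "",
            "Endpoint SD versus AEF fraction; see doseresponse.png.", "")
  } else {
    md <- c(md, "## Dose response", "", "No data.", "")
  }
  rk <- read_if("ranking.csv")
  if (!is.null(rk) && nrow(rk) > 0) {
    md <- c(md, "## Activity ranking", "",
            paste0("| rank | species | mean SD |"), "|---|---|---|",
            sprintf("| %d | %s | %.3f |", rk$rank, rk$species, rk$mean_sd), "")
  } else {
    md <- c(md, "## Activity ranking", "", "No data.", "")
  }
  treep <- file.path(cfg$outdir, "upgma_tree.nwk")
  if (file.exists(treep)) {
    tree <- ape::read.tree(treep)
    grDevices::png(file.path(rep_dir, "tree.png"), width = 700, height = 500)
    ape::plot.phylo(tree, main = "UPGMA tree of SAA family")
    grDevices::dev.off()
    md <- c(md, "## Homology tree", "", "See tree.png.", "")
  } else {
    md <- c(md, "## Homology tree", "", "No data.", "")
  }
  sites <- read_if("sites.csv")
  if (!is.null(sites) && nrow(sites) > 0) {
    readr::write_csv(sites, file.path(rep_dir, "sites.csv"))
    md <- c(md, "## Discriminative sites", "",
            "| column | high group | low group | classes |", "|---|---|---|---|",
            sprintf("| %d | %s | %s | %s vs %s |", sites$column,
                    sites$group_a_residues, sites$group_b_residues,
                    sites$group_a_class, sites$group_b_class), "")
  } else {
    md <- c(md, "## Discriminative sites", "", "No data.", "")
  }
  writeLines(md, file.path(rep_dir, "summary.md"))
  log_line(cfg, "report: written to %s", rep_dir)
  invisible(rep_dir)
}

#' Run the whole pipeline
#'
#' `simulate -> quantify -> homology -> report` under one config and seed.
#'
#' @param cfg A `run_config`.
#' @return Invisibly, a list with the quantification and homology results.
#' @export
run_all <- function(cfg = default_config()) {
  validate_config(cfg)
  run_simulate(cfg)
  quant <- run_quantify(cfg)
  hom <- run_homology(cfg)
  run_report(cfg)
  invisible(list(quantify = quant, homology = hom))
}
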