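#' @title End-to-end experiment orchestration
#' @name cli_io
#' @description
#' `run_experiment()` composes the whole analysis — simulate two-channel
#' cells per condition, detect spots in both channels, calibrate the
#' single-peptide unit from free peptides, quantify every mRNA's
#' translation site, aggregate per-cell fractions, and compare conditions —
#' as a pure function of a configuration and a master seed. Per-cell seeds
#' are derived deterministically from (master seed, condition, cell index),
#' so adding cells or conditions never perturbs existing ones.
NULL

# Deterministic 31-bit hash of (master seed, condition name, cell index,
# stream id); plain double arithmetic, exact below 2^53.
derive_cell_seed <- function(master_seed, condition, cell_index,
                             stream = 0L) {
  m <- 2147483647
  h <- as.numeric(master_seed) %% m
  chars <- utf8ToInt(as.character(condition))
  for (ch in chars) h <- (h * 131 + ch) %% m
  h <- (h * 48271 + as.numeric(cell_index) * 7919 +
          as.numeric(stream) * 104729 + 1) %% m
  as.integer(h)
}

#' Experiment configuration
#'
#' Bundles every tunable of the simulate-detect-calibrate-quantify-compare
#' pipeline with the study defaults.
#'
#' @param presets list of [condition_preset()]s (default: all four study
#'   conditions).
#' @param n_cells_per_condition cells simulated per condition.
#' @param seed master seed.
#' @param geometry,psf,noise,i_single_true imaging model, see
#'   [render_stack()].
#' @param n_mrna_range per-cell mRNA count range (uniform draw).
#' @param k_mad detection threshold multiplier.
#' @param bounds spot [quality_bounds()].
#' @param site_params [site_fit_params()] for translation-site fits.
#' @param exclusion_radius_nm free-peptide exclusion radius around mRNAs.
#' @param min_calibration_spots minimum free peptides for calibration.
#' @param var_equal use pooled-variance t-tests instead of Welch.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(presets = condition_presets(),
                              n_cells_per_condition = 24,
                              seed = 1,
                              geometry = default_cell_geometry(),
                              psf = psf_model(),
                              noise = noise_model(),
                              i_single_true = 800,
                              n_mrna_range = c(8L, 30L),
                              k_mad = 6,
                              bounds = quality_bounds(),
                              site_params = site_fit_params(),
                              exclusion_radius_nm = 500,
                              min_calibration_spots = 5,
                              var_equal = FALSE) {
  structure(list(presets = presets,
                 n_cells_per_condition = n_cells_per_condition,
                 seed = seed, geometry = geometry, psf = psf,
                 noise = noise, i_single_true = i_single_true,
                 n_mrna_range = n_mrna_range, k_mad = k_mad,
                 bounds = bounds, site_params = site_params,
                 exclusion_radius_nm = exclusion_radius_nm,
                 min_calibration_spots = min_calibration_spots,
                 var_equal = var_equal),
            class = "experiment_config")
}

#' Analyze one simulated or loaded cell
#'
#' Runs detection on both channels, keeps cytoplasmic mRNA spots, selects
#' free peptides, calibrates the single-peptide unit, and quantifies one
#' translation site per mRNA.
#'
#' @param stacks list with `image_stack` elements `mrna` and `protein`.
#' @param config an [experiment_config()].
#' @return List: `mrna_spots`, `protein_spots`, `free_peptides`,
#'   `calibration`, `sites` (one row per cytoplasmic mRNA).
#' @export
analyze_cell <- function(stacks, config = experiment_config()) {
  sig <- psf_sigma_voxels(config$psf, config$geometry)
  mrna_spots <- detect_spots(stacks$mrna, sig["sigma_xy"], sig["sigma_z"],
                             config$k_mad, bounds = config$bounds)
  mask <- config$geometry$cyto_mask
  if (nrow(mrna_spots) > 0) {
    yi <- pmin(pmax(round(mrna_spots$y0), 1), nrow(mask))
    xi <- pmin(pmax(round(mrna_spots$x0), 1), ncol(mask))
    mrna_spots <- mrna_spots[mask[cbind(yi, xi)], , drop = FALSE]
  }
  protein_spots <- detect_spots(stacks$protein, sig["sigma_xy"],
                                sig["sigma_z"], config$k_mad,
                                bounds = config$bounds)
  free <- select_free_peptides(protein_spots, mrna_spots, mask,
                               config$exclusion_radius_nm,
                               config$geometry$voxel_nm[3])
  cal <- calibrate_single_peptide(free, config$min_calibration_spots)
  sites <- if (nrow(mrna_spots) == 0) {
    data.frame(mrna_id = integer(0), I_ts = numeric(0), N = numeric(0),
               distance_px = numeric(0), associated = logical(0))
  } else {
    do.call(rbind, lapply(seq_len(nrow(mrna_spots)), function(i) {
      sp <- mrna_spots[i, ]
      sp$mrna_id <- i
      quantify_translation_site(stacks$protein, sp, cal,
                                config$site_params)
    }))
  }
  list(mrna_spots = mrna_spots, protein_spots = protein_spots,
       free_peptides = free, calibration = cal, sites = sites)
}

#' Run the full multi-condition experiment
#'
#' Pure function of (config, master seed): simulates every cell, analyzes
#' it, aggregates per-cell statistics, summarizes each condition (mean
#' fraction with SEM over included cells) and performs all pairwise
#' two-sample t-tests. A failing cell is recorded with its stage and id
#' and the remaining cells are still processed.
#'
#' @param config an [experiment_config()].
#' @param out_dir optional directory; when given, the per-cell table,
#'   condition summaries and pairwise tests are written there as CSV/JSON.
#' @param quiet suppress per-cell progress messages.
#' @return List of class `experiment_report`: `cells` (per-cell
#'   data.frame), `summaries`, `tests`, `errors`, `provenance`.
#' @export
run_experiment <- function(config = experiment_config(), out_dir = NULL,
                           quiet = TRUE) {
  cells <- list(); errors <- list()
  for (preset in config$presets) {
    for (cell in seq_len(config$n_cells_per_condition)) {
      res <- tryCatch({
        s_n <- derive_cell_seed(config$seed, preset$name, cell, 0L)
        s_gt <- derive_cell_seed(config$seed, preset$name, cell, 1L)
        s_rd <- derive_cell_seed(config$seed, preset$name, cell, 2L)
        n_mrna <- with_seed(s_n, sample(
          config$n_mrna_range[1]:config$n_mrna_range[2], 1L))
        gt <- sample_ground_truth(preset, config$geometry, n_mrna,
                                  seed = s_gt)
        stacks <- render_stack(gt, config$geometry, config$psf,
                               config$noise, config$i_single_true,
                               seed = s_rd)
        an <- analyze_cell(stacks, config)
        cs <- cell_summary(an$sites, cell_id = cell,
                           condition = preset$name)
        cs$n_mRNA_true <- n_mrna
        cs$true_fraction <- mean(gt$mrna$translating)
        cs$I_single <- an$calibration$I_single
        if (!quiet)
          message(sprintf("%s cell %d: %d mRNAs, fraction %.2f",
                          preset$name, cell, cs$n_mRNA, cs$fraction))
        cs
      }, error = function(e) {
        errors[[length(errors) + 1L]] <<- list(
          condition = preset$name, cell = cell,
          message = conditionMessage(e))
        NULL
      })
      if (!is.null(res)) cells[[length(cells) + 1L]] <- res
    }
  }
  cells <- if (length(cells)) do.call(rbind, cells) else data.frame()
  summaries <- lapply(split(cells, cells$condition), function(cc)
    tryCatch(condition_summary(cc), error = function(e) NULL))
  summaries <- Filter(Negate(is.null), summaries)
  tests <- pairwise_condition_tests(cells, config$var_equal)
  report <- structure(list(
    cells = cells, summaries = summaries, tests = tests, errors = errors,
    provenance = list(
      seed = config$seed,
      n_cells_per_condition = config$n_cells_per_condition,
      presets = lapply(config$presets, unclass),
      geometry_dim = config$geometry$dim,
      voxel_nm = config$geometry$voxel_nm,
      psf = unclass(config$psf), noise = unclass(config$noise),
      i_single_true = config$i_single_true,
      package_version = as.character(utils::packageVersion("nascentq"))
    )), class = "experiment_report")
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir))
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(cells, file.path(out_dir, "cells.csv"),
                     row.names = FALSE)
    if (nrow(tests))
      utils::write.csv(tests, file.path(out_dir, "pairwise_tests.csv"),
                       row.names = FALSE)
    jsonlite::write_json(list(summaries = summaries,
                              provenance = report$provenance),
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("experiment_report:", nrow(x$cells), "cells,",
      length(x$summaries), "conditions,",
      length(x$errors), "errors\n")
  for (s in x$summaries)
    cat(sprintf("  %-18s n=%2d  mean fraction %.3f  (SEM %.3f)\n",
                s$condition, s$n_cells, s$mean_fraction, s$sem))
  invisible(x)
}
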