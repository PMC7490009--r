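#' @title Synthetic smFISH-IF scene generation
#' @name synthetic_imaging
#' @description
#' The simulator produces matched two-channel 3D stacks (an mRNA/FISH channel
#' and a protein/SunTag channel) plus a ground-truth table with the
#' statistical structure the downstream colocalization analysis assumes:
#' each mRNA is independently translating with a per-condition probability,
#' translating mRNAs carry `k >= 1` nascent chains so their translation site
#' is `k` single-peptide units bright, and released single peptides are
#' scattered through the cytoplasm at approximately one unit each.
NULL

# Evaluate expr with a temporary RNG state seeded at `seed`; the caller's
# RNG stream is untouched so derived per-cell seeds stay independent.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# log-normal with mean `mean` and coefficient of variation `cv`
rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv <= 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

# Uniform positions over the cytoplasm mask with an optional minimum
# pairwise x-y spacing (rejection sampling). Returns a data.frame(z, y, x)
# in continuous 1-based voxel coordinates.
sample_positions <- function(geometry, n, min_spacing = 0) {
  pix <- which(geometry$cyto_mask, arr.ind = TRUE)  # (y, x) integer pixels
  if (nrow(pix) == 0) stop("geometry has an empty cytoplasm mask")
  if (n == 0)
    return(data.frame(z = numeric(0), y = numeric(0), x = numeric(0)))
  nz <- geometry$dim[1]
  zlo <- 1 + geometry$z_margin
  zhi <- nz - geometry$z_margin
  if (zhi < zlo) { zlo <- zhi <- (1 + nz) / 2 }
  ys <- xs <- numeric(n)
  placed <- 0L
  tries <- 0L
  max_tries <- 2000L * n
  while (placed < n) {
    if (tries >= max_tries)
      stop("could not place ", n, " positions at spacing ", min_spacing,
           " in the cytoplasm mask")
    tries <- tries + 1L
    i <- sample.int(nrow(pix), 1L)
    y <- pix[i, 1] + stats::runif(1, -0.5, 0.5)
    x <- pix[i, 2] + stats::runif(1, -0.5, 0.5)
    if (min_spacing > 0 && placed > 0) {
      d2 <- (ys[seq_len(placed)] - y)^2 + (xs[seq_len(placed)] - x)^2
      if (min(d2) < min_spacing^2) next
    }
    placed <- placed + 1L
    ys[placed] <- y; xs[placed] <- x
  }
  data.frame(z = stats::runif(n, zlo, zhi), y = ys, x = xs)
}

#' Sample per-cell ground truth for one condition
#'
#' Draws mRNA positions uniformly over the cytoplasm (with a minimum
#' pairwise lateral spacing so translation sites stay resolvable), assigns
#' each mRNA an independent translating state with the preset's probability,
#' draws nascent-chain counts `k = 1 + Poisson(lambda)` on translating
#' mRNAs, and scatters released single peptides through the cytoplasm.
#'
#' @param preset a [condition_preset()].
#' @param geometry a [cell_geometry()].
#' @param n_mRNA number of cytoplasmic mRNAs to place.
#' @param seed integer seed; the draw is reproducible for a fixed seed and
#'   leaves the caller's RNG stream untouched.
#' @param min_spacing minimum pairwise mRNA spacing, x-y pixels.
#' @param mean_mrna_intensity mean integrated intensity of an mRNA spot,
#'   counts; per-spot intensities are log-normal with CV
#'   `cv_mrna_intensity` around it.
#' @param cv_mrna_intensity coefficient of variation of mRNA intensities.
#' @param cv_peptide_intensity coefficient of variation of free-peptide
#'   intensities (in single-peptide units, mean 1).
#' @return A `ground_truth` object: list with data.frames `mrna`
#'   (id, z, y, x, translating, k, mrna_intensity) and `free`
#'   (id, z, y, x, intensity), positions in continuous 1-based voxel units.
#' @export
sample_ground_truth <- function(preset, geometry, n_mRNA, seed,
                                min_spacing = 5,
                                mean_mrna_intensity = 800,
                                cv_mrna_intensity = 0.2,
                                cv_peptide_intensity = 0.1) {
  stopifnot(inherits(preset, "condition_preset"), n_mRNA >= 0)
  if (!any(geometry$cyto_mask))
    stop("geometry has an empty cytoplasm mask")
  with_seed(seed, {
    pos <- sample_positions(geometry, n_mRNA, min_spacing)
    translating <- stats::rbinom(n_mRNA, 1, preset$p_translating) == 1
    k <- integer(n_mRNA)
    k[translating] <- 1L + stats::rpois(sum(translating),
                                        preset$lambda_nascent)
    mrna <- data.frame(
      id = seq_len(n_mRNA),
      z = pos$z, y = pos$y, x = pos$x,
      translating = translating, k = k,
      mrna_intensity = rlnorm_mean_cv(n_mRNA, mean_mrna_intensity,
                                      cv_mrna_intensity)
    )
    n_free <- stats::rpois(1, preset$free_peptide_density)
    fpos <- sample_positions(geometry, n_free, min_spacing = 0)
    free <- data.frame(
      id = seq_len(n_free),
      z = fpos$z, y = fpos$y, x = fpos$x,
      intensity = rlnorm_mean_cv(n_free, 1, cv_peptide_intensity)
    )
    structure(list(mrna = mrna, free = free, preset = preset$name,
                   seed = as.integer(seed)),
              class = "ground_truth")
  })
}

# Add one point-sampled 3D Gaussian of integrated intensity `intensity`
# (counts) at continuous center (z0, y0, x0); sigmas in voxel units.
add_gaussian_spot <- function(arr, z0, y0, x0, intensity,
                              sigma_xy, sigma_z, radius_sigma = 6) {
  d <- dim(arr)
  amp <- intensity / ((2 * pi)^1.5 * sigma_xy^2 * sigma_z)
  rz <- ceiling(radius_sigma * sigma_z)
  rxy <- ceiling(radius_sigma * sigma_xy)
  zi <- max(1, floor(z0) - rz):min(d[1], ceiling(z0) + rz)
  yi <- max(1, floor(y0) - rxy):min(d[2], ceiling(y0) + rxy)
  xi <- max(1, floor(x0) - rxy):min(d[3], ceiling(x0) + rxy)
  gz <- exp(-(zi - z0)^2 / (2 * sigma_z^2))
  gy <- exp(-(yi - y0)^2 / (2 * sigma_xy^2))
  gx <- exp(-(xi - x0)^2 / (2 * sigma_xy^2))
  arr[zi, yi, xi] <- arr[zi, yi, xi] + amp * outer(gz, outer(gy, gx))
  arr
}

apply_noise <- function(arr, noise) {
  expected <- arr + noise$background
  if (noise$gain > 0) {
    out <- noise$gain * stats::rpois(length(expected),
                                     pmax(expected, 0) / noise$gain)
  } else {
    out <- expected
  }
  if (noise$read_sigma > 0)
    out <- out + stats::rnorm(length(expected), 0, noise$read_sigma)
  array(out, dim = dim(arr))
}

#' Render a two-channel stack from ground truth
#'
#' Every mRNA renders one Gaussian spot in the mRNA channel with its drawn
#' integrated intensity. In the protein channel, each translating mRNA
#' renders a translation-site spot of integrated intensity
#' `k * i_single_true` at the mRNA position, and each free peptide a spot of
#' `intensity * i_single_true` (intensity ~ 1). Spots are point-sampled
#' Gaussians, so a fitted sampled-Gaussian model recovers the generating
#' parameters exactly in the noiseless limit. Noise is applied last.
#'
#' @param gt a `ground_truth` from [sample_ground_truth()].
#' @param geometry a [cell_geometry()].
#' @param psf a [psf_model()].
#' @param noise a [noise_model()].
#' @param i_single_true integrated intensity of one single SunTag peptide,
#'   counts.
#' @param seed integer seed for the noise draw; identical inputs and seed
#'   give bit-identical stacks.
#' @return List with `image_stack` elements `mrna` and `protein`.
#' @export
render_stack <- function(gt, geometry, psf = psf_model(),
                         noise = noise_model(), i_single_true = 800,
                         seed = 1) {
  d <- geometry$dim
  sig <- psf_sigma_voxels(psf, geometry)
  ok_pos <- function(df) {
    nrow(df) == 0 || all(df$z >= 0.5 & df$z <= d[1] + 0.5 &
                           df$y >= 0.5 & df$y <= d[2] + 0.5 &
                           df$x >= 0.5 & df$x <= d[3] + 0.5)
  }
  if (!ok_pos(gt$mrna) || !ok_pos(gt$free))
    stop("ground-truth positions fall outside the stack")
  mrna <- array(0, dim = d)
  prot <- array(0, dim = d)
  for (i in seq_len(nrow(gt$mrna))) {
    m <- gt$mrna[i, ]
    mrna <- add_gaussian_spot(mrna, m$z, m$y, m$x, m$mrna_intensity,
                              sig["sigma_xy"], sig["sigma_z"])
    if (m$k > 0)
      prot <- add_gaussian_spot(prot, m$z, m$y, m$x, m$k * i_single_true,
                                sig["sigma_xy"], sig["sigma_z"])
  }
  for (i in seq_len(nrow(gt$free))) {
    f <- gt$free[i, ]
    prot <- add_gaussian_spot(prot, f$z, f$y, f$x,
                              f$intensity * i_single_true,
                              sig["sigma_xy"], sig["sigma_z"])
  }
  with_seed(seed, {
    mrna <- apply_noise(mrna, noise)
    prot <- apply_noise(prot, noise)
  })
  list(mrna = image_stack(mrna, geometry$voxel_nm),
       protein = image_stack(prot, geometry$voxel_nm))
}

#' Generate a multi-condition experiment on disk
#'
#' Simulates `n_cells_per_condition` cells for each preset and writes, per
#' cell, a two-channel pair of multi-page TIFF stacks and a ground-truth
#' CSV, plus one manifest CSV linking them and a JSON sidecar echoing the
#' generation parameters. Per-cell mRNA counts are drawn uniformly on
#' `n_mrna_range` (default 8-30) so simulated cells pass the downstream
#' 6-35 mRNA inclusion filter.
#'
#' @param presets list of [condition_preset()] (e.g. [condition_presets()]).
#' @param n_cells_per_condition cells per preset, `>= 1`.
#' @param seed master seed; per-cell seeds are derived deterministically so
#'   adding cells never perturbs existing ones.
#' @param out_dir output directory (created if needed).
#' @param geometry,psf,noise,i_single_true imaging model, as in
#'   [render_stack()].
#' @param n_mrna_range integer range for per-cell mRNA counts.
#' @return Invisibly, the manifest data.frame.
#' @export
generate_experiment <- function(presets, n_cells_per_condition, seed,
                                out_dir,
                                geometry = default_cell_geometry(),
                                psf = psf_model(), noise = noise_model(),
                                i_single_true = 800,
                                n_mrna_range = c(8L, 30L)) {
  stopifnot(n_cells_per_condition >= 1)
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  rows <- list()
  for (ci in seq_along(presets)) {
    preset <- presets[[ci]]
    for (cell in seq_len(n_cells_per_condition)) {
      s_n <- derive_cell_seed(seed, ci, cell, 0L)
      s_gt <- derive_cell_seed(seed, ci, cell, 1L)
      s_rd <- derive_cell_seed(seed, ci, cell, 2L)
      n_mrna <- with_seed(s_n, sample(n_mrna_range[1]:n_mrna_range[2], 1L))
      gt <- sample_ground_truth(preset, geometry, n_mrna, seed = s_gt)
      stacks <- render_stack(gt, geometry, psf, noise, i_single_true,
                             seed = s_rd)
      base <- sprintf("%s_cell%03d", preset$name, cell)
      f_mrna <- file.path(out_dir, paste0(base, "_mrna.tif"))
      f_prot <- file.path(out_dir, paste0(base, "_protein.tif"))
      f_gt <- file.path(out_dir, paste0(base, "_truth.csv"))
      write_stack(stacks$mrna, f_mrna)
      write_stack(stacks$protein, f_prot)
      write_ground_truth(gt, f_gt)
      rows[[length(rows) + 1L]] <- data.frame(
        condition = preset$name, cell = cell, n_mRNA = n_mrna,
        mrna_tiff = basename(f_mrna), protein_tiff = basename(f_prot),
        truth_csv = basename(f_gt), seed_gt = s_gt, seed_render = s_rd
      )
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  params <- list(
    seed = seed, n_cells_per_condition = n_cells_per_condition,
    presets = lapply(presets, unclass),
    geometry = list(dim = geometry$dim, voxel_nm = geometry$voxel_nm),
    psf = unclass(psf), noise = unclass(noise),
    i_single_true = i_single_true, n_mrna_range = n_mrna_range,
    package_version = as.character(utils::packageVersion("nascentq"))
  )
  jsonlite::write_json(params, file.path(out_dir, "params.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Write / read a ground-truth table as CSV
#'
#' The two record types (mRNAs and free peptides) share one CSV with a
#' `record` column; the round trip is lossless up to numeric printing at
#' full precision.
#'
#' @param gt a `ground_truth`.
#' @param path CSV path.
#' @return `write_ground_truth` returns `path` invisibly;
#'   `read_ground_truth` returns a `ground_truth`.
#' @export
write_ground_truth <- function(gt, path) {
  m <- cbind(record = "mrna", gt$mrna, intensity = NA_real_)
  f <- cbind(record = "free", gt$free, translating = NA, k = NA_integer_,
             mrna_intensity = NA_real_)
  cols <- c("record", "id", "z", "y", "x", "translating", "k",
            "mrna_intensity", "intensity")
  tab <- rbind(m[, cols], f[, cols])
  utils::write.csv(format(tab, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  m <- tab[tab$record == "mrna", ]
  f <- tab[tab$record == "free", ]
  structure(list(
    mrna = data.frame(id = as.integer(m$id), z = m$z, y = m$y, x = m$x,
                      translating = as.logical(m$translating),
                      k = as.integer(m$k), mrna_intensity = m$mrna_intensity),
    free = data.frame(id = as.integer(f$id), z = f$z, y = f$y, x = f$x,
                      intensity = f$intensity),
    preset = NA_character_, seed = NA_integer_
  ), class = "ground_truth")
}
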