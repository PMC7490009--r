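# Shared scene builders for the test suite. All fixtures are generated in
# code; nothing is read from disk.

# Small all-cytoplasm geometry (no nucleus) for fast scenes.
small_geometry <- function(dim_zyx = c(9L, 64L, 64L)) {
  mask <- matrix(TRUE, dim_zyx[2], dim_zyx[3])
  cell_geometry(dim_zyx, c(300, 107.5, 107.5), cyto_mask = mask)
}

# Default PSF widths in voxel units for the standard geometry.
SIG_XY <- 100 / 107.5
SIG_Z <- 350 / 300

# A bare array with point-sampled Gaussian spots added at the given
# centers (data.frame z, y, x, I) over a constant background.
render_spots_array <- function(dim_zyx, spots, background = 0,
                               sigma_xy = SIG_XY, sigma_z = SIG_Z) {
  a <- array(background, dim = dim_zyx)
  for (i in seq_len(nrow(spots)))
    a <- nascentq:::add_gaussian_spot(a, spots$z[i], spots$y[i],
                                      spots$x[i], spots$I[i],
                                      sigma_xy, sigma_z)
  a
}

# Hand-built ground_truth object (bypasses the sampler) for controlled
# rendering scenes.
manual_ground_truth <- function(mrna = NULL, free = NULL) {
  if (is.null(mrna))
    mrna <- data.frame(id = integer(0), z = numeric(0), y = numeric(0),
                       x = numeric(0), translating = logical(0),
                       k = integer(0), mrna_intensity = numeric(0))
  if (is.null(free))
    free <- data.frame(id = integer(0), z = numeric(0), y = numeric(0),
                       x = numeric(0), intensity = numeric(0))
  structure(list(mrna = mrna, free = free, preset = "manual", seed = 0L),
            class = "ground_truth")
}

# A noiseless single-peptide calibration: renders `n` isolated peptides of
# exactly one unit (i_single counts) and fits them.
noiseless_calibration <- function(i_single = 800, n = 6,
                                  geometry = small_geometry(c(9L, 48L, 96L))) {
  xs <- seq(12, by = 14, length.out = n)
  free <- data.frame(id = seq_len(n), z = 5, y = 24, x = xs, intensity = 1)
  gt <- manual_ground_truth(free = free)
  st <- render_stack(gt, geometry, noise = no_noise(10),
                     i_single_true = i_single, seed = 1)
  spots <- detect_spots(st$protein)
  calibrate_single_peptide(spots, min_spots = min(n, 5))
}

# Grid of well-separated lateral positions inside a stack.
grid_positions <- function(n, dim_zyx, spacing = 16, margin = 10) {
  per_row <- floor((dim_zyx[3] - 2 * margin) / spacing) + 1
  i <- seq_len(n) - 1
  data.frame(z = rep((dim_zyx[1] + 1) / 2, n),
             y = margin + (i %/% per_row) * spacing,
             x = margin + (i %% per_row) * spacing)
}
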