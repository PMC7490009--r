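#' Cell geometry for a simulated acquisition
#'
#' Describes the voxel grid of one two-channel acquisition together with the
#' cytoplasm and nucleus masks. Masks are 2D (y, x) logical matrices applied
#' to every z-plane (cells are treated as extruded in z, which is adequate at
#' an 11-plane stack depth). The cytoplasm mask excludes the nucleus, so the
#' two masks are disjoint by construction.
#'
#' @param dim_zyx integer vector `c(n_z, n_y, n_x)`, stack shape in voxels.
#' @param voxel_nm numeric vector `c(dz, dy, dx)` physical voxel size in nm.
#'   The lateral sizes must be equal (square pixels).
#' @param cyto_mask logical `n_y x n_x` matrix, TRUE inside the cytoplasm.
#' @param nucleus_mask logical `n_y x n_x` matrix, TRUE inside the nucleus.
#' @param z_margin numeric, emitters are kept at least this many voxels away
#'   from the first and last z-plane so their peaks are sampled.
#' @return An object of class `cell_geometry`.
#' @export
cell_geometry <- function(dim_zyx, voxel_nm = c(300, 107.5, 107.5),
                          cyto_mask, nucleus_mask = NULL, z_margin = 1.5) {
  stopifnot(length(dim_zyx) == 3, all(dim_zyx >= 1),
            length(voxel_nm) == 3, all(voxel_nm > 0))
  if (abs(voxel_nm[2] - voxel_nm[3]) > 1e-9)
    stop("lateral voxel sizes must be equal (dy = dx)")
  cyto_mask <- as.matrix(cyto_mask)
  if (!identical(dim(cyto_mask), as.integer(dim_zyx[2:3])))
    stop("cyto_mask dimensions must be (n_y, n_x)")
  if (is.null(nucleus_mask))
    nucleus_mask <- matrix(FALSE, dim_zyx[2], dim_zyx[3])
  # nucleus takes precedence: cytoplasm never overlaps it
  cyto_mask <- cyto_mask & !nucleus_mask
  structure(list(
    dim = as.integer(dim_zyx),
    voxel_nm = as.numeric(voxel_nm),
    cyto_mask = cyto_mask,
    nucleus_mask = nucleus_mask,
    z_margin = z_margin
  ), class = "cell_geometry")
}

#' Default simulated-cell geometry
#'
#' An 11 x 256 x 256 voxel stack at 107.5 nm lateral / 300 nm axial voxel
#' size (a standard widefield smFISH acquisition geometry), with an
#' elliptical cell footprint and an elliptical nucleus cut out of the
#' cytoplasm.
#'
#' @param dim_zyx stack shape, default `c(11, 256, 256)`.
#' @param voxel_nm voxel size `c(dz, dy, dx)` in nm.
#' @return A `cell_geometry`.
#' @export
default_cell_geometry <- function(dim_zyx = c(11L, 256L, 256L),
                                  voxel_nm = c(300, 107.5, 107.5)) {
  ny <- dim_zyx[2]; nx <- dim_zyx[3]
  cy <- (ny + 1) / 2; cx <- (nx + 1) / 2
  yy <- matrix(seq_len(ny), ny, nx)
  xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  # cell footprint: ellipse filling most of the field, 8-px border margin
  ay <- ny / 2 - 8; ax <- nx / 2 - 8
  cell <- ((yy - cy) / ay)^2 + ((xx - cx) / ax)^2 <= 1
  # nucleus: smaller ellipse, offset slightly off-center
  nuc <- ((yy - cy + ny * 0.06) / (ny * 0.18))^2 +
    ((xx - cx - nx * 0.05) / (nx * 0.20))^2 <= 1
  cell_geometry(dim_zyx, voxel_nm, cyto_mask = cell, nucleus_mask = nuc)
}

#' Point spread function model
#'
#' Isotropic-in-xy anisotropic-in-z Gaussian PSF. Defaults approximate a
#' 1.4 NA oil objective at ~515 nm emission.
#'
#' @param sigma_xy lateral Gaussian width, nm.
#' @param sigma_z axial Gaussian width, nm. Must be `>= sigma_xy`.
#' @return An object of class `psf_model`.
#' @export
psf_model <- function(sigma_xy = 100, sigma_z = 350) {
  stopifnot(sigma_xy > 0, sigma_z > 0)
  if (sigma_z < sigma_xy)
    stop("axial PSF width must be at least the lateral width")
  structure(list(sigma_xy = sigma_xy, sigma_z = sigma_z),
            class = "psf_model")
}

# PSF widths in voxel units for a given geometry
psf_sigma_voxels <- function(psf, geometry) {
  c(sigma_xy = psf$sigma_xy / geometry$voxel_nm[3],
    sigma_z = psf$sigma_z / geometry$voxel_nm[1])
}

#' Camera noise model
#'
#' Standard sCMOS-class model: Poisson shot noise on (signal + background)
#' photoelectrons, scaled by a gain, plus additive Gaussian read noise.
#' `gain = 0` disables shot noise entirely, which makes renders
#' deterministic up to read noise (and fully deterministic when
#' `read_sigma = 0` too) — used by the noiseless test scenes.
#'
#' @param background constant background offset, counts.
#' @param gain counts per photoelectron; drives the shot-noise variance
#'   (`var = gain * expected_counts`). 0 disables shot noise.
#' @param read_sigma Gaussian read noise standard deviation, counts.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(background = 50, gain = 1, read_sigma = 2) {
  stopifnot(background >= 0, gain >= 0, read_sigma >= 0)
  structure(list(background = background, gain = gain,
                 read_sigma = read_sigma), class = "noise_model")
}

#' Noise-free camera model (for deterministic scenes)
#' @param background background offset, counts.
#' @return A `noise_model` with shot and read noise disabled.
#' @export
no_noise <- function(background = 50) {
  noise_model(background = background, gain = 0, read_sigma = 0)
}
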