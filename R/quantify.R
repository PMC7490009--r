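#' @title Single-peptide calibration and nascent-chain counting
#' @name quantification
#' @description
#' The protein channel is quantified in units of one released, fully
#' synthesized SunTag polypeptide: free single peptides in the cytoplasm
#' are selected (away from any mRNA), robustly averaged into the idealized
#' single-peptide integrated intensity `I_single`, and each mRNA's
#' translation site is then fit inside an 11 x 11 lateral box and expressed
#' as a nascent-chain count `N = I_ts / I_single`. A site whose fit fails
#' any shape, amplitude, or distance filter carries `I_ts = 0`; mRNAs with
#' `N < 1` are classified as unassociated with SunTag signal.
NULL

#' Select free single-peptide spots
#'
#' Keeps protein-channel spots whose fitted centers lie inside the
#' cytoplasm mask and farther (laterally) than `exclusion_radius_nm` from
#' every mRNA spot, so translation sites never contaminate the calibration.
#'
#' @param protein_spots data.frame of fitted protein-channel spots.
#' @param mrna_spots data.frame of fitted mRNA-channel spots (may be empty).
#' @param cyto_mask logical `(n_y, n_x)` cytoplasm mask.
#' @param exclusion_radius_nm minimum lateral distance to any mRNA, nm.
#' @param pixel_nm lateral pixel size, nm.
#' @return The retained subset of `protein_spots`.
#' @export
select_free_peptides <- function(protein_spots, mrna_spots, cyto_mask,
                                 exclusion_radius_nm = 500,
                                 pixel_nm = 107.5) {
  if (nrow(protein_spots) == 0) return(protein_spots)
  yi <- pmin(pmax(round(protein_spots$y0), 1), nrow(cyto_mask))
  xi <- pmin(pmax(round(protein_spots$x0), 1), ncol(cyto_mask))
  in_cyto <- cyto_mask[cbind(yi, xi)] &
    round(protein_spots$y0) >= 1 & round(protein_spots$y0) <= nrow(cyto_mask) &
    round(protein_spots$x0) >= 1 & round(protein_spots$x0) <= ncol(cyto_mask)
  if (nrow(mrna_spots) == 0) return(protein_spots[in_cyto, , drop = FALSE])
  r_px <- exclusion_radius_nm / pixel_nm
  far <- vapply(seq_len(nrow(protein_spots)), function(i) {
    d2 <- (mrna_spots$y0 - protein_spots$y0[i])^2 +
      (mrna_spots$x0 - protein_spots$x0[i])^2
    min(d2) > r_px^2
  }, logical(1))
  protein_spots[in_cyto & far, , drop = FALSE]
}

#' Calibrate the single-peptide intensity unit
#'
#' Robustly averages free-peptide integrated intensities: spots outside
#' median +/- 3 MAD in `I_int`, `sigma_xy`, or `sigma_z` are dropped (an
#' automated stand-in for manual inspection of single-peptide fits), and
#' `I_single` is the mean `I_int` of the survivors.
#'
#' @param free_spots data.frame of free-peptide spots.
#' @param min_spots minimum surviving spots required.
#' @return An object of class `single_peptide_calibration`: `I_single`,
#'   `n_spots_used`, `cv`, and the survivors' median widths
#'   `sigma_xy`, `sigma_z` (voxels), used later as site shape references.
#' @export
calibrate_single_peptide <- function(free_spots, min_spots = 5) {
  n <- if (is.null(free_spots)) 0L else nrow(free_spots)
  if (n < min_spots)
    stop("single-peptide calibration failed: ", n,
         " candidate spot(s), need at least ", min_spots)
  keep <- rep(TRUE, n)
  for (col in c("I_int", "sigma_xy", "sigma_z")) {
    v <- free_spots[[col]]
    med <- stats::median(v)
    # floor the band at numerical precision so near-identical noiseless
    # fits are never trimmed on float dust; zero MAD disables the trim
    lim <- max(3 * stats::mad(v), 1e-6 * abs(med))
    if (lim > 0) keep <- keep & abs(v - med) <= lim
  }
  surv <- free_spots[keep, , drop = FALSE]
  if (nrow(surv) < min_spots)
    stop("single-peptide calibration failed: only ", nrow(surv),
         " spot(s) survive robust filtering, need at least ", min_spots)
  i_single <- mean(surv$I_int)
  structure(list(
    I_single = i_single,
    n_spots_used = nrow(surv),
    cv = stats::sd(surv$I_int) / i_single,
    sigma_xy = stats::median(surv$sigma_xy),
    sigma_z = stats::median(surv$sigma_z)
  ), class = "single_peptide_calibration")
}

#' Site-fit acceptance parameters
#'
#' @param box_xy lateral bounding-box side, pixels (odd).
#' @param z_halfwidth axial search half-extent around the mRNA's plane.
#' @param max_distance_px maximum fitted-center-to-mRNA lateral distance.
#' @param sigma_factor allowed widths relative to the calibration spots'
#'   median widths, `c(lower, upper)` multipliers.
#' @return A named list of parameters.
#' @export
site_fit_params <- function(box_xy = 11, z_halfwidth = 2,
                            max_distance_px = 3,
                            sigma_factor = c(0.5, 3)) {
  list(box_xy = box_xy, z_halfwidth = z_halfwidth,
       max_distance_px = max_distance_px, sigma_factor = sigma_factor)
}

#' Quantify the translation site of one mRNA
#'
#' Draws a `box_xy` x `box_xy` lateral box at the mRNA position spanning
#' `z_halfwidth` planes either side of the mRNA's plane, locates the
#' brightest protein-channel voxel inside it, and fits a 3D Gaussian
#' seeded there. The site passes only if the fit converges with positive
#' amplitude, widths within `sigma_factor` of the calibration medians, and
#' a fitted center within `max_distance_px` of the mRNA; any failure sets
#' the site intensity to 0. The nascent-chain count is
#' `N = I_ts / I_single`.
#'
#' @param protein_stack the protein-channel [image_stack()].
#' @param mrna_spot one-row data.frame of a fitted mRNA spot.
#' @param cal a [calibrate_single_peptide()] result.
#' @param params a [site_fit_params()] list.
#' @return One-row data.frame: `mrna_id` (if present on the spot), site
#'   intensity `I_ts`, `N`, lateral `distance_px`, and `associated`.
#' @export
quantify_translation_site <- function(protein_stack, mrna_spot, cal,
                                      params = site_fit_params()) {
  stopifnot(inherits(cal, "single_peptide_calibration"))
  a <- as_stack_array(protein_stack)
  d <- dim(a)
  h <- (params$box_xy - 1) / 2
  mz <- pmin(pmax(round(mrna_spot$z0), 1), d[1])
  my <- pmin(pmax(round(mrna_spot$y0), 1), d[2])
  mx <- pmin(pmax(round(mrna_spot$x0), 1), d[3])
  zr <- max(1, mz - params$z_halfwidth):min(d[1], mz + params$z_halfwidth)
  yr <- max(1, my - h):min(d[2], my + h)
  xr <- max(1, mx - h):min(d[3], mx + h)
  box <- a[zr, yr, xr, drop = FALSE]
  top <- which(box == max(box), arr.ind = TRUE)[1, , drop = TRUE]
  peak <- list(z = zr[top[1]], y = yr[top[2]], x = xr[top[3]])
  fit <- fit_spot(a, peak,
                  window = c(length(zr), params$box_xy, params$box_xy))
  id <- if (!is.null(mrna_spot$mrna_id)) mrna_spot$mrna_id else NA_integer_
  dist_px <- sqrt((fit$y0 - mrna_spot$y0)^2 + (fit$x0 - mrna_spot$x0)^2)
  sig_ok <- !is.na(fit$sigma_xy) &&
    fit$sigma_xy >= params$sigma_factor[1] * cal$sigma_xy &&
    fit$sigma_xy <= params$sigma_factor[2] * cal$sigma_xy &&
    fit$sigma_z >= params$sigma_factor[1] * cal$sigma_z &&
    fit$sigma_z <= params$sigma_factor[2] * cal$sigma_z
  ok <- isTRUE(fit$pass) && sig_ok && !is.na(dist_px) &&
    dist_px <= params$max_distance_px && fit$A > 0
  i_ts <- if (ok) max(fit$I_int, 0) else 0
  site <- data.frame(
    mrna_id = id,
    I_ts = i_ts,
    N = i_ts / cal$I_single,
    distance_px = if (is.na(dist_px)) NA_real_ else dist_px,
    associated = NA
  )
  site$associated <- classify_association(site)
  site
}

#' Classify association of a quantified site
#'
#' An mRNA is associated with SunTag signal when its site carries at least
#' one idealized single peptide of intensity (`N >= 1`); sites below one
#' peptide, including failed fits with `I_ts = 0`, are unassociated.
#'
#' @param site one-row data.frame with an `N` column (or a numeric `N`).
#' @return Logical flag.
#' @export
classify_association <- function(site) {
  n <- if (is.data.frame(site) || is.list(site)) site$N else site
  !is.na(n) & n >= 1
}
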