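#' @title Spot detection and 3D Gaussian fitting
#' @name spot_detection
#' @description
#' Diffraction-limited spots are detected per channel by a
#' Laplacian-of-Gaussian (LoG) bandpass tuned to the PSF scale, thresholded
#' at a robust (median + k * MAD) level over the filtered stack, and each
#' candidate is refined by a nonlinear least-squares fit of an anisotropic
#' 3D Gaussian, `A * exp(-((x-x0)^2+(y-y0)^2)/(2*sxy^2) -
#' (z-z0)^2/(2*sz^2)) + B`. The background-subtracted integrated intensity
#' of a passing spot is `A * (2*pi)^(3/2) * sxy^2 * sz` (voxel units).
NULL

as_stack_array <- function(stack) {
  if (inherits(stack, "image_stack")) stack$data
  else if (is.array(stack) && length(dim(stack)) == 3) stack
  else stop("expected an image_stack or a 3D array")
}

# Separable Gaussian blur along one axis via a row-normalized banded
# operator; edge rows renormalize the truncated kernel so constants are
# preserved exactly.
blur_axis <- function(a, sigma, axis) {
  if (sigma <= 0.05) return(a)
  n <- dim(a)[axis]
  r <- min(n - 1L, as.integer(ceiling(3 * sigma)))
  off <- -r:r
  w <- exp(-off^2 / (2 * sigma^2))
  K <- matrix(0, n, n)
  for (j in seq_along(off)) {
    i <- seq_len(n)
    jj <- i + off[j]
    keep <- jj >= 1 & jj <= n
    K[cbind(i[keep], jj[keep])] <- K[cbind(i[keep], jj[keep])] + w[j]
  }
  K <- K / rowSums(K)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  m <- matrix(ap, nrow = n)
  out <- array(K %*% m, dim = dim(ap))
  aperm(out, order(perm))
}

# Shift a 3D array by (dz, dy, dx); out-of-range entries get `fill`
# ("replicate" clamps to the edge instead).
shift_array <- function(a, dz, dy, dx, fill = -Inf) {
  d <- dim(a)
  idx <- function(n, s) {
    i <- seq_len(n) + s
    if (identical(fill, "replicate")) pmin(pmax(i, 1L), n) else i
  }
  zi <- idx(d[1], dz); yi <- idx(d[2], dy); xi <- idx(d[3], dx)
  if (identical(fill, "replicate")) return(a[zi, yi, xi, drop = FALSE])
  out <- array(fill, dim = d)
  okz <- zi >= 1 & zi <= d[1]; oky <- yi >= 1 & yi <= d[2]
  okx <- xi >= 1 & xi <= d[3]
  out[okz, oky, okx] <- a[zi[okz], yi[oky], xi[okx], drop = FALSE]
  out
}

#' Laplacian-of-Gaussian bandpass filter
#'
#' Gaussian-smooths the stack at the PSF scale, then applies a discrete
#' 3D Laplacian with replicated edges, sign-flipped so that bright spots
#' become response maxima. A constant stack maps to an identically zero
#' response.
#'
#' @param stack an [image_stack()] or 3D array.
#' @param sigma_xy,sigma_z smoothing scale in voxel units (typically the
#'   PSF widths; see [psf_sigma_voxels()]-style conversion).
#' @return An `image_stack` of filter responses, same shape as the input.
#' @export
bandpass_filter <- function(stack, sigma_xy = 1, sigma_z = 1.2) {
  stopifnot(sigma_xy > 0, sigma_z > 0)
  a <- as_stack_array(stack)
  sm <- blur_axis(blur_axis(blur_axis(a, sigma_z, 1), sigma_xy, 2),
                  sigma_xy, 3)
  lap <- (shift_array(sm, 1, 0, 0, "replicate") +
            shift_array(sm, -1, 0, 0, "replicate") +
            shift_array(sm, 0, 1, 0, "replicate") +
            shift_array(sm, 0, -1, 0, "replicate") +
            shift_array(sm, 0, 0, 1, "replicate") +
            shift_array(sm, 0, 0, -1, "replicate") - 6 * sm)
  res <- -lap
  # snap float dust to exactly zero (constant regions of noiseless data
  # otherwise carry ~1e-13 ripple that would register as local maxima)
  res[abs(res) < 1e-10 * max(abs(a))] <- 0
  voxel_nm <- if (inherits(stack, "image_stack")) stack$voxel_nm
  else c(300, 107.5, 107.5)
  image_stack(res, voxel_nm)
}

#' Detect candidate peaks in a filtered stack
#'
#' Candidates are strict local maxima over 3x3x3 neighborhoods with
#' response above `median + k_mad * MAD` of the whole filtered stack (plus
#' a relative epsilon of the response range, which keeps float-level ripple
#' on exactly-flat noiseless data below threshold). On plateaus of exactly
#' equal response the lowest `(z, y, x)` voxel wins. The returned table is
#' sorted by decreasing response.
#'
#' @param filtered output of [bandpass_filter()].
#' @param k_mad robust threshold multiplier.
#' @return data.frame with integer voxel coordinates `z, y, x` and
#'   `response`; zero rows when nothing exceeds threshold.
#' @export
detect_candidates <- function(filtered, k_mad = 6) {
  stopifnot(k_mad > 0)
  a <- as_stack_array(filtered)
  rng <- range(a)
  thr <- stats::median(a) + k_mad * stats::mad(a) +
    1e-9 * max(rng[2] - rng[1], 0)
  ok <- a > thr
  if (any(ok)) {
    offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
    offs <- offs[!(offs$dz == 0 & offs$dy == 0 & offs$dx == 0), ]
    for (i in seq_len(nrow(offs))) {
      d <- offs[i, ]
      nb <- shift_array(a, d$dz, d$dy, d$dx, fill = -Inf)
      # neighbor at a lexicographically smaller position must be strictly
      # beaten; larger positions only tied-or-beaten (lowest index wins)
      lex_neg <- d$dz < 0 || (d$dz == 0 && (d$dy < 0 ||
                                              (d$dy == 0 && d$dx < 0)))
      ok <- ok & (if (lex_neg) a > nb else a >= nb)
      if (!any(ok)) break
    }
  }
  w <- which(ok, arr.ind = TRUE)
  out <- data.frame(z = w[, 1], y = w[, 2], x = w[, 3],
                    response = a[w])
  out[order(-out$response, out$z, out$y, out$x), , drop = FALSE]
}

gauss3d_model <- function(par, zg, yg, xg) {
  gz <- exp(-(zg - par[3])^2 / (2 * par[7]^2))
  gy <- exp(-(yg - par[4])^2 / (2 * par[6]^2))
  gx <- exp(-(xg - par[5])^2 / (2 * par[6]^2))
  par[2] + par[1] * outer(gz, outer(gy, gx))
}

#' Fit a 3D Gaussian to one candidate peak
#'
#' Levenberg-Marquardt least squares of an anisotropic 3D Gaussian plus
#' constant background over a window centered on the candidate voxel
#' (clamped to the stack). Non-convergence, non-positive amplitude, a
#' fitted center leaving the window, or a width pinned at its bound set
#' the `pass = FALSE` flag.
#'
#' @param stack an [image_stack()] or 3D array.
#' @param peak list/row with integer `z, y, x` of the candidate.
#' @param window odd voxel extents `c(wz, wy, wx)`; default `c(5, 11, 11)`
#'   matches an 11 x 11 lateral box with the coarser axial sampling.
#' @param sigma_init initial widths `c(sigma_xy, sigma_z)` in voxels.
#' @param sigma_max upper bound on fitted widths, voxels.
#' @return One-row data.frame: window-center voxel, fitted `z0, y0, x0`
#'   (voxel units), `A`, `B`, `sigma_xy`, `sigma_z`, integrated intensity
#'   `I_int = A * (2*pi)^(3/2) * sigma_xy^2 * sigma_z`, residual norm
#'   `rss`, and `pass`.
#' @export
fit_spot <- function(stack, peak, window = c(5, 11, 11),
                     sigma_init = c(1, 1.2), sigma_max = 5) {
  a <- as_stack_array(stack)
  d <- dim(a)
  pz <- round(peak$z); py <- round(peak$y); px <- round(peak$x)
  if (pz < 1 || pz > d[1] || py < 1 || py > d[2] || px < 1 || px > d[3])
    stop("candidate peak lies outside the stack")
  h <- (window - 1) / 2
  zr <- max(1, pz - h[1]):min(d[1], pz + h[1])
  yr <- max(1, py - h[2]):min(d[2], py + h[2])
  xr <- max(1, px - h[3]):min(d[3], px + h[3])
  wd <- a[zr, yr, xr, drop = FALSE]
  B0 <- stats::median(wd)
  A0 <- max(wd) - B0
  par0 <- c(A = max(A0, 1e-3), B = B0, z0 = pz, y0 = py, x0 = px,
            sxy = sigma_init[1], sz = sigma_init[2])
  lower <- c(0, -Inf, min(zr) - 0.5, min(yr) - 0.5, min(xr) - 0.5,
             0.2, 0.2)
  upper <- c(Inf, Inf, max(zr) + 0.5, max(yr) + 0.5, max(xr) + 0.5,
             sigma_max, sigma_max)
  resid_fn <- function(p) as.vector(gauss3d_model(p, zr, yr, xr) - wd)
  fit <- tryCatch(
    minpack.lm::nls.lm(par0, lower, upper, fn = resid_fn,
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  out <- data.frame(peak_z = pz, peak_y = py, peak_x = px,
                    z0 = NA_real_, y0 = NA_real_, x0 = NA_real_,
                    A = NA_real_, B = NA_real_,
                    sigma_xy = NA_real_, sigma_z = NA_real_,
                    I_int = NA_real_, rss = NA_real_, pass = FALSE)
  if (is.null(fit)) return(out)
  p <- fit$par
  out$z0 <- p[3]; out$y0 <- p[4]; out$x0 <- p[5]
  out$A <- p[1]; out$B <- p[2]
  out$sigma_xy <- p[6]; out$sigma_z <- p[7]
  out$I_int <- p[1] * (2 * pi)^1.5 * p[6]^2 * p[7]
  out$rss <- sqrt(sum(fit$fvec^2))
  converged <- fit$info %in% 1:4
  in_window <- p[3] > min(zr) - 0.5 && p[3] < max(zr) + 0.5 &&
    p[4] > min(yr) - 0.5 && p[4] < max(yr) + 0.5 &&
    p[5] > min(xr) - 0.5 && p[5] < max(xr) + 0.5
  sane_sigma <- p[6] < sigma_max - 1e-6 && p[7] < sigma_max - 1e-6 &&
    p[6] > 0.2 + 1e-6 && p[7] > 0.2 + 1e-6
  out$pass <- converged && p[1] > 1e-8 && in_window && sane_sigma
  out
}

#' Quality bounds for spot filtering
#'
#' @param amplitude,sigma_xy,sigma_z,intensity two-element `c(min, max)`
#'   vectors; widths in voxel units, amplitude/intensity in counts.
#' @return A named list of bounds.
#' @export
quality_bounds <- function(amplitude = c(0, Inf),
                           sigma_xy = c(0.4, 3),
                           sigma_z = c(0.4, 4),
                           intensity = c(0, Inf)) {
  list(amplitude = amplitude, sigma_xy = sigma_xy, sigma_z = sigma_z,
       intensity = intensity)
}

#' Filter fitted spots on quality bounds
#'
#' Keeps only pass-flagged spots whose amplitude, widths and integrated
#' intensity fall within the bounds; input order is preserved.
#'
#' @param spots data.frame of fitted spots (rows from [fit_spot()]).
#' @param bounds a [quality_bounds()] list.
#' @return The retained subset, same columns and order.
#' @export
filter_spots <- function(spots, bounds = quality_bounds()) {
  if (nrow(spots) == 0) return(spots)
  keep <- spots$pass &
    spots$A >= bounds$amplitude[1] & spots$A <= bounds$amplitude[2] &
    spots$sigma_xy >= bounds$sigma_xy[1] &
    spots$sigma_xy <= bounds$sigma_xy[2] &
    spots$sigma_z >= bounds$sigma_z[1] &
    spots$sigma_z <= bounds$sigma_z[2] &
    spots$I_int >= bounds$intensity[1] & spots$I_int <= bounds$intensity[2]
  spots[keep, , drop = FALSE]
}

#' Detect and fit all spots in one channel
#'
#' Convenience wrapper: LoG bandpass at the PSF scale, robust candidate
#' thresholding, per-candidate Gaussian fits, quality filtering, and a
#' final merge of duplicate fits that converged onto the same emitter
#' (centers within 2 px laterally and 1.5 planes axially keep only the
#' brighter fit).
#'
#' @param stack an [image_stack()].
#' @param sigma_xy,sigma_z PSF scale in voxel units.
#' @param k_mad detection threshold multiplier.
#' @param window fit window extents, see [fit_spot()].
#' @param bounds a [quality_bounds()] list.
#' @return data.frame of passing spots sorted by decreasing `I_int`.
#' @export
detect_spots <- function(stack, sigma_xy = 1, sigma_z = 1.2, k_mad = 6,
                         window = c(5, 11, 11),
                         bounds = quality_bounds()) {
  filt <- bandpass_filter(stack, sigma_xy, sigma_z)
  cand <- detect_candidates(filt, k_mad)
  if (nrow(cand) == 0) return(empty_spot_table())
  fits <- do.call(rbind, lapply(seq_len(nrow(cand)), function(i)
    fit_spot(stack, cand[i, ], window)))
  spots <- filter_spots(fits, bounds)
  if (nrow(spots) <= 1) return(spots)
  spots <- spots[order(-spots$I_int), , drop = FALSE]
  keep <- rep(TRUE, nrow(spots))
  for (i in seq_len(nrow(spots))[-1]) {
    prev <- which(keep[seq_len(i - 1)])
    dxy2 <- (spots$y0[prev] - spots$y0[i])^2 +
      (spots$x0[prev] - spots$x0[i])^2
    dz <- abs(spots$z0[prev] - spots$z0[i])
    if (any(dxy2 < 4 & dz < 1.5)) keep[i] <- FALSE
  }
  spots[keep, , drop = FALSE]
}

empty_spot_table <- function() {
  data.frame(peak_z = integer(0), peak_y = integer(0), peak_x = integer(0),
             z0 = numeric(0), y0 = numeric(0), x0 = numeric(0),
             A = numeric(0), B = numeric(0),
             sigma_xy = numeric(0), sigma_z = numeric(0),
             I_int = numeric(0), rss = numeric(0), pass = logical(0))
}
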