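#' @title Diffusion spatial-resolution calculator
#' @name diffusion
#' @description
#' Free diffusion in `n` dimensions obeys the mean-squared-displacement
#' relation `<x^2> = 2 n D t`. These helpers convert between time and RMS
#' displacement for a cytosolic protein; the default diffusion coefficient
#' of 126 um^2/s is the measured cytosolic GFP value, under which a
#' released protein is expected to travel ~100 um (1D RMS) in well under a
#' minute — the scale argument for why short metabolic-labeling pulses
#' cannot localize translation.
NULL

#' RMS displacement after time t
#'
#' @param D diffusion coefficient, um^2/s.
#' @param n dimensionality, 1, 2 or 3.
#' @param t time, s (vectorized).
#' @return `sqrt(2 n D t)`, um.
#' @export
rms_displacement <- function(D = 126, n = 1, t) {
  stopifnot(D > 0, n %in% 1:3, all(t >= 0))
  sqrt(2 * n * D * t)
}

#' Time to reach an RMS displacement
#'
#' Exact inverse of [rms_displacement()]: `t = x^2 / (2 n D)`.
#'
#' @param D diffusion coefficient, um^2/s.
#' @param n dimensionality, 1, 2 or 3.
#' @param x RMS displacement, um (vectorized).
#' @return Time, s.
#' @export
time_to_reach <- function(D = 126, n = 1, x) {
  stopifnot(D > 0, n %in% 1:3, all(x >= 0))
  x^2 / (2 * n * D)
}

#' RMS displacement curves for n = 1, 2, 3
#'
#' @param D diffusion coefficient, um^2/s.
#' @param t_grid nondecreasing, nonnegative time grid, s.
#' @return data.frame with columns `t`, `n`, `displacement_um` (long
#'   format, one block per dimensionality).
#' @export
displacement_curve <- function(D = 126, t_grid) {
  stopifnot(all(t_grid >= 0), !is.unsorted(t_grid))
  do.call(rbind, lapply(1:3, function(n)
    data.frame(t = t_grid, n = n,
               displacement_um = rms_displacement(D, n, t_grid))))
}
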