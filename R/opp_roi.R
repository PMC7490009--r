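#' @title ROI quantification of metabolic-labeling images
#' @name opp_roi_quant
#' @description
#' Quantification of OPP (O-propargyl-puromycin) click-labeling signal in
#' germline images: average-intensity z-projection, mean fluorescence over
#' a hand-drawn polygonal ROI, and normalization of every sample to the
#' mean of the control ("OPP alone") group, whose normalized values
#' therefore average to exactly 1. Groups are compared with the unpaired
#' t-test from [two_sample_ttest()].
NULL

#' Average-intensity z-projection
#'
#' @param stack an [image_stack()] or 3D array `(z, y, x)`.
#' @return A `(n_y, n_x)` matrix of per-pixel means across z.
#' @export
average_projection <- function(stack) {
  a <- as_stack_array(stack)
  colMeans(a, dims = 1)
}

#' Point-in-polygon test (even-odd rule)
#'
#' Ray-casting along +x; points exactly on edges follow the half-open
#' crossing convention. Vectorized over query points.
#'
#' @param px,py numeric vectors of query coordinates.
#' @param poly two-column matrix of polygon vertices `(x, y)`, implicitly
#'   closed.
#' @return Logical vector.
#' @export
point_in_polygon <- function(px, py, poly) {
  poly <- as.matrix(poly)
  stopifnot(ncol(poly) == 2, nrow(poly) >= 3)
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Mean intensity over a polygonal ROI
#'
#' Pixel membership is by pixel-center containment under the even-odd
#' rule; pixel `(row, col)` has its center at `(x = col, y = row)` in the
#' polygon's coordinate frame.
#'
#' @param image 2D numeric matrix (e.g. an [average_projection()]).
#' @param roi two-column matrix of polygon vertices `(x, y)` in pixel
#'   coordinates.
#' @return Mean intensity over covered pixels.
#' @export
roi_mean <- function(image, roi) {
  roi <- as.matrix(roi)
  if (nrow(roi) < 3) stop("ROI polygon needs at least 3 vertices")
  # only test pixels inside the polygon's bounding box
  rows <- max(1, floor(min(roi[, 2]))):min(nrow(image), ceiling(max(roi[, 2])))
  cols <- max(1, floor(min(roi[, 1]))):min(ncol(image), ceiling(max(roi[, 1])))
  if (length(rows) == 0 || length(cols) == 0)
    stop("ROI polygon covers zero pixels")
  py <- rep(rows, times = length(cols))
  px <- rep(cols, each = length(rows))
  inside <- point_in_polygon(px, py, roi)
  if (!any(inside)) stop("ROI polygon covers zero pixels")
  mean(image[cbind(py[inside], px[inside])])
}

#' Normalize ROI measurements to a control group
#'
#' Divides every ROI mean by the mean of the control group's ROI means, so
#' the control group's normalized values average to exactly 1 and a global
#' intensity rescaling (e.g. an exposure change) cancels.
#'
#' @param values data.frame with columns `sample_id`, `group`, `roi_mean`.
#' @param control_group name of the control group.
#' @return The input with a `normalized` column appended.
#' @export
normalize_to_control <- function(values, control_group) {
  ctrl <- values$roi_mean[values$group == control_group]
  if (length(ctrl) == 0)
    stop("control group '", control_group, "' is empty")
  values$normalized <- values$roi_mean / mean(ctrl)
  values
}
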