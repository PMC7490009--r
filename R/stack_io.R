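#' Single-channel 3D image stack
#'
#' A thin container: a numeric array in `(z, y, x)` axis order plus the
#' physical voxel size. Voxel indices are 1-based and continuous spot
#' coordinates refer to voxel centers (voxel `i` spans `i - 0.5` to
#' `i + 0.5`).
#'
#' @param data numeric 3D array, dim `(n_z, n_y, n_x)`.
#' @param voxel_nm numeric `c(dz, dy, dx)` in nm.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(data, voxel_nm = c(300, 107.5, 107.5)) {
  stopifnot(is.array(data), length(dim(data)) == 3,
            length(voxel_nm) == 3, all(voxel_nm > 0))
  structure(list(data = data, voxel_nm = as.numeric(voxel_nm)),
            class = "image_stack")
}

#' @export
dim.image_stack <- function(x) dim(x$data)

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("image_stack: %d x %d x %d voxels (z,y,x), %g/%g nm\n",
              d[1], d[2], d[3], x$voxel_nm[1], x$voxel_nm[2]))
  invisible(x)
}

#' Write / read a stack as 16-bit multi-page TIFF
#'
#' One page per z-plane, unsigned 16-bit, values clipped to \[0, 65535\] and
#' rounded (the camera-count convention). Voxel sizes travel in a JSON
#' sidecar `<path>.meta.json`; the voxel round trip is bit-exact for
#' integer-valued data in range.
#'
#' @param stack an [image_stack()].
#' @param path TIFF file path.
#' @return `write_stack` returns `path` invisibly; `read_stack` returns an
#'   `image_stack`.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$data)
  pages <- lapply(seq_len(d[1]), function(z) {
    pmin(pmax(round(stack$data[z, , ]), 0), 65535) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  jsonlite::write_json(list(voxel_nm = stack$voxel_nm, dim = d),
                       paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop("no such TIFF file: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = FALSE),
                    error = function(e)
                      stop("cannot read TIFF file '", path, "': ",
                           conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  d <- c(length(pages), dim(pages[[1]]))
  arr <- array(0, dim = d)
  for (z in seq_len(d[1])) arr[z, , ] <- round(pages[[z]] * 65535)
  voxel_nm <- c(300, 107.5, 107.5)
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    if (!is.null(meta$voxel_nm)) voxel_nm <- as.numeric(meta$voxel_nm)
  }
  image_stack(arr, voxel_nm)
}
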