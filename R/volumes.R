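#' Membrane probability volume
#'
#' Wraps a 3D scalar grid of per-voxel membrane probabilities together with the
#' physical voxel dimensions. Values must lie in `[0, 1]`; anisotropic voxels
#' are allowed (e.g. 162.5 nm in-plane, 500 nm between planes), but all
#' synthetic fixtures in this package are isotropic with `voxel_size = 1`, so
#' downstream lengths are then in voxel units.
#'
#' Voxel `(i, j, k)` (1-based) has its centre at physical coordinate
#' `(i - 0.5, j - 0.5, k - 0.5) * voxel_size`.
#'
#' @param data 3D numeric array with values in `[0, 1]`.
#' @param voxel_size positive numeric of length 1 or 3; physical edge lengths
#'   of a voxel along x, y, z.
#' @return A `prob_volume` object.
#' @export
prob_volume <- function(data, voxel_size = c(1, 1, 1)) {
  if (length(dim(data)) != 3) {
    abort("`data` must be a 3D array")
  }
  if (length(voxel_size) == 1) voxel_size <- rep(voxel_size, 3)
  if (length(voxel_size) != 3 || any(!is.finite(voxel_size)) || any(voxel_size <= 0)) {
    abort("`voxel_size` must be three positive finite numbers")
  }
  rng <- range(data)
  if (rng[1] < 0 || rng[2] > 1) {
    abort("probability values must lie within [0, 1]")
  }
  structure(
    list(data = data, voxel_size = as.numeric(voxel_size)),
    class = "prob_volume"
  )
}

#' @export
print.prob_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<prob_volume> %d x %d x %d voxels, voxel_size = (%g, %g, %g)\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

#' @export
dim.prob_volume <- function(x) dim(x$data)

#' Read / write single-channel volumes as multi-page TIFF
#'
#' `read_volume_tiff()` stacks the pages of a grayscale TIFF into a 3D array
#' (page rows become x, columns y, pages z) and rescales integer data to
#' `[0, 1]`. `write_volume_tiff()` writes a volume or a label array; label
#' arrays are stored as 16-bit.
#'
#' @param path file path.
#' @param voxel_size physical voxel dimensions to attach (not stored in TIFF
#'   tags by this writer).
#' @return `read_volume_tiff()` returns a [prob_volume()].
#' @export
read_volume_tiff <- function(path, voxel_size = c(1, 1, 1)) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort("reading TIFF volumes requires the 'tiff' package")
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- vapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]
    t(p)
  }, matrix(0, ncol(pages[[1]]), nrow(pages[[1]])))
  prob_volume(arr, voxel_size = voxel_size)
}

#' @rdname read_volume_tiff
#' @param x a [prob_volume()] or 3D numeric/integer array.
#' @export
write_volume_tiff <- function(x, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort("writing TIFF volumes requires the 'tiff' package")
  }
  arr <- if (inherits(x, "prob_volume")) x$data else x
  is_label <- is.integer(arr) || all(arr == round(arr))
  nz <- dim(arr)[3]
  scale <- if (is_label) max(1, max(arr)) else 1
  pages <- lapply(seq_len(nz), function(k) t(arr[, , k]) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}
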