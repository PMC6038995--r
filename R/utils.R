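#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data abort warn inform `%||%`
#' @importFrom stats sd setNames
#' @useDynLib embryoforce, .registration = TRUE
NULL

# unit-normalise rows of a matrix (or a single vector)
unitize <- function(v) {
  if (is.matrix(v)) {
    n <- sqrt(rowSums(v^2))
    v / n
  } else {
    v / sqrt(sum(v^2))
  }
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# physical coordinates of voxel centres ((index - 1) + 0.5) * voxel_size
voxel_to_physical <- function(ijk, voxel_size) {
  sweep(ijk - 0.5, 2, voxel_size, `*`)
}

physical_to_voxel <- function(xyz, voxel_size, dim) {
  ijk <- sweep(xyz, 2, voxel_size, `/`)
  ijk <- floor(ijk) + 1L
  for (a in 1:3) ijk[, a] <- pmin(pmax(ijk[, a], 1L), dim[a])
  ijk
}

as_xyz_matrix <- function(x, cols = c("x", "y", "z")) {
  if (is.matrix(x)) {
    stopifnot(ncol(x) == 3)
    m <- x
  } else {
    m <- as.matrix(x[, cols])
  }
  storage.mode(m) <- "double"
  dimnames(m) <- NULL
  m
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi
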