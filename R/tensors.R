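#' Per-point surface area weights of a membrane cloud
#'
#' Mesh-free clouds carry no intrinsic area element; each point is assigned
#' the area of the disk spanned by its `k` nearest same-face neighbours,
#' `a_i = pi r_k^2 / k`. On a uniformly sampled smooth surface this estimates
#' the local inverse point density without orientation bias.
#'
#' @param cloud membrane cloud with `face`, `x`, `y`, `z`.
#' @param k neighbourhood size of the density estimate.
#' @return The cloud with an `area` column (physical units squared).
#' @export
point_area_weights <- function(cloud, k = 16) {
  out <- cloud
  out$area <- NA_real_
  for (rows in split(seq_len(nrow(cloud)), cloud$face)) {
    pts <- as_xyz_matrix(cloud[rows, ])
    kk <- min(k, nrow(pts) - 1)
    if (kk < 1) {
      out$area[rows] <- 1
      next
    }
    nn <- cpp_knn(pts, pts, kk, TRUE)
    rk <- nn$dist[, kk]
    out$area[rows] <- pi * rk^2 / kk
  }
  out
}

#' Cell-averaged stress tensors
#'
#' Integrates the interfacial traction over each cell's membranes and divides
#' by the cell volume:
#' `sigma = -(P_c - P_b) I + (1/V) sum_k T_k int_face (I - n n^T) dS`,
#' the pressure part plus the tension of each face times its tangential
#' projector. For a closed cell this is equivalent, by the surface divergence
#' theorem, to the volume-averaged moment of the traction
#' `(1/V) int (r - r0) (x) T(r) dS` with `T(r) = 2 H T n`. The surface
#' integral is discretised with the per-point area weights of
#' [point_area_weights()] (computed on the fly when the cloud lacks an `area`
#' column). Principal directions with negative eigenvalues are compressive.
#'
#' An open (non-watertight) cell surface is detected through its closure
#' defect `|sum a_i n_out| / sum a_i` and reported as a warning.
#'
#' @param fit a `force_fit`.
#' @param cloud curvature-annotated membrane cloud (with normals).
#' @param labels the `cell_labels` (for volumes and centroids).
#' @return A `cell_tensors` tibble: one row per cell with the six unique
#'   components, eigenvalues (descending), eigenvector matrix as a list
#'   column, and the number of compressive directions.
#' @export
cell_stress_tensors <- function(fit, cloud, labels) {
  stopifnot(inherits(fit, "force_fit"), inherits(labels, "cell_labels"))
  if (!"area" %in% names(cloud)) cloud <- point_area_weights(cloud)
  P_b <- fit$system$P_b
  tension <- fit$tensions
  rows <- lapply(seq_len(labels$n_cells), function(cell) {
    p_c <- fit$pressures$pressure[fit$pressures$cell == cell]
    V <- labels$cells$volume[labels$cells$cell == cell]
    sub <- cloud[cloud$cell_i == cell | cloud$cell_j == cell, ]
    sigma <- -(p_c - P_b) * diag(3)
    defect <- c(0, 0, 0)
    total_area <- 0
    for (f in unique(sub$face)) {
      fc <- sub[sub$face == f, ]
      Tk <- tension$tension[tension$face == f]
      nrm <- as.matrix(fc[, c("nx", "ny", "nz")])
      a <- fc$area
      proj_int <- sum(a) * diag(3) - crossprod(nrm * sqrt(a))
      sigma <- sigma + Tk * proj_int / V
      out_sign <- if (fc$cell_i[1] == cell) 1 else -1
      defect <- defect + out_sign * colSums(nrm * a)
      total_area <- total_area + sum(a)
    }
    if (sqrt(sum(defect^2)) > 0.05 * total_area) {
      warn(sprintf("cell %d surface is not closed (defect area %.3g of %.3g)",
                   cell, sqrt(sum(defect^2)), total_area))
    }
    tensor_row(cell, (sigma + t(sigma)) / 2)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("cell_tensors", class(out))
  attr(out, "type") <- "stress"
  out
}

#' Cell shape tensors
#'
#' Area-weighted second moment of the cell's membrane surface about its
#' centroid, rescaled by volume:
#' `tau = (1/V) int (r - r0) (x) (r - r0) dS` (units length^2 when curvature
#' and coordinates are voxel-based times the voxel size). The principal axes
#' resemble those of an ellipsoid fitted to the cell; eigenvalue ratios
#' quantify shape anisotropy. Set `volume_integral = TRUE` for the
#' volume-integrated variant `(1/V) int (r - r0) (x) (r - r0) dV` over the
#' cell's voxels (a true moment-of-inertia-like tensor); the surface form is
#' the default.
#'
#' @param cloud membrane cloud.
#' @param labels the `cell_labels`.
#' @param volume_integral integrate over voxels instead of the surface.
#' @return A `cell_tensors` tibble (see [cell_stress_tensors()]).
#' @export
cell_shape_tensors <- function(cloud, labels, volume_integral = FALSE) {
  stopifnot(inherits(labels, "cell_labels"))
  if (!volume_integral && !"area" %in% names(cloud)) {
    cloud <- point_area_weights(cloud)
  }
  vs <- labels$voxel_size
  rows <- lapply(seq_len(labels$n_cells), function(cell) {
    info <- labels$cells[labels$cells$cell == cell, ]
    r0 <- c(info$x, info$y, info$z)
    V <- info$volume
    if (volume_integral) {
      idx <- which(labels$labels == cell, arr.ind = TRUE)
      pts <- voxel_to_physical(idx, vs)
      rel <- sweep(pts, 2, r0)
      tau <- crossprod(rel) * prod(vs) / V
    } else {
      sub <- cloud[cloud$cell_i == cell | cloud$cell_j == cell, ]
      rel <- sweep(as_xyz_matrix(sub), 2, r0)
      tau <- crossprod(rel * sqrt(sub$area)) / V
    }
    tensor_row(cell, (tau + t(tau)) / 2)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("cell_tensors", class(out))
  attr(out, "type") <- "shape"
  out
}

tensor_row <- function(cell, S) {
  eg <- eigen(S, symmetric = TRUE)
  tibble::tibble(
    cell = cell,
    xx = S[1, 1], yy = S[2, 2], zz = S[3, 3],
    xy = S[1, 2], xz = S[1, 3], yz = S[2, 3],
    e1 = eg$values[1], e2 = eg$values[2], e3 = eg$values[3],
    vectors = list(eg$vectors),
    n_compressive = sum(eg$values < 0)
  )
}
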