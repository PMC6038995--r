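#' Membrane voxels as a mesh-free point cloud
#'
#' Converts the face voxels of a [extract_membrane_faces()] map into physical
#' point coordinates (voxel centres scaled by the voxel size), one row per
#' membrane point, tagged with the owning face and its cell pair.
#'
#' @param face_map a `face_map`.
#' @return Tibble with columns `face`, `cell_i`, `cell_j`, `x`, `y`, `z`.
#' @export
face_point_cloud <- function(face_map) {
  stopifnot(inherits(face_map, "face_map"))
  vs <- face_map$voxel_size
  face_map$voxels |>
    dplyr::transmute(
      .data$face, .data$cell_i, .data$cell_j,
      x = (.data$i - 0.5) * vs[1],
      y = (.data$j - 0.5) * vs[2],
      z = (.data$k - 0.5) * vs[3]
    )
}

#' PCA smoothing and normal estimation of a membrane cloud
#'
#' For each point p the surface normal and a shift along it are estimated
#' jointly by minimising `sum_k ((x_k - (p + t eta)) . eta)^2` over the unit
#' normal `eta` and scalar shift `t`, using the `k` nearest neighbours of p on
#' the same face. The closed-form solution takes `eta` as the
#' smallest-eigenvalue eigenvector of the neighbour covariance about the
#' neighbour centroid and `t = (centroid - p) . eta`; the smoothed position is
#' `p + t eta`. Points whose two smallest covariance eigenvalues coincide
#' (relative gap below `gap_tol`) are flagged `ambiguous` and excluded from
#' curvature averaging downstream.
#'
#' Normals at this stage have arbitrary sign; see [orient_cloud_normals()].
#' If the input already carries normals (`nx`, `ny`, `nz`), the estimated
#' normal keeps the input's hemisphere, which makes the operation equivariant
#' under rigid motions of an oriented cloud.
#'
#' @param cloud tibble with `face`, `x`, `y`, `z` (e.g. [face_point_cloud()]).
#' @param k number of nearest neighbours `K_S` (within the same face).
#' @param gap_tol eigenvalue-gap ratio below which a normal is ambiguous.
#' @return The cloud with smoothed `x`, `y`, `z`, raw positions `x0,y0,z0`,
#'   unit normals `nx,ny,nz`, the `shift` t, and `ambiguous`.
#' @export
smooth_cloud <- function(cloud, k = 50, gap_tol = 1e-6) {
  stopifnot(k >= 4)
  had_normals <- all(c("nx", "ny", "nz") %in% names(cloud))
  by_face <- split(seq_len(nrow(cloud)), cloud$face)
  out <- cloud
  out$x0 <- cloud$x; out$y0 <- cloud$y; out$z0 <- cloud$z
  out$nx <- out$ny <- out$nz <- out$shift <- NA_real_
  out$ambiguous <- NA
  for (rows in by_face) {
    pts <- as_xyz_matrix(cloud[rows, ])
    res <- cpp_smooth_normals(pts, min(k, nrow(pts) - 1), gap_tol)
    nrm <- res$normal
    if (had_normals) {
      prev <- as.matrix(cloud[rows, c("nx", "ny", "nz")])
      flip <- rowSums(nrm * prev) < 0
      nrm[flip, ] <- -nrm[flip, ]
    }
    out$x[rows] <- res$smoothed[, 1]
    out$y[rows] <- res$smoothed[, 2]
    out$z[rows] <- res$smoothed[, 3]
    out$nx[rows] <- nrm[, 1]
    out$ny[rows] <- nrm[, 2]
    out$nz[rows] <- nrm[, 3]
    out$shift[rows] <- res$shift
    out$ambiguous[rows] <- res$ambiguous
  }
  out
}

#' Normal estimation with smoothing shift at a single point
#'
#' Reference implementation of the constrained least squares solved per point
#' by [smooth_cloud()]. Exposed for testing and didactic use.
#'
#' @param p numeric length-3 position.
#' @param neighbors n x 3 matrix of neighbouring points.
#' @return List with `normal` (unit), `shift` t, `smoothed` position and
#'   `ambiguous` flag.
#' @export
estimate_normal_and_shift <- function(p, neighbors, gap_tol = 1e-6) {
  neighbors <- as_xyz_matrix(neighbors)
  stopifnot(nrow(neighbors) >= 4)
  ctr <- colMeans(neighbors)
  C <- crossprod(sweep(neighbors, 2, ctr))
  eg <- eigen(C, symmetric = TRUE)
  eta <- eg$vectors[, 3]
  lam <- rev(eg$values) # ascending
  t <- sum((ctr - p) * eta)
  list(normal = eta, shift = t, smoothed = p + t * eta,
       ambiguous = (lam[2] - lam[1]) / max(lam[3], .Machine$double.eps) < gap_tol)
}

#' Orient cloud normals consistently
#'
#' Propagates normal signs along the minimum spanning tree of the k-nearest
#' neighbour graph (Euclidean edge weights) of each face, flipping a child
#' when its normal opposes its parent's. If `labels` is supplied, the global
#' sign per face is calibrated so that normals point from cell i into cell j
#' (`i < j`; exterior is 0, so exterior-face normals point into the cell):
#' sample points are probed a short distance along both normal directions in
#' the label volume and the majority vote decides the face's sign.
#'
#' @param cloud output of [smooth_cloud()].
#' @param labels optional `cell_labels` for the global i -> j calibration.
#' @param kgraph neighbourhood size of the orientation graph.
#' @param n_probe number of sample points probed per face.
#' @return The cloud with consistently signed `nx,ny,nz`.
#' @export
orient_cloud_normals <- function(cloud, labels = NULL, kgraph = 8,
                                 n_probe = 200) {
  by_face <- split(seq_len(nrow(cloud)), cloud$face)
  out <- cloud
  for (rows in by_face) {
    pts <- as_xyz_matrix(cloud[rows, ])
    nrm <- as.matrix(cloud[rows, c("nx", "ny", "nz")])
    res <- cpp_orient_mst(pts, nrm, kgraph)
    if (res$undecided > 0) {
      warn(sprintf("%d orientation edge(s) had exactly orthogonal normals; sign kept",
                   res$undecided))
    }
    nrm <- nrm * res$sign
    out$nx[rows] <- nrm[, 1]
    out$ny[rows] <- nrm[, 2]
    out$nz[rows] <- nrm[, 3]
  }
  if (!is.null(labels)) out <- calibrate_face_orientation(out, labels, n_probe)
  out
}

# Majority-vote global sign per face: normals must point cell_i -> cell_j.
calibrate_face_orientation <- function(cloud, labels, n_probe = 200) {
  stopifnot(inherits(labels, "cell_labels"))
  dims <- dim(labels$labels)
  vs <- labels$voxel_size
  step <- max(vs)
  by_face <- split(seq_len(nrow(cloud)), cloud$face)
  out <- cloud
  for (rows in by_face) {
    ci <- cloud$cell_i[rows[1]]
    cj <- cloud$cell_j[rows[1]]
    take <- rows[unique(round(seq(1, length(rows), length.out = min(n_probe, length(rows)))))]
    pts <- as_xyz_matrix(cloud[take, ])
    nrm <- as.matrix(cloud[take, c("nx", "ny", "nz")])
    vote <- 0L
    for (s in c(1.5, 2.5) * step) {
      lp <- labels$labels[physical_to_voxel(pts + s * nrm, vs, dims)]
      lm <- labels$labels[physical_to_voxel(pts - s * nrm, vs, dims)]
      vote <- vote + sum(lp == cj & lm == ci) - sum(lp == ci & lm == cj)
    }
    if (vote == 0L) {
      warn(sprintf("face {%d,%d}: orientation probes inconclusive; sign kept", ci, cj))
    } else if (vote < 0L) {
      out$nx[rows] <- -out$nx[rows]
      out$ny[rows] <- -out$ny[rows]
      out$nz[rows] <- -out$nz[rows]
    }
  }
  out
}

#' Quadric fit of a local surface patch
#'
#' Fits `z = a x + b y + c/2 x^2 + d x y + e/2 y^2` to neighbours expressed in
#' the local frame `(t1, t2, eta)` at a (smoothed) point: x, y, z are the
#' projections of `x_k - p` on `t1`, `t2` and the normal `eta`. Reference
#' implementation used per point; [estimate_curvature()] runs the compiled
#' batched equivalent.
#'
#' @param p length-3 position.
#' @param neighbors n x 3 matrix (n >= 5).
#' @param eta unit normal at p.
#' @return List `coef` (a, b, c, d, e) and `frame` (t1, t2, eta).
#' @export
fit_quadric <- function(p, neighbors, eta) {
  neighbors <- as_xyz_matrix(neighbors)
  stopifnot(nrow(neighbors) >= 5, abs(sum(eta^2) - 1) < 1e-6)
  ax <- which.min(abs(eta))
  t1 <- c(0, 0, 0); t1[ax] <- 1
  t1 <- unitize(t1 - sum(t1 * eta) * eta)
  t2 <- vcross(eta, t1)
  rel <- sweep(neighbors, 2, p)
  u <- rel %*% t1
  v <- rel %*% t2
  w <- rel %*% eta
  A <- cbind(u, v, u^2 / 2, u * v, v^2 / 2)
  qrA <- qr(A)
  if (qrA$rank < 5) abort("degenerate patch: rank-deficient quadric design")
  coef <- qr.coef(qrA, w)
  list(coef = setNames(as.numeric(coef), c("a", "b", "c", "d", "e")),
       frame = list(t1 = t1, t2 = t2, eta = eta))
}

#' Mean curvature and normal update from a quadric fit
#'
#' Builds the Weingarten (shape) operator of the fitted patch
#' `r(u, v) = u t1 + v t2 + z(u, v) eta` at the origin from the first and
#' second fundamental forms (`E = 1 + a^2`, `F = a b`, `G = 1 + b^2`;
#' `L = c/s`, `M = d/s`, `N = e/s` with `s = sqrt(1 + a^2 + b^2)`). Mean
#' curvature is reported in the `kappa = -n . dt/ds` convention:
#' `kappa_m = -trace(II I^-1) / 2`, so a surface bending towards `+eta` has
#' negative curvature and a convex surface with outward normals has positive
#' mean curvature. The normal is updated to
#' `eta - (a t1 + b t2)/s`, renormalised.
#'
#' @param fit result of [fit_quadric()].
#' @return List `kappa_m` and `eta_updated`.
#' @export
mean_curvature_from_fit <- function(fit) {
  cf <- fit$coef
  a <- cf["a"]; b <- cf["b"]
  s <- sqrt(1 + a^2 + b^2)
  E <- 1 + a^2; Ff <- a * b; G <- 1 + b^2
  L <- cf["c"] / s; M <- cf["d"] / s; N <- cf["e"] / s
  det <- E * G - Ff^2
  kappa <- -0.5 * (L * G - 2 * M * Ff + N * E) / det
  eta_upd <- fit$frame$eta - (a / s) * fit$frame$t1 - (b / s) * fit$frame$t2
  list(kappa_m = as.numeric(kappa), eta_updated = unitize(eta_upd))
}

#' Per-point mean curvature of an oriented cloud
#'
#' Runs the quadric fit of [fit_quadric()] / [mean_curvature_from_fit()] at
#' every smoothed point using its `k` nearest same-face neighbours, adds the
#' signed mean curvature `kappa`, the fitted Taylor coefficients and the
#' updated normals. Points with a rank-deficient patch or an ambiguous normal
#' are marked invalid (`valid = FALSE`, `kappa = NA`).
#'
#' @param cloud oriented output of [orient_cloud_normals()].
#' @param k number of nearest neighbours `K_C`.
#' @param rcond_tol reciprocal-condition threshold for a degenerate patch.
#' @return The cloud with `kappa`, coefficient columns `qa..qe`, updated
#'   normals and `valid`.
#' @export
estimate_curvature <- function(cloud, k = 50, rcond_tol = 1e-12) {
  stopifnot(k >= 5)
  by_face <- split(seq_len(nrow(cloud)), cloud$face)
  out <- cloud
  out$kappa <- NA_real_
  out$qa <- out$qb <- out$qc <- out$qd <- out$qe <- NA_real_
  out$fnx <- out$fny <- out$fnz <- NA_real_
  out$valid <- FALSE
  for (rows in by_face) {
    pts <- as_xyz_matrix(cloud[rows, ])
    nrm <- as.matrix(cloud[rows, c("nx", "ny", "nz")])
    res <- cpp_quadric_curvature(pts, nrm, min(k, nrow(pts) - 1), rcond_tol)
    out$kappa[rows] <- res$kappa
    out$qa[rows] <- res$coef[, "a"]; out$qb[rows] <- res$coef[, "b"]
    out$qc[rows] <- res$coef[, "c"]; out$qd[rows] <- res$coef[, "d"]
    out$qe[rows] <- res$coef[, "e"]
    # keep the fit-frame normal: the local frame (t1, t2, eta) of the stored
    # Taylor coefficients is reconstructible from it
    out$fnx[rows] <- nrm[, 1]
    out$fny[rows] <- nrm[, 2]
    out$fnz[rows] <- nrm[, 3]
    out$nx[rows] <- res$normal[, 1]
    out$ny[rows] <- res$normal[, 2]
    out$nz[rows] <- res$normal[, 3]
    amb <- if ("ambiguous" %in% names(cloud)) cloud$ambiguous[rows] else FALSE
    out$valid[rows] <- res$ok & !amb
  }
  out
}

#' Face-averaged mean curvature
#'
#' The per-face mean curvature `H_k` entering the Young-Laplace rows is the
#' arithmetic mean of the per-point curvatures over a face's valid points,
#' signed in the global i -> j normal convention.
#'
#' @param cloud output of [estimate_curvature()].
#' @return Tibble `face`, `cell_i`, `cell_j`, `H`, `n_points`.
#' @export
face_curvatures <- function(cloud) {
  res <- cloud |>
    dplyr::filter(.data$valid) |>
    dplyr::group_by(.data$face, .data$cell_i, .data$cell_j) |>
    dplyr::summarise(H = mean(.data$kappa), n_points = dplyr::n(),
                     .groups = "drop")
  missing <- setdiff(unique(cloud$face), res$face)
  if (length(missing) > 0) {
    abort(paste0("no valid curvature points on face(s) ",
                 paste(missing, collapse = ", ")))
  }
  res
}

#' Sub-voxel crest refinement of membrane points
#'
#' Watershed ridge voxels carry integer positions, which terraces shallow
#' surfaces (a bowl with a sagitta of one or two voxels becomes a staircase of
#' flat plateaus and loses its tilt near the junction). The probability map
#' still holds the sub-voxel membrane location, so each point is moved along
#' its estimated normal to the quadratic-interpolated maximum of the
#' probability profile (samples at -step, 0, +step; trilinear interpolation;
#' move clamped to one step). Standard sub-pixel ridge localisation; a single
#' pass before the final smoothing restores continuum positions to well below
#' voxel accuracy.
#'
#' @param cloud cloud with raw positions `x0,y0,z0` and normals (e.g. the
#'   output of [smooth_cloud()]).
#' @param vol the [prob_volume()] the ridge was extracted from.
#' @param step sampling step along the normal, in physical units.
#' @return The cloud with refined `x`, `y`, `z`.
#' @export
refine_cloud_crest <- function(cloud, vol, step = 1) {
  stopifnot(inherits(vol, "prob_volume"),
            all(c("x0", "y0", "z0", "nx", "ny", "nz") %in% names(cloud)))
  vs <- vol$voxel_size
  pts <- as_xyz_matrix(cloud, c("x0", "y0", "z0"))
  pts_vox <- sweep(pts, 2, vs, `/`)
  nrm <- as.matrix(cloud[, c("nx", "ny", "nz")])
  nrm_vox <- sweep(nrm, 2, vs, `/`)
  ref <- cpp_crest_refine(vol$data, as.integer(dim(vol$data)),
                          pts_vox, nrm_vox, step)
  out <- cloud
  out$x <- ref[, 1] * vs[1]
  out$y <- ref[, 2] * vs[2]
  out$z <- ref[, 3] * vs[3]
  out
}

#' Reconstruct all membrane faces of a segmentation
#'
#' Convenience wrapper chaining [face_point_cloud()], a first
#' [smooth_cloud()] pass for normal estimates, optional sub-voxel crest
#' refinement against the probability volume ([refine_cloud_crest()]),
#' the final smoothing pass, [orient_cloud_normals()] (with global
#' calibration against the label volume) and [estimate_curvature()].
#'
#' @param face_map a `face_map`.
#' @param labels the `cell_labels` the map came from.
#' @param vol the source [prob_volume()]; when supplied, membrane points are
#'   refined to the sub-voxel probability crest before smoothing.
#' @param k_s,k_c smoothing / curvature neighbourhood sizes.
#' @return The oriented, curvature-annotated cloud tibble.
#' @export
reconstruct_surfaces <- function(face_map, labels, vol = NULL,
                                 k_s = 50, k_c = 50) {
  cloud <- face_point_cloud(face_map) |>
    smooth_cloud(k = k_s)
  if (!is.null(vol)) {
    cloud <- refine_cloud_crest(cloud, vol) |>
      smooth_cloud(k = k_s)
  }
  cloud |>
    orient_cloud_normals(labels = labels) |>
    estimate_curvature(k = k_c)
}
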