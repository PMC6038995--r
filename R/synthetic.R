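#' Analytic ground truth for the axisymmetric two-cell system
#'
#' Constructs the equilibrium configuration of two spherical-cap cells joined
#' by a spherical-cap interface: cap radii `R1 = 5 L` and `R2 = 4 L`, circular
#' triple junction of radius `d = 3 L`. The symmetry axis is x, cell 1 (the
#' larger cap) sits at lower x. Setting the exterior pressure to 0 and
#' `P1 = 1` before rescaling, the Young-Laplace relation on the outer caps
#' fixes `T1 = P1 R1 / 2` and `T2 = P2 R2 / 2`; the interface tension and its
#' tangent direction follow from tension balance at the junction,
#' `T1 t1 + T2 t2 + T3 t3 = 0` in the meridian plane, and the interface
#' curvature from `H3 = (P1 - P2) / (2 T3)` (which the junction balance makes
#' consistent with the interface geometry). Tensions are rescaled so their
#' mean is 1 and pressures are rescaled accordingly, so the configuration
#' satisfies every force-balance relation exactly.
#'
#' Curvatures are signed by the face normal convention used throughout the
#' package: for face `{i, j}` with `i < j` normals point from region i into
#' region j, and mean curvature follows `kappa = -n . dt/ds`, so the two
#' exterior faces (normals pointing into the cells) have `H = -1/R`.
#'
#' All lengths are in voxels.
#'
#' @param L length scale in voxels; the cell diameters are `10 L` and `8 L`.
#' @param pressure_ratio target `P2 / P1`. Must lie in the feasible interval
#'   (see [two_cell_feasible_interval()]); the interval endpoints correspond to
#'   the interface folding onto one of the caps.
#' @param min_angle smallest admissible dihedral sector angle, in radians,
#'   used for the feasibility check.
#' @return A `two_cell_truth` object: tensions (mean 1), pressures (exterior
#'   0), signed face curvatures `H`, junction angles, and the meridian
#'   geometry (sphere centres, radii, junction plane).
#' @export
two_cell_truth <- function(L = 20, pressure_ratio = 0.8, min_angle = deg2rad(10)) {
  stopifnot(L > 0, pressure_ratio > 0)
  geo <- two_cell_solve(L, pressure_ratio)
  ang <- geo$angles
  if (min(ang) < min_angle || max(ang) > pi - min_angle) {
    iv <- two_cell_feasible_interval(min_angle)
    abort(sprintf(
      "pressure_ratio %.4g is outside the feasible interval (%.4g, %.4g)",
      pressure_ratio, iv[1], iv[2]))
  }
  geo
}

# closed-form meridian solution; no feasibility guard
two_cell_solve <- function(L, pressure_ratio) {
  R1 <- 5 * L
  R2 <- 4 * L
  d <- 3 * L
  xj <- 0
  c1x <- xj - sqrt(R1^2 - d^2)   # -4L
  c2x <- xj + sqrt(R2^2 - d^2)   # +sqrt(7)L
  P1 <- 1
  P2 <- pressure_ratio
  T1 <- P1 * R1 / 2
  T2 <- P2 * R2 / 2
  # meridian pull directions (x, rho) of the outer caps at the junction
  t1 <- c(-d / R1, sqrt(R1^2 - d^2) / R1)
  t2 <- c(d / R2, sqrt(R2^2 - d^2) / R2)
  v <- -(T1 * t1 + T2 * t2)
  T3 <- sqrt(sum(v^2))
  t3 <- v / T3
  if (t3[2] >= 0) {
    abort("degenerate configuration: interface pull direction not toward the axis")
  }
  H3 <- (P1 - P2) / (2 * T3)     # signed, face {1,2} normal pointing cell 1 -> 2
  flat <- abs(H3) < 1e-12
  R3 <- if (flat) Inf else 1 / abs(H3)
  s3 <- sign(H3)                  # +1: interface bulges toward cell 2
  c3x <- if (flat) NA_real_ else xj - s3 * sqrt(R3^2 - d^2)
  angles <- c(theta_12 = acos(sum(t1 * t2)),
              theta_13 = acos(sum(t1 * t3)),
              theta_23 = acos(sum(t2 * t3)))
  stopifnot(abs(sum(angles) - 2 * pi) < 1e-9)
  tensions <- c(T1, T2, T3)
  scale <- 3 / sum(tensions)
  structure(list(
    L = L,
    pressure_ratio = pressure_ratio,
    R = c(R1, R2),
    d = d,
    tensions = setNames(tensions * scale, c("T1", "T2", "T3")),
    pressures = setNames(c(0, P1, P2) * scale, c("P0", "P1", "P2")),
    H = setNames(c(-1 / R1, -1 / R2, H3), c("H1", "H2", "H3")),
    angles = angles,
    geometry = list(xj = xj, c1x = c1x, c2x = c2x, c3x = c3x,
                    R1 = R1, R2 = R2, R3 = R3, s3 = s3, flat = flat,
                    t1 = t1, t2 = t2, t3 = t3)
  ), class = "two_cell_truth")
}

#' @export
print.two_cell_truth <- function(x, ...) {
  cat(sprintf("<two_cell_truth> L = %g (R1 = %g, R2 = %g, d = %g), P2/P1 = %g\n",
              x$L, x$R[1], x$R[2], x$d, x$pressure_ratio))
  cat(sprintf("  tensions: %s\n", paste(signif(x$tensions, 5), collapse = ", ")))
  cat(sprintf("  H3 = %g, angles (deg): %s\n", x$H[3],
              paste(signif(rad2deg(x$angles), 5), collapse = ", ")))
  invisible(x)
}

#' Feasible pressure-ratio interval of the two-cell family
#'
#' The cap radii and the junction radius are fixed, so the configuration
#' degenerates when one of the junction sector angles collapses or the
#' interface folds onto a cap (an angle reaching pi). The interval is found by
#' bisection on the closed-form angles and is independent of `L`.
#'
#' @inheritParams two_cell_truth
#' @return Numeric `c(lower, upper)` of admissible `P2 / P1`.
#' @export
two_cell_feasible_interval <- function(min_angle = deg2rad(10)) {
  ok <- function(r) {
    geo <- two_cell_solve(1, r)
    min(geo$angles) >= min_angle && max(geo$angles) <= pi - min_angle
  }
  stopifnot(ok(1))
  lo <- 1; step <- 0.5
  while (lo > 1e-6 && ok(max(lo - step, 1e-6))) lo <- max(lo - step, 1e-6)
  a <- max(lo - step, 1e-6); b <- lo
  for (i in 1:60) { m <- (a + b) / 2; if (ok(m)) b <- m else a <- m }
  lower <- b
  hi <- 1
  while (hi < 64 && ok(hi + step)) hi <- hi + step
  a <- hi; b <- hi + step
  for (i in 1:60) { m <- (a + b) / 2; if (ok(m)) a <- m else b <- m }
  c(lower, a)
}

#' Distances from points to the analytic two-cell surfaces
#'
#' Reference implementation (plain R) of the distance from arbitrary 3D points
#' to each of the three membrane surfaces of a [two_cell_truth()]
#' configuration, in the truth coordinate frame (junction plane at x = 0,
#' symmetry axis y = z = 0). Used to validate the compiled renderer and for
#' ray-marching checks.
#'
#' @param points n x 3 matrix (or data frame with x, y, z).
#' @param truth a [two_cell_truth()].
#' @return n x 3 matrix of distances to faces 1, 2, 3.
#' @export
two_cell_surface_distance <- function(points, truth) {
  p <- as_xyz_matrix(points)
  g <- truth$geometry
  x <- p[, 1]
  rho <- sqrt(p[, 2]^2 + p[, 3]^2)
  circ <- sqrt((x - g$xj)^2 + (rho - truth$d)^2)
  cap_dist <- function(cx, R, side) {
    r <- pmax(sqrt((x - cx)^2 + rho^2), 1e-12)
    qx <- cx + (x - cx) * R / r
    ifelse(side * (qx - g$xj) <= 0, abs(r - R), circ)
  }
  d1 <- cap_dist(g$c1x, g$R1, +1)
  d2 <- cap_dist(g$c2x, g$R2, -1)
  if (g$flat) {
    d3 <- ifelse(rho <= truth$d, abs(x - g$xj), circ)
  } else {
    d3 <- cap_dist(g$c3x, g$R3, -g$s3)
  }
  cbind(d1, d2, d3)
}

#' Render synthetic probability volumes
#'
#' Emulates a pixel-classification probability map for the analytic fixtures:
#' the per-voxel probability is a Gaussian profile of the distance to the
#' nearest membrane surface, `exp(-d^2 / (2 blur_width^2))`, truncated to
#' exactly 0 beyond `cutoff` blur widths so that cell interiors and the
#' exterior are flat plateaus (this mimics the vanishing membrane class
#' probability away from membranes and gives the watershed clean minima).
#'
#' `render_two_cell()` places the [two_cell_truth()] configuration in a volume
#' with a margin of `margin + ceiling(cutoff * blur_width)` voxels; the offset
#' from truth coordinates to volume coordinates is returned as attribute
#' `"offset"` (volume = truth + offset).
#'
#' The default blur width is `0.15 L` voxels — fixed in physical units across
#' the resolution family (1.5 voxels at the coarsest scale `L = 10`). A
#' resolution study images the same specimen with the same optics on finer
#' grids, so the membrane profile must occupy proportionally more voxels as
#' `L` grows; a blur fixed in voxels would instead change the imaging physics
#' with every resolution.
#'
#' @param truth a [two_cell_truth()].
#' @param blur_width Gaussian width of the membrane profile in voxels;
#'   `NULL` (default) uses `0.15 L`.
#' @param margin clear voxels beyond the blur support.
#' @param cutoff truncation of the Gaussian profile, in blur widths (the
#'   default 4 leaves tails below the 1/255 quantisation step).
#' @return A [prob_volume()] with attributes `truth` and `offset`.
#' @export
render_two_cell <- function(truth, blur_width = NULL, margin = 5, cutoff = 4) {
  if (is.null(blur_width)) blur_width <- 0.15 * truth$L
  g <- truth$geometry
  pad <- margin + ceiling(cutoff * blur_width)
  xmin <- g$c1x - g$R1 - pad
  xmax <- g$c2x + g$R2 + pad
  rmax <- max(g$R1, g$R2) + pad
  dims <- c(ceiling(xmax - xmin), ceiling(2 * rmax), ceiling(2 * rmax))
  offset <- c(-xmin, rmax, rmax)
  dat <- cpp_render_two_cell(
    as.integer(dims),
    g$c1x + offset[1], g$c2x + offset[1], g$xj + offset[1],
    offset[2], offset[3],
    g$R1, g$R2, truth$d,
    g$flat, if (g$flat) 0 else g$c3x + offset[1],
    if (g$flat) 0 else g$R3, if (g$flat) 1 else g$s3,
    blur_width, cutoff)
  dim(dat) <- dims
  vol <- prob_volume(dat)
  attr(vol, "truth") <- truth
  attr(vol, "offset") <- offset
  vol
}

#' @rdname render_two_cell
#' @param R sphere radius in voxels.
#' @export
render_sphere <- function(R = 20, blur_width = 1.5, margin = 5, cutoff = 4) {
  pad <- margin + ceiling(cutoff * blur_width)
  n <- ceiling(2 * (R + pad))
  ctr <- n / 2
  dat <- cpp_render_sphere(as.integer(c(n, n, n)), ctr, ctr, ctr, R,
                           blur_width, cutoff)
  dim(dat) <- c(n, n, n)
  vol <- prob_volume(dat)
  attr(vol, "center") <- rep(ctr, 3)
  attr(vol, "radius") <- R
  vol
}

#' @rdname render_two_cell
#' @param n_cells number of equal cells in the row.
#' @param spacing centre-to-centre distance (must be `< 2 R`).
#' @export
render_cell_row <- function(n_cells = 3, R = 16, spacing = 24,
                            blur_width = 1.5, margin = 5, cutoff = 4) {
  stopifnot(n_cells >= 2, spacing < 2 * R)
  pad <- margin + ceiling(cutoff * blur_width)
  centers <- R + pad + spacing * (seq_len(n_cells) - 1)
  nx <- ceiling(centers[n_cells] + R + pad)
  nyz <- ceiling(2 * (R + pad))
  dims <- c(nx, nyz, nyz)
  dat <- cpp_render_cell_row(as.integer(dims), centers, nyz / 2, nyz / 2, R,
                             blur_width, cutoff)
  dim(dat) <- dims
  vol <- prob_volume(dat)
  attr(vol, "centers_x") <- centers
  vol
}

#' Rasterise a point cloud back into a grayscale membrane volume
#'
#' Reproducibility perturbation: positions are rounded to their nearest voxel,
#' the binarised voxel set is diffused `decay_range` voxels outward, and
#' intensity decreases linearly with distance,
#' `I(v) = max(0, 1 - dist(v, membrane) / decay_range)`. Running the pipeline
#' on the result probes the sensitivity of the inference to the image-side
#' representation.
#'
#' @param points cloud positions (physical coordinates) as a matrix or a
#'   tibble with `x`, `y`, `z`.
#' @param dim integer dimensions of the target volume.
#' @param voxel_size physical voxel size of the target volume.
#' @param decay_range linear decay range in voxels.
#' @return A [prob_volume()] holding the grayscale intensities.
#' @export
reprocess_volume <- function(points, dim, voxel_size = c(1, 1, 1),
                             decay_range = 3) {
  stopifnot(decay_range > 0)
  p <- as_xyz_matrix(points)
  if (nrow(p) == 0) abort("empty point cloud")
  if (length(voxel_size) == 1) voxel_size <- rep(voxel_size, 3)
  ijk <- physical_to_voxel(p, voxel_size, dim)
  ijk <- unique(ijk)
  storage.mode(ijk) <- "integer"
  dat <- cpp_stamp_distance(ijk, as.integer(dim), decay_range)
  dim(dat) <- dim
  prob_volume(dat, voxel_size = voxel_size)
}
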