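#' Assemble the force-balance linear system
#'
#' Builds the overdetermined system `M x = b` for the unknowns
#' `x = (P_0, P_1..P_nc, T_1..T_nm)`:
#'
#' * one Young-Laplace row per membrane face k between cells `i < j`:
#'   `P_i - P_j - 2 H_k T_k = 0`, with `H_k` signed in the package's i -> j
#'   normal convention (see [mean_curvature_from_fit()]);
#' * two tension-balance rows per junction, in the sorted face ordering
#'   `f1 < f2 < f3` with averaged dihedral angles:
#'   `T_f1 + T_f2 cos(theta_12) + T_f3 cos(theta_13) = 0` and
#'   `T_f2 sin(theta_12) - T_f3 sin(theta_13) = 0`;
#' * two gauge rows fixing the exterior pressure, `P_0 = P_b`, and the tension
#'   scale, `sum T = n_m` (mean tension 1).
#'
#' So `M` is `(n_m + 2 n_j + 2) x (n_m + n_c + 1)` and
#' `b = (0, ..., 0, P_b, n_m)`. Curvatures are divided by `length_scale` so
#' that pressures are expressed per physical length when voxel-based
#' curvatures are supplied; with the default 1, curvatures stay in 1/voxel
#' and pressures in tension per voxel.
#'
#' The gauge rows are ordinary least-squares rows; with consistent data they
#' are satisfied exactly.
#'
#' @param topology an `embryo_topology`.
#' @param curvatures tibble with `face`, `H` (from [face_curvatures()]).
#' @param angles tibble with `junction`, `theta_12`, `theta_13` (from
#'   [average_junction_angles()]).
#' @param P_b exterior pressure.
#' @param length_scale physical length per voxel.
#' @return A `force_system` with `M`, `b` and labelling metadata.
#' @export
assemble_force_system <- function(topology, curvatures, angles, P_b = 0,
                                  length_scale = 1) {
  stopifnot(inherits(topology, "embryo_topology"))
  n_c <- topology$n_cells
  n_m <- topology$n_faces
  n_j <- topology$n_junctions
  faces <- topology$faces
  juncs <- topology$junctions

  missing_H <- setdiff(faces$face, curvatures$face)
  if (length(missing_H) > 0) {
    abort(paste0("missing mean curvature for face(s) ",
                 paste(missing_H, collapse = ", ")))
  }
  if (n_j > 0) {
    missing_a <- setdiff(juncs$junction, angles$junction)
    if (length(missing_a) > 0) {
      abort(paste0("missing averaged angles for junction(s) ",
                   paste(missing_a, collapse = ", ")))
    }
  }

  col_names <- c(paste0("P", 0:n_c), paste0("T", seq_len(n_m)))
  pcol <- function(cell) cell + 1L
  tcol <- function(face) n_c + 1L + face
  nrow_M <- n_m + 2 * n_j + 2
  M <- matrix(0, nrow_M, n_m + n_c + 1,
              dimnames = list(NULL, col_names))
  row_labels <- character(nrow_M)

  H <- curvatures$H[match(faces$face, curvatures$face)] / length_scale
  for (k in seq_len(n_m)) {
    M[k, pcol(faces$cell_i[k])] <- 1
    M[k, pcol(faces$cell_j[k])] <- M[k, pcol(faces$cell_j[k])] - 1
    M[k, tcol(faces$face[k])] <- -2 * H[k]
    row_labels[k] <- paste0("YL_", faces$face[k])
  }
  if (n_j > 0) {
    th <- angles[match(juncs$junction, angles$junction), ]
    for (jj in seq_len(n_j)) {
      r <- n_m + 2 * (jj - 1) + 1
      M[r, tcol(juncs$f1[jj])] <- 1
      M[r, tcol(juncs$f2[jj])] <- cos(th$theta_12[jj])
      M[r, tcol(juncs$f3[jj])] <- cos(th$theta_13[jj])
      M[r + 1, tcol(juncs$f2[jj])] <- sin(th$theta_12[jj])
      M[r + 1, tcol(juncs$f3[jj])] <- -sin(th$theta_13[jj])
      row_labels[r] <- paste0("JT_", juncs$junction[jj])
      row_labels[r + 1] <- paste0("JN_", juncs$junction[jj])
    }
  }
  M[n_m + 2 * n_j + 1, pcol(0)] <- 1
  M[n_m + 2 * n_j + 2, (n_c + 2):(n_c + 1 + n_m)] <- 1
  row_labels[n_m + 2 * n_j + 1] <- "gauge_P0"
  row_labels[n_m + 2 * n_j + 2] <- "gauge_T"
  rownames(M) <- row_labels
  b <- c(rep(0, n_m + 2 * n_j), P_b, n_m)

  structure(list(M = M, b = b, topology = topology,
                 curvatures = curvatures, angles = angles,
                 P_b = P_b, length_scale = length_scale),
            class = "force_system")
}

#' @export
print.force_system <- function(x, ...) {
  cat(sprintf("<force_system> M is %d x %d (n_c = %d, n_m = %d, n_j = %d), P_b = %g\n",
              nrow(x$M), ncol(x$M), x$topology$n_cells, x$topology$n_faces,
              x$topology$n_junctions, x$P_b))
  invisible(x)
}

#' Solve the force-balance system
#'
#' Least-squares solution `x = (M^T M)^-1 M^T b` (computed by QR for
#' numerical stability; identical to the pseudoinverse solution when `M` has
#' full column rank). Rank deficiency is an error — the system is never
#' silently regularised — and the null-space basis is attached to the error
#' for diagnosis.
#'
#' @param system a `force_system`.
#' @return A `force_fit` with the solution vector, tidy `pressures` and
#'   `tensions` tibbles and the row residuals.
#' @export
solve_forces <- function(system) {
  stopifnot(inherits(system, "force_system"))
  M <- system$M
  qrM <- qr(M)
  if (qrM$rank < ncol(M)) {
    sv <- svd(M)
    null_basis <- sv$v[, sv$d < max(sv$d) * 1e-10, drop = FALSE]
    rlang::abort("force system is rank deficient; not solvable uniquely",
                 null_basis = null_basis)
  }
  x <- qr.coef(qrM, system$b)
  names(x) <- colnames(M)
  fitted <- as.numeric(M %*% x)
  topo <- system$topology
  n_c <- topo$n_cells
  pressures <- tibble::tibble(cell = 0:n_c, pressure = as.numeric(x[1:(n_c + 1)]))
  tensions <- topo$faces |>
    dplyr::transmute(.data$face, .data$cell_i, .data$cell_j,
                     tension = as.numeric(x[n_c + 1 + .data$face]))
  structure(list(x = x, pressures = pressures, tensions = tensions,
                 fitted = fitted, residuals = fitted - system$b,
                 system = system),
            class = "force_fit")
}

#' @export
print.force_fit <- function(x, ...) {
  cat("<force_fit>\n  pressures:\n")
  print(x$pressures)
  cat("  tensions:\n")
  print(x$tensions)
  invisible(x)
}

#' Per-face Young-Laplace residuals
#'
#' Signed relative error of each Young-Laplace relation,
#' `(P_i - P_j - 2 H_k T_k) / (|P_i| + |P_j| + |2 H_k T_k|)`, with pressures
#' measured relative to the exterior pressure `P_b`. Faces are classed as
#' `outer` (one side exterior) or `inner`. A face with all three magnitudes
#' zero has residual 0 by convention.
#'
#' @param fit a `force_fit`.
#' @return Tibble with per-face `lhs`, `rhs`, `rel_residual` and `class`.
#' @export
membrane_residuals <- function(fit) {
  stopifnot(inherits(fit, "force_fit"))
  sys <- fit$system
  topo <- sys$topology
  H <- sys$curvatures$H[match(topo$faces$face, sys$curvatures$face)] /
    sys$length_scale
  p <- fit$pressures$pressure - sys$P_b
  Tn <- fit$tensions$tension
  Pi <- p[topo$faces$cell_i + 1]
  Pj <- p[topo$faces$cell_j + 1]
  lhs <- Pi - Pj
  rhs <- 2 * H * Tn
  denom <- abs(Pi) + abs(Pj) + abs(rhs)
  rel <- ifelse(denom == 0, 0, (lhs - rhs) / denom)
  topo$faces |>
    dplyr::transmute(.data$face, .data$cell_i, .data$cell_j,
                     lhs = lhs, rhs = rhs, rel_residual = rel,
                     class = ifelse(.data$cell_i == 0, "outer", "inner"))
}

#' Per-junction tension-balance residuals
#'
#' The absolute junction error is the Euclidean norm of the residual of the
#' two in-plane balance equations; the relative error divides it by the mean
#' total junction force (sum of the three member tensions) over all junctions.
#'
#' @param fit a `force_fit`.
#' @return Tibble with per-junction `abs_residual` and `rel_residual`.
#' @export
junction_residuals <- function(fit) {
  stopifnot(inherits(fit, "force_fit"))
  sys <- fit$system
  topo <- sys$topology
  if (topo$n_junctions == 0) {
    return(tibble::tibble(junction = integer(), abs_residual = numeric(),
                          rel_residual = numeric()))
  }
  th <- sys$angles[match(topo$junctions$junction, sys$angles$junction), ]
  Tn <- fit$tensions$tension
  j <- topo$junctions
  T1 <- Tn[j$f1]; T2 <- Tn[j$f2]; T3 <- Tn[j$f3]
  e_t <- T1 + T2 * cos(th$theta_12) + T3 * cos(th$theta_13)
  e_n <- T2 * sin(th$theta_12) - T3 * sin(th$theta_13)
  total <- T1 + T2 + T3
  tibble::tibble(junction = j$junction,
                 abs_residual = sqrt(e_t^2 + e_n^2),
                 rel_residual = sqrt(e_t^2 + e_n^2) / mean(total))
}

#' Sensitivity spectrum of the pseudoinverse
#'
#' Amplification factors `lambda_i` of perturbations `delta b -> delta x`
#' through the pseudoinverse `(M^T M)^-1 M^T`: its singular values, i.e. the
#' reciprocals of the nonzero singular values of `M`, sorted descending.
#' Values above 1 flag directions in which the inference amplifies noise. The
#' most amplified solution-space direction (the right-singular vector of `M`
#' with the smallest singular value) is reported as `dominant_mode`; for
#' well-posed embryo systems it is the constant-pressure / zero-tension
#' direction, which does not contaminate pressure differences.
#'
#' @param system a `force_system`.
#' @return A `sensitivity_spectrum` tibble (`index`, `lambda`) with the
#'   dominant mode and full mode matrix as attributes.
#' @export
sensitivity_spectrum <- function(system) {
  stopifnot(inherits(system, "force_system"))
  sv <- svd(system$M)
  ord <- order(sv$d) # ascending sigma = descending lambda
  lambda <- 1 / sv$d[ord]
  modes <- sv$v[, ord, drop = FALSE]
  rownames(modes) <- colnames(system$M)
  out <- tibble::tibble(index = seq_along(lambda), lambda = lambda)
  attr(out, "dominant_mode") <- setNames(modes[, 1], colnames(system$M))
  attr(out, "modes") <- modes
  class(out) <- c("sensitivity_spectrum", class(out))
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted force system
#'
#' One row per inferred quantity: exterior/cell pressures and face tensions.
#'
#' @param x a `force_fit`.
#' @param ... unused.
#' @export
tidy.force_fit <- function(x, ...) {
  dplyr::bind_rows(
    x$pressures |>
      dplyr::transmute(term = paste0("P", .data$cell), type = "pressure",
                       entity = .data$cell, estimate = .data$pressure),
    x$tensions |>
      dplyr::transmute(term = paste0("T", .data$face), type = "tension",
                       entity = .data$face, estimate = .data$tension)
  )
}

#' Summarise a fitted force system
#'
#' @param x a `force_fit`.
#' @param ... unused.
#' @export
glance.force_fit <- function(x, ...) {
  topo <- x$system$topology
  mres <- membrane_residuals(x)
  jres <- junction_residuals(x)
  spec <- sensitivity_spectrum(x$system)
  tibble::tibble(
    n_cells = topo$n_cells,
    n_faces = topo$n_faces,
    n_junctions = topo$n_junctions,
    rss = sum(x$residuals^2),
    mean_membrane_residual = mean(abs(mres$rel_residual)),
    mean_junction_residual = if (nrow(jres)) mean(jres$rel_residual) else NA_real_,
    lambda_max = spec$lambda[1]
  )
}
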