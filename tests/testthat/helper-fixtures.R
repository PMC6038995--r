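# Analytic point-cloud fixtures and small oracles shared across tests.

# uniform random sample on a sphere, optional Gaussian radial noise
sphere_cloud <- function(n, R = 20, sigma = 0, center = c(0, 0, 0), seed = 1) {
  set.seed(seed)
  u <- matrix(stats::rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  r <- R + if (sigma > 0) stats::rnorm(n, 0, sigma) else 0
  tibble::tibble(face = 1L, cell_i = 0L, cell_j = 1L,
                 x = center[1] + r * u[, 1],
                 y = center[2] + r * u[, 2],
                 z = center[3] + r * u[, 3])
}

# regular-ish grid sample of a plane patch z = a*x + b*y
plane_cloud <- function(n_side = 15, a = 0, b = 0, spacing = 1) {
  g <- expand.grid(x = seq_len(n_side), y = seq_len(n_side))
  g <- g * spacing
  tibble::tibble(face = 1L, cell_i = 0L, cell_j = 1L,
                 x = g$x, y = g$y, z = a * g$x + b * g$y)
}

# three half-planes meeting along the z axis at given azimuths (degrees)
three_half_planes <- function(azimuths = c(90, 210, 330), extent = 20,
                              spacing = 0.5, zmax = 20) {
  out <- list()
  for (i in seq_along(azimuths)) {
    phi <- azimuths[i] * pi / 180
    s <- seq(spacing, extent, by = spacing)
    g <- expand.grid(s = s, z = seq(0, zmax, by = spacing))
    out[[i]] <- tibble::tibble(
      face = i, cell_i = 0L, cell_j = i,
      x = g$s * cos(phi), y = g$s * sin(phi), z = g$z,
      nx = -sin(phi), ny = cos(phi), nz = 0)
  }
  dplyr::bind_rows(out)
}

# noisy circle in the xy plane
circle_cloud <- function(n = 400, R = 30, sigma = 0, seed = 1) {
  set.seed(seed)
  phi <- sort(stats::runif(n, 0, 2 * pi))
  r <- R + if (sigma > 0) stats::rnorm(n, 0, sigma) else 0
  tibble::tibble(junction = 1L, x = r * cos(phi), y = r * sin(phi),
                 z = if (sigma > 0) stats::rnorm(n, 0, sigma) else rep(0, n))
}

# chain-of-cells topology (cells 1..n in a row, all touching the exterior):
# faces {0,c} for every cell and {c,c+1} for neighbours; junctions at every
# adjacent pair. Returns an embryo_topology-compatible structure.
chain_topology <- function(n_cells) {
  outer <- tibble::tibble(cell_i = 0L, cell_j = seq_len(n_cells))
  inner <- if (n_cells > 1) {
    tibble::tibble(cell_i = seq_len(n_cells - 1), cell_j = 2:n_cells)
  } else {
    tibble::tibble(cell_i = integer(), cell_j = integer())
  }
  faces <- dplyr::bind_rows(outer, inner) |>
    dplyr::arrange(cell_i, cell_j) |>
    dplyr::mutate(face = dplyr::row_number(), .before = 1)
  fid <- function(a, b) faces$face[match(paste(pmin(a, b), pmax(a, b)),
                                         paste(faces$cell_i, faces$cell_j))]
  juncs <- if (n_cells > 1) {
    purrr::map_dfr(seq_len(n_cells - 1), function(c) {
      fs <- sort(c(fid(0, c), fid(0, c + 1), fid(c, c + 1)))
      tibble::tibble(junction = c, f1 = fs[1], f2 = fs[2], f3 = fs[3],
                     cell_1 = 0L, cell_2 = c, cell_3 = c + 1L, n_voxels = 1L)
    })
  } else {
    tibble::tibble(junction = integer(), f1 = integer(), f2 = integer(),
                   f3 = integer(), cell_1 = integer(), cell_2 = integer(),
                   cell_3 = integer(), n_voxels = integer())
  }
  structure(list(n_cells = n_cells, n_faces = nrow(faces),
                 n_junctions = nrow(juncs), faces = faces, junctions = juncs),
            class = "embryo_topology")
}

# populate a topology with a consistent ground truth: random tensions
# satisfying the per-junction triangle inequalities, angles back-computed from
# the tensions, pressures random, curvatures from Young-Laplace.
consistent_system <- function(topology, seed = 1, P_b = 0) {
  set.seed(seed)
  n_m <- topology$n_faces
  repeat {
    tension <- stats::runif(n_m, 0.7, 1.3)
    tension <- tension * n_m / sum(tension)
    ok <- TRUE
    for (j in seq_len(topology$n_junctions)) {
      Tj <- tension[unlist(topology$junctions[j, c("f1", "f2", "f3")])]
      if (2 * max(Tj) >= sum(Tj)) { ok <- FALSE; break }
    }
    if (ok) break
  }
  pressure <- c(P_b, stats::runif(topology$n_cells, 0.5, 1.5))
  # angle between pull tangents a and b given the three tensions:
  # cos(theta_ab) = (T_c^2 - T_a^2 - T_b^2) / (2 T_a T_b)
  angles <- purrr::map_dfr(seq_len(topology$n_junctions), function(j) {
    fs <- unlist(topology$junctions[j, c("f1", "f2", "f3")])
    Tj <- tension[fs]
    ang <- function(a, b, cc) {
      acos((Tj[cc]^2 - Tj[a]^2 - Tj[b]^2) / (2 * Tj[a] * Tj[b]))
    }
    tibble::tibble(junction = j, theta_12 = ang(1, 2, 3),
                   theta_13 = ang(1, 3, 2), theta_23 = ang(2, 3, 1))
  })
  H <- (pressure[topology$faces$cell_i + 1] -
          pressure[topology$faces$cell_j + 1]) /
    (2 * tension[topology$faces$face])
  list(curvatures = tibble::tibble(face = topology$faces$face, H = H),
       angles = angles,
       tension = tension, pressure = pressure, P_b = P_b)
}

rotation_matrix <- function(seed = 1) {
  set.seed(seed)
  qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
}

rotate_cloud <- function(cloud, Rm, cols = list(c("x", "y", "z"),
                                                c("nx", "ny", "nz"))) {
  out <- cloud
  for (cc in cols) {
    if (all(cc %in% names(cloud))) {
      out[, cc] <- as.matrix(cloud[, cc]) %*% t(Rm)
    }
  }
  out
}

# mean curvature of a graph z = f(x, y) at the origin (divergence form),
# with the kappa = -n.dt/ds sign for the +z normal
graph_mean_curvature <- function(fx, fy, fxx, fxy, fyy) {
  -((1 + fy^2) * fxx - 2 * fx * fy * fxy + (1 + fx^2) * fyy) /
    (2 * (1 + fx^2 + fy^2)^1.5)
}

# small vector helpers (independent of package internals)
unitize <- function(v) if (is.matrix(v)) v / sqrt(rowSums(v^2)) else v / sqrt(sum(v^2))
vcross <- function(a, b) c(a[2]*b[3] - a[3]*b[2], a[3]*b[1] - a[1]*b[3],
                           a[1]*b[2] - a[2]*b[1])
deg2rad <- function(x) x * pi / 180
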