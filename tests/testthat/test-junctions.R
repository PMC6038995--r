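# Junction extraction, thinning, tangents and dihedral angles.

test_that("junction points are membrane points close to both other faces", {
  cl <- three_half_planes()
  topo <- structure(list(
    n_cells = 3L, n_faces = 3L, n_junctions = 1L,
    faces = tibble::tibble(face = 1:3, cell_i = 0L, cell_j = 1:3,
                           n_voxels = NA_integer_),
    junctions = tibble::tibble(junction = 1L, f1 = 1L, f2 = 2L, f3 = 3L,
                               cell_1 = 1L, cell_2 = 2L, cell_3 = 3L,
                               n_voxels = 1L)
  ), class = "embryo_topology")
  jp <- extract_junction_points(cl, topo, d_T = 2)
  # qualifying points hug the z axis
  expect_lt(max(sqrt(jp$x^2 + jp$y^2)), 2.1)
  expect_gt(nrow(jp), 50)
  expect_error(extract_junction_points(cl, topo, d_T = 0), "positive")
  expect_error(extract_junction_points(cl, topo, d_T = 1e-6), "do not meet")
})

test_that("thinning collapses a noisy circle onto the curve", {
  cl <- circle_cloud(n = 600, R = 30, sigma = 1, seed = 31)
  th <- thin_junction_points(cl, k_J = 50)
  rms <- function(t) sqrt(mean((sqrt(t$x^2 + t$y^2) - 30)^2 + t$z^2))
  expect_gt(rms(cl) / rms(th), 3)
  expect_equal(nrow(th), nrow(cl))

  # exact circle: thinned points stay on a slightly smaller circle
  ex <- circle_cloud(n = 600, R = 30, sigma = 0, seed = 1)
  thx <- thin_junction_points(ex, k_J = 50)
  r <- sqrt(thx$x^2 + thx$y^2)
  # chord-centroid shrinkage bound: arc covered by K_J of n points
  arc <- 2 * pi * 30 * (50 / 600)
  expect_true(all(r <= 30 + 1e-9))
  expect_true(all(r >= 30 - arc^2 / (8 * 30)))

  # collinear points stay collinear
  ln <- tibble::tibble(junction = 1L, x = seq(0, 10, by = 0.1), y = 0, z = 0)
  expect_warning(thl <- thin_junction_points(ln, k_J = 200), "using all")
  expect_equal(max(abs(thl$y)), 0)
  expect_equal(max(abs(thl$z)), 0)
})

test_that("junction tangent formula handles clean and degenerate input", {
  # three planes meeting along z at 120 degrees: horizontal normals
  n1 <- c(1, 0, 0)
  n2 <- c(cos(2 * pi / 3), sin(2 * pi / 3), 0)
  n3 <- c(cos(4 * pi / 3), sin(4 * pi / 3), 0)
  m <- junction_tangent(n1, n2, n3)
  expect_equal(abs(m[3]), 1, tolerance = 1e-12)
  expect_error(junction_tangent(n1, n1, n1), "tangent undefined")
})

test_that("dihedral sector angles partition the normal plane", {
  m <- c(0, 0, 1)
  # symmetric 120-degree junction: membranes along d_i, normals in-plane
  phis <- c(90, 210, 330) * pi / 180
  d <- lapply(phis, function(p) c(cos(p), sin(p), 0))
  n <- lapply(phis, function(p) c(-sin(p), cos(p), 0))
  th <- dihedral_angles(m, n[[1]], n[[2]], n[[3]],
                        away1 = d[[1]], away2 = d[[2]], away3 = d[[3]])
  expect_equal(unname(th), rep(2 * pi / 3, 3), tolerance = 1e-12)
  expect_equal(sum(th), 2 * pi, tolerance = 1e-12)

  # two coplanar membranes plus one perpendicular: (pi/2, pi/2, pi)
  # membranes: half-planes along -y, +y (coplanar) and +x
  th2 <- dihedral_angles(m,
                         n1 = c(1, 0, 0), n2 = c(1, 0, 0), n3 = c(0, 1, 0),
                         away1 = c(0, -1, 0), away2 = c(0, 1, 0),
                         away3 = c(1, 0, 0))
  expect_equal(unname(th2), c(pi, pi / 2, pi / 2), tolerance = 1e-12)

  # membrane tangent to the junction: projected normal vanishes
  expect_error(dihedral_angles(m, c(0, 0, 1), n[[2]], n[[3]]),
               "tangent to junction")

  # property: sectors always sum to 2 pi for random configurations
  set.seed(37)
  for (rep in 1:25) {
    ns <- lapply(1:3, function(i) unitize(rnorm(3)))
    mm <- tryCatch(junction_tangent(ns[[1]], ns[[2]], ns[[3]]),
                   error = function(e) NULL)
    if (is.null(mm)) next
    aws <- lapply(1:3, function(i) unitize(rnorm(3)))
    th <- tryCatch(dihedral_angles(mm, ns[[1]], ns[[2]], ns[[3]],
                                   aws[[1]], aws[[2]], aws[[3]]),
                   error = function(e) NULL)
    if (is.null(th)) next
    expect_equal(sum(th), 2 * pi, tolerance = 1e-9)
  }
})

test_that("quadric normal transport reproduces analytic sphere normals", {
  cl <- sphere_cloud(8000, R = 30, seed = 41)
  or <- orient_cloud_normals(smooth_cloud(cl, k = 40))
  cv <- estimate_curvature(or, k = 40)
  pts <- as.matrix(cv[, c("x", "y", "z")])
  set.seed(42)
  a_idx <- sample(nrow(pts), 200)
  # targets roughly 7 voxels away along the surface from each anchor
  nnq <- embryoforce:::cpp_knn(pts, pts[a_idx, ], 100, FALSE)
  t_idx <- nnq$idx[, 100]
  nm <- quadric_normal_at(cv[a_idx, c("x", "y", "z")],
                          cv[a_idx, c("fnx", "fny", "fnz")],
                          as.matrix(cv[a_idx, c("qa", "qb", "qc", "qd", "qe")]),
                          pts[t_idx, ])
  truth <- unitize(pts[t_idx, ])
  err <- acos(pmin(1, abs(rowSums(nm * truth))))
  expect_lt(stats::median(err), deg2rad(1.5))
})

test_that("the two-cell junction ring reproduces the analytic geometry", {
  run <- shared_two_cell()
  tr <- run$truth
  off <- attr(render_two_cell(tr), "offset")
  jg <- run$junction_geometry
  # ring of radius d around the axis
  rho <- sqrt((jg$y - off[2])^2 + (jg$z - off[3])^2)
  expect_equal(mean(rho), tr$d, tolerance = 0.03 * tr$d)
  # tangents are azimuthal: within 3 degrees of the analytic circle tangent
  tang <- cbind(0, -(jg$z - off[3]), jg$y - off[2]) / rho
  dots <- abs(rowSums(tang * as.matrix(jg[, c("mx", "my", "mz")])))
  expect_gt(mean(dots > cos(deg2rad(3))), 0.95)
  # averaged sector angles close to the closed-form dihedral angles
  th <- unlist(run$angles[1, c("theta_12", "theta_13", "theta_23")])
  expect_lt(max(abs(th - tr$angles) / tr$angles), 0.02)
  # sums are preserved exactly by construction and by averaging
  expect_equal(sum(th), 2 * pi, tolerance = 1e-9)
  per_point <- rowSums(as.matrix(jg[, c("theta_12", "theta_13", "theta_23")]))
  expect_lt(max(abs(per_point - 2 * pi)), 1e-9)
})

test_that("angle averaging is linear and order-preserving", {
  jg <- tibble::tibble(junction = rep(1:2, each = 3),
                       x = 0, y = 0, z = 0, mx = 1, my = 0, mz = 0,
                       theta_12 = c(1, 1, 1, 1.0, 1.2, 1.4),
                       theta_13 = c(2, 2, 2, 2.0, 2.2, 2.4),
                       theta_23 = 2 * pi - c(3, 3, 3, 3.0, 3.4, 3.8))
  av <- average_junction_angles(jg)
  expect_equal(av$theta_12, c(1, 1.2))
  expect_equal(av$theta_13, c(2, 2.2))
  expect_equal(av$theta_12 + av$theta_13 + av$theta_23, rep(2 * pi, 2))
  expect_equal(av$n_points, c(3L, 3L))
})
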