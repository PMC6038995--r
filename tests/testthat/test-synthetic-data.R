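# Ground-truth generator: the two-cell family and its invariants.

test_that("two-cell ground truth satisfies all force-balance relations exactly", {
  for (r in c(0.7, 0.85, 1, 1.2)) {
    tr <- two_cell_truth(L = 20, pressure_ratio = r)
    Tn <- tr$tensions
    P <- tr$pressures
    # Young-Laplace on each face, in the i -> j normal convention
    expect_lt(abs((P["P0"] - P["P1"]) - 2 * tr$H["H1"] * Tn["T1"]), 1e-12)
    expect_lt(abs((P["P0"] - P["P2"]) - 2 * tr$H["H2"] * Tn["T2"]), 1e-12)
    expect_lt(abs((P["P1"] - P["P2"]) - 2 * tr$H["H3"] * Tn["T3"]), 1e-12)
    # junction balance written with the sector angles
    th <- tr$angles
    expect_lt(abs(Tn["T1"] + Tn["T2"] * cos(th[1]) + Tn["T3"] * cos(th[2])), 1e-12)
    expect_lt(abs(Tn["T2"] * sin(th[1]) - Tn["T3"] * sin(th[2])), 1e-12)
    expect_equal(sum(th), 2 * pi, tolerance = 1e-12)
    expect_equal(sum(Tn), 3, tolerance = 1e-12)
  }
})

test_that("junction balance holds under a brute-force tangent check", {
  # tangents recomputed by finite differences on the analytic surfaces at
  # many sampled junction points: independent of the closed-form meridian
  # vectors stored in the truth object
  tr <- two_cell_truth(L = 20, pressure_ratio = 0.8)
  g <- tr$geometry
  n <- 10000
  phi <- seq(0, 2 * pi, length.out = n + 1)[-1]
  jpt <- cbind(g$xj, tr$d * cos(phi), tr$d * sin(phi))
  eps <- 1e-5
  step_on_sphere <- function(cx, R, dpsi) {
    psi_j <- atan2(tr$d, g$xj - cx)
    psi <- psi_j + dpsi
    x <- cx + R * cos(psi)
    rho <- R * sin(psi)
    cbind(x, rho * cos(phi), rho * sin(phi))
  }
  # step each membrane away from the junction into its own surface
  q1 <- step_on_sphere(g$c1x, g$R1, +eps)  # over the top of cap 1
  q2 <- step_on_sphere(g$c2x, g$R2, -eps)  # over the top of cap 2
  q3 <- step_on_sphere(g$c3x, g$R3, -g$s3 * eps) # interface toward the axis
  tan_of <- function(q) {
    d <- q - jpt
    d / sqrt(rowSums(d^2))
  }
  res <- tr$tensions[1] * tan_of(q1) + tr$tensions[2] * tan_of(q2) +
    tr$tensions[3] * tan_of(q3)
  expect_lt(max(sqrt(rowSums(res^2))), 1e-3)
})

test_that("flat-interface limit and feasibility guards behave", {
  tr <- two_cell_truth(L = 10, pressure_ratio = 1)
  expect_equal(unname(tr$H["H3"]), 0)
  expect_true(tr$geometry$flat)

  iv <- two_cell_feasible_interval()
  expect_lt(iv[1], 0.7)
  expect_gt(iv[2], 1.4)
  expect_error(two_cell_truth(10, iv[1] * 0.5), "feasible interval")
  expect_error(two_cell_truth(10, iv[2] * 1.5), "feasible interval")
  # interval endpoints themselves are constructible
  expect_s3_class(two_cell_truth(10, iv[1] * 1.05), "two_cell_truth")
})

test_that("interface geometry is self-consistent", {
  tr <- two_cell_truth(L = 15, pressure_ratio = 0.75)
  g <- tr$geometry
  # junction circle lies on all three spheres
  on_sphere <- function(cx, R) abs(sqrt((g$xj - cx)^2 + tr$d^2) - R)
  expect_lt(on_sphere(g$c1x, g$R1), 1e-9)
  expect_lt(on_sphere(g$c2x, g$R2), 1e-9)
  expect_lt(on_sphere(g$c3x, g$R3), 1e-9)
  # signed interface curvature equals the meridian tangent geometry
  expect_equal(abs(g$t3[1]), tr$d / g$R3, tolerance = 1e-12)
})

test_that("rendered probability peaks on the analytic surfaces", {
  tr <- two_cell_truth(L = 10, pressure_ratio = 0.8)
  vol <- render_two_cell(tr)
  expect_s3_class(vol, "prob_volume")
  expect_true(all(vol$data >= 0 & vol$data <= 1))
  off <- attr(vol, "offset")
  # march a ray along x through the middle of cap 1 and compare the voxel of
  # maximum probability with the analytic surface crossing
  yj <- round(off[2]) ; zj <- round(off[3])
  ray <- vol$data[, yj, zj]
  ray_x <- seq_along(ray) - 0.5
  pts <- cbind(ray_x - off[1], yj - 0.5 - off[2], zj - 0.5 - off[3])
  d <- two_cell_surface_distance(pts, tr)
  crossing <- ray_x[which.min(d[, 1])]
  lhs_peak <- ray_x[ray_x < off[1] - tr$d][which.max(ray[ray_x < off[1] - tr$d])]
  expect_lt(abs(lhs_peak - crossing), 0.5 + 1e-9)
  # compiled renderer agrees with the plain-R distance reference
  blur <- 0.15 * 10 # default width at L = 10
  dmin <- pmin(d[, 1], d[, 2], d[, 3])
  expect_equal(ray, exp(-dmin^2 / (2 * blur^2)) * (dmin <= 4 * blur),
               tolerance = 1e-12)
})

test_that("sphere fixture at the L = 10 scale spans about 45 voxels", {
  vol <- render_sphere(R = 22.5)
  labs <- segment_cells(vol)
  idx <- which(labs$labels == 1L, arr.ind = TRUE)
  extent <- apply(idx, 2, function(v) diff(range(v))) + 1
  expect_true(all(extent >= 43 & extent <= 47))
})

test_that("reprocess perturbation rasterises with a linear intensity decay", {
  pt <- matrix(c(10.2, 10.4, 10.6), 1)
  vol <- reprocess_volume(pt, dim = c(21, 21, 21), decay_range = 3)
  expect_equal(vol$data[11, 11, 11], 1)
  expect_equal(vol$data[14, 11, 11], 0)          # exactly 3 voxels away
  expect_equal(vol$data[13, 11, 11], 1 - 2 / 3)  # linear profile
  expect_equal(vol$data[11, 12, 11], 1 - 1 / 3)
  # support is a ball of radius 3: 7 voxels across each axis
  expect_equal(sum(vol$data[, 11, 11] > 0), 5)
  expect_error(reprocess_volume(matrix(nrow = 0, ncol = 3), c(5, 5, 5)),
               "empty")
})

test_that("generation is deterministic", {
  v1 <- render_two_cell(two_cell_truth(10, 0.9))
  v2 <- render_two_cell(two_cell_truth(10, 0.9))
  expect_identical(v1$data, v2$data)
})
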