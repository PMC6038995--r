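# Assembly and least-squares solution of the force-balance system.

test_that("a single sphere gives a square consistent system", {
  topo <- chain_topology(1)
  H <- tibble::tibble(face = 1L, H = -1 / 20) # inward normal on face {0,1}
  ang <- tibble::tibble(junction = integer(), theta_12 = numeric(),
                        theta_13 = numeric(), theta_23 = numeric())
  sys <- assemble_force_system(topo, H, ang)
  expect_equal(dim(sys$M), c(3L, 3L))
  fit <- solve_forces(sys)
  expect_equal(unname(fit$tensions$tension), 1, tolerance = 1e-12)
  # P1 - P0 = -2 H T = 2 T / R
  expect_equal(fit$pressures$pressure[2] - fit$pressures$pressure[1],
               2 / 20, tolerance = 1e-12)
  expect_lt(sum(fit$residuals^2), 1e-24)
})

test_that("the two-cell system has the documented shape and exact solution", {
  tr <- two_cell_truth(20, 0.8)
  topo <- chain_topology(2)
  sys <- assemble_force_system(
    topo,
    tibble::tibble(face = 1:3, H = as.numeric(tr$H)),
    tibble::tibble(junction = 1L, theta_12 = tr$angles[1],
                   theta_13 = tr$angles[2], theta_23 = tr$angles[3]))
  # (n_m + 2 n_j + 2) x (n_m + n_c + 1) = 7 x 6
  expect_equal(dim(sys$M), c(7L, 6L))
  fit <- solve_forces(sys)
  expect_equal(unname(fit$tensions$tension), unname(tr$tensions),
               tolerance = 1e-10)
  expect_equal(unname(fit$pressures$pressure), unname(tr$pressures),
               tolerance = 1e-10)
})

test_that("exact analytic inputs are recovered on randomized topologies", {
  for (seed in 1:5) {
    topo <- chain_topology(7)
    gt <- consistent_system(topo, seed = seed)
    sys <- assemble_force_system(topo, gt$curvatures, gt$angles)
    expect_equal(dim(sys$M),
                 c(topo$n_faces + 2 * topo$n_junctions + 2,
                   topo$n_faces + topo$n_cells + 1))
    fit <- solve_forces(sys)
    expect_lt(max(abs(fit$tensions$tension - gt$tension)), 1e-8)
    expect_lt(max(abs(fit$pressures$pressure - gt$pressure)), 1e-8)
    # gauge rows hold to solver precision on consistent data
    expect_lt(abs(sum(fit$tensions$tension) - topo$n_faces), 1e-9)
    expect_lt(abs(fit$pressures$pressure[1] - sys$P_b), 1e-9)
  }
})

test_that("missing inputs and rank deficiency raise errors", {
  topo <- chain_topology(2)
  gt <- consistent_system(topo, seed = 2)
  expect_error(assemble_force_system(topo, gt$curvatures[-2, ], gt$angles),
               "missing mean curvature.*2")
  expect_error(assemble_force_system(topo, gt$curvatures, gt$angles[0, ]),
               "missing averaged angles")
  sys <- assemble_force_system(topo, gt$curvatures, gt$angles)
  sys$M[, 2] <- 0 # destroy a pressure column
  expect_error(solve_forces(sys), "rank deficient")
})

test_that("membrane residuals follow the normalised Young-Laplace error", {
  topo <- chain_topology(1)
  ang <- tibble::tibble(junction = integer(), theta_12 = numeric(),
                        theta_13 = numeric(), theta_23 = numeric())
  sys0 <- assemble_force_system(topo, tibble::tibble(face = 1L, H = -0.05), ang)
  expect_equal(membrane_residuals(solve_forces(sys0))$rel_residual, 0,
               tolerance = 1e-12)
  # fix the solution from the clean system but perturb H by +10 percent:
  # relative error has the closed form (dP - 2 H' T)/(|dP| + |2 H' T|)
  fit <- solve_forces(sys0)
  fit$system$curvatures$H <- -0.055
  mres <- membrane_residuals(fit)
  dP <- fit$pressures$pressure[1] - fit$pressures$pressure[2]
  expected <- (dP - 2 * (-0.055) * 1) / (abs(dP) + abs(2 * 0.055))
  expect_equal(mres$rel_residual, expected, tolerance = 1e-12)
  expect_equal(mres$class, "outer")
})

test_that("junction residuals match the trigonometric closed form", {
  topo <- chain_topology(2)
  gt <- consistent_system(topo, seed = 3)
  sys <- assemble_force_system(topo, gt$curvatures, gt$angles)
  fit <- solve_forces(sys)
  expect_lt(junction_residuals(fit)$rel_residual, 1e-10)

  # equal tensions with angles (2pi/3 + delta, 2pi/3 - delta): the residual
  # vector norm is 2 |sin(delta/2)|
  delta <- 0.05
  fit$tensions$tension <- rep(1, 3)
  fit$system$angles <- tibble::tibble(
    junction = 1L, theta_12 = 2 * pi / 3 + delta,
    theta_13 = 2 * pi / 3 - delta, theta_23 = 2 * pi / 3)
  jr <- junction_residuals(fit)
  expect_equal(jr$abs_residual, 2 * abs(sin(delta / 2)), tolerance = 1e-12)
  expect_equal(jr$rel_residual, 2 * abs(sin(delta / 2)) / 3, tolerance = 1e-12)
})

test_that("sensitivity spectrum equals the pseudoinverse singular values", {
  # gauge-only identity system: all amplification factors are 1
  sys_id <- structure(list(M = diag(3), b = rep(0, 3)), class = "force_system")
  expect_equal(sensitivity_spectrum(sys_id)$lambda, rep(1, 3))

  # random full-rank M: lambdas match an explicit pseudoinverse SVD and
  # the eigenvalues of (M^T M)^-1 are lambda^2
  set.seed(43)
  M <- matrix(rnorm(42), 7, 6)
  sys <- structure(list(M = M, b = rep(0, 7)), class = "force_system")
  spec <- sensitivity_spectrum(sys)
  Mt <- solve(t(M) %*% M) %*% t(M)
  expect_equal(spec$lambda, sort(svd(Mt)$d, decreasing = TRUE),
               tolerance = 1e-10)
  lam2 <- sort(eigen(solve(t(M) %*% M), symmetric = TRUE)$values,
               decreasing = TRUE)
  expect_equal(spec$lambda^2, lam2, tolerance = 1e-8)
})

test_that("the dominant mode is the constant-pressure zero-tension direction", {
  tr <- two_cell_truth(20, 0.8)
  sys <- assemble_force_system(
    chain_topology(2),
    tibble::tibble(face = 1:3, H = as.numeric(tr$H)),
    tibble::tibble(junction = 1L, theta_12 = tr$angles[1],
                   theta_13 = tr$angles[2], theta_23 = tr$angles[3]))
  spec <- sensitivity_spectrum(sys)
  mode <- attr(spec, "dominant_mode")
  ref <- c(rep(1, 3), rep(0, 3)) / sqrt(3)
  expect_gt(abs(sum(mode * ref)), 0.99)
  expect_gt(spec$lambda[1], 1) # the mode that amplifies noise
  expect_true(all(diff(spec$lambda) <= 0))
})

test_that("coordinate rescaling divides curvatures and pressure differences", {
  topo <- chain_topology(2)
  gt <- consistent_system(topo, seed = 5)
  fit1 <- solve_forces(assemble_force_system(topo, gt$curvatures, gt$angles))
  half <- gt$curvatures
  half$H <- half$H / 2 # all coordinates scaled by 2
  fit2 <- solve_forces(assemble_force_system(topo, half, gt$angles))
  expect_equal(fit2$tensions$tension, fit1$tensions$tension, tolerance = 1e-10)
  expect_equal(fit2$pressures$pressure, fit1$pressures$pressure / 2,
               tolerance = 1e-10)
})

test_that("tidy and glance summarise a fit", {
  run <- shared_two_cell()
  td <- tidy(run$fit)
  expect_equal(nrow(td), 3 + 3) # P0..P2, T1..T3
  expect_setequal(td$type, c("pressure", "tension"))
  gl <- glance(run$fit)
  expect_equal(gl$n_faces, 3L)
  expect_lt(gl$mean_membrane_residual, 0.02)
  expect_gt(gl$lambda_max, 1)
})
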