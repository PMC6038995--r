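# Normal estimation, PCA smoothing, quadric fits and mean curvature.

test_that("normal-and-shift estimation matches its defining least squares", {
  # coplanar neighbours: normal is the plane normal, no shift
  nb <- as.matrix(plane_cloud(6)[, c("x", "y", "z")])
  res <- estimate_normal_and_shift(c(3, 3, 0), nb)
  expect_equal(abs(res$normal[3]), 1, tolerance = 1e-12)
  expect_equal(res$shift, 0, tolerance = 1e-12)

  # point displaced off the plane projects back onto it
  res <- estimate_normal_and_shift(c(3, 3, 0.4), nb)
  expect_equal(abs(res$shift), 0.4, tolerance = 1e-12)
  expect_equal(res$smoothed[3], 0, tolerance = 1e-12)

  # closed form vs direct numerical minimisation of the objective
  set.seed(7)
  nb <- matrix(rnorm(30), 10, 3)
  p <- c(0.1, -0.2, 0.3)
  res <- estimate_normal_and_shift(p, nb)
  obj <- function(par) {
    eta <- c(sin(par[1]) * cos(par[2]), sin(par[1]) * sin(par[2]), cos(par[1]))
    sum((sweep(nb, 2, p + par[3] * eta) %*% eta)^2)
  }
  opt <- optim(c(1, 1, 0), obj, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 1000))
  direct <- obj(c(acos(res$normal[3]),
                  atan2(res$normal[2], res$normal[1]), res$shift))
  expect_lt(direct, opt$value + 1e-10)

  # noisy sphere samples: estimated normal within 3 degrees of radial
  cl <- sphere_cloud(4000, R = 20, sigma = 0.2, seed = 11)
  sm <- smooth_cloud(cl, k = 50)
  rad <- unitize(as.matrix(sm[, c("x", "y", "z")]))
  dots <- abs(rowSums(rad * as.matrix(sm[, c("nx", "ny", "nz")])))
  expect_gt(stats::quantile(dots, 0.05), cos(deg2rad(3)))
  expect_gt(mean(dots), cos(deg2rad(2)))
})

test_that("compiled smoothing agrees with the reference implementation", {
  cl <- sphere_cloud(300, R = 15, sigma = 0.1, seed = 3)
  sm <- smooth_cloud(cl, k = 12)
  pts <- as.matrix(cl[, c("x", "y", "z")])
  nn <- embryoforce:::cpp_knn(pts, pts, 12, TRUE)
  for (i in c(1, 57, 200)) {
    ref <- estimate_normal_and_shift(pts[i, ], pts[nn$idx[i, ], ])
    expect_equal(abs(sum(ref$normal * unlist(sm[i, c("nx", "ny", "nz")]))), 1,
                 tolerance = 1e-9)
    expect_equal(ref$shift * sign(sum(ref$normal * unlist(sm[i, c("nx", "ny", "nz")]))),
                 sm$shift[i], tolerance = 1e-9)
  }
})

test_that("MST orientation makes normals globally consistent", {
  cl <- sphere_cloud(1500, R = 20, seed = 5)
  sm <- smooth_cloud(cl, k = 20)
  set.seed(9) # scramble signs
  flip <- sample(c(-1, 1), nrow(sm), replace = TRUE)
  sm$nx <- sm$nx * flip; sm$ny <- sm$ny * flip; sm$nz <- sm$nz * flip
  or <- orient_cloud_normals(sm)
  rad <- unitize(as.matrix(or[, c("x", "y", "z")]))
  dots <- rowSums(rad * as.matrix(or[, c("nx", "ny", "nz")]))
  expect_true(all(dots > 0) || all(dots < 0)) # closed convex surface

  pl <- smooth_cloud(plane_cloud(12), k = 8)
  pl$nz <- pl$nz * rep(c(1, -1), length.out = nrow(pl))
  po <- orient_cloud_normals(pl)
  expect_true(all(po$nz > 0.999) || all(po$nz < -0.999))
})

test_that("interface normals follow the global i -> j convention", {
  run <- shared_two_cell()
  off <- attr(render_two_cell(run$truth), "offset")
  # face 3 = {1,2}: normals point from cell 1 (low x) toward cell 2 (+x)
  f3 <- run$cloud[run$cloud$face == 3, ]
  expect_gt(mean(f3$nx), 0.9)
  # face 1 = {0,1}: normals point from exterior into cell 1 (toward centroid)
  f1 <- run$cloud[run$cloud$face == 1, ]
  ctr <- unlist(run$labels$cells[1, c("x", "y", "z")])
  toward <- unitize(matrix(ctr, nrow(f1), 3, byrow = TRUE) -
                      as.matrix(f1[, c("x", "y", "z")]))
  expect_gt(mean(rowSums(toward * as.matrix(f1[, c("nx", "ny", "nz")]))), 0.8)
})

test_that("quadric fits recover exact Taylor coefficients", {
  g <- expand.grid(u = seq(-1, 1, by = 0.2), v = seq(-1, 1, by = 0.2))
  # paraboloid z = (x^2 + y^2) / 2
  nb <- cbind(g$u, g$v, (g$u^2 + g$v^2) / 2)
  fit <- fit_quadric(c(0, 0, 0), nb, c(0, 0, 1))
  expect_equal(unname(fit$coef), c(0, 0, 1, 0, 1), tolerance = 1e-10)

  # plane z = 0.3 x
  nb <- cbind(g$u, g$v, 0.3 * g$u)
  fit <- fit_quadric(c(0, 0, 0), nb, c(0, 0, 1))
  expect_equal(unname(fit$coef), c(0.3, 0, 0, 0, 0), tolerance = 1e-10)

  # dense noiseless sphere patch of radius 10
  R <- 10
  phi <- seq(0, 2 * pi, length.out = 40)
  rr <- rep(seq(0.2, 1.4, by = 0.2), each = 40)
  nb <- cbind(rr * cos(phi), rr * sin(phi), R - sqrt(R^2 - rr^2))
  fit <- fit_quadric(c(0, 0, 0), nb, c(0, 0, 1))
  expect_equal(unname(fit$coef["c"]), 1 / R, tolerance = 0.01)
  expect_equal(unname(fit$coef["e"]), 1 / R, tolerance = 0.01)
  expect_lt(abs(fit$coef["d"]), 1e-3)

  # rank-deficient design (all points on a line)
  line <- cbind(seq(-1, 1, length.out = 10), 0, 0)
  expect_error(fit_quadric(c(0, 0, 0), line, c(0, 0, 1)), "degenerate")
})

test_that("Weingarten mean curvature follows the kappa = -n.dt/ds convention", {
  frame <- list(t1 = c(1, 0, 0), t2 = c(0, 1, 0), eta = c(0, 0, 1))
  mk <- function(coef) mean_curvature_from_fit(
    list(coef = setNames(coef, c("a", "b", "c", "d", "e")), frame = frame))

  # bowl towards +eta: kappa = -1/R; so a surface whose outward normal is
  # +eta (neighbours deviating towards -eta) has kappa = +1/R
  R <- 8
  expect_equal(mk(c(0, 0, 1 / R, 0, 1 / R))$kappa_m, -1 / R, tolerance = 1e-12)
  expect_equal(mk(c(0, 0, -1 / R, 0, -1 / R))$kappa_m, 1 / R, tolerance = 1e-12)

  # minimal-surface saddle
  expect_equal(mk(c(0, 0, 1 / R, 0, -1 / R))$kappa_m, 0, tolerance = 1e-12)

  # tilted patch: full first-fundamental-form correction, checked against the
  # closed-form mean curvature of the graph z = x + (x^2 + y^2)/2
  res <- mk(c(1, 0, 1, 0, 1))
  expect_equal(res$kappa_m, graph_mean_curvature(1, 0, 1, 0, 1),
               tolerance = 1e-12)
  # normal update: eta - (a t1)/sqrt(a^2+b^2+1), renormalised
  s <- sqrt(2)
  expect_equal(res$eta_updated, unitize(c(-1 / s, 0, 1)), tolerance = 1e-12)
})

test_that("batched curvature equals the per-point reference", {
  cl <- sphere_cloud(600, R = 25, seed = 13)
  sm <- smooth_cloud(cl, k = 20)
  or <- orient_cloud_normals(sm)
  cv <- estimate_curvature(or, k = 20)
  pts <- as.matrix(or[, c("x", "y", "z")])
  nn <- embryoforce:::cpp_knn(pts, pts, 20, TRUE)
  for (i in c(2, 111, 400)) {
    eta <- unlist(or[i, c("nx", "ny", "nz")])
    fit <- fit_quadric(pts[i, ], pts[nn$idx[i, ], ], eta)
    ref <- mean_curvature_from_fit(fit)
    expect_equal(cv$kappa[i], ref$kappa_m, tolerance = 1e-9)
    expect_equal(unlist(cv[i, c("nx", "ny", "nz")]), ref$eta_updated,
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("curvature matches closed forms on analytic surfaces", {
  # sphere with outward normals: positive mean curvature 1/R
  cl <- sphere_cloud(6000, R = 20, seed = 17)
  or <- orient_cloud_normals(smooth_cloud(cl, k = 50))
  cv <- estimate_curvature(or, k = 50)
  rad <- unitize(as.matrix(cv[, c("x", "y", "z")]))
  sgn <- sign(sum(rad * as.matrix(cv[, c("nx", "ny", "nz")])))
  H <- mean(cv$kappa[cv$valid]) * sgn # in the outward orientation
  expect_equal(H, 1 / 20, tolerance = 0.05)

  # cylinder with outward normals: mean curvature 1/(2R)
  set.seed(19)
  n <- 6000; R <- 15
  phi <- runif(n, 0, 2 * pi)
  cyl <- tibble::tibble(face = 1L, x = R * cos(phi), y = R * sin(phi),
                        z = runif(n, -20, 20),
                        nx = cos(phi), ny = sin(phi), nz = 0)
  cvc <- estimate_curvature(smooth_cloud(cyl, k = 50), k = 50)
  mid <- abs(cvc$z) < 12 & cvc$valid # away from the open ends
  expect_equal(mean(cvc$kappa[mid]), 1 / (2 * R), tolerance = 0.05)
})

test_that("face-average curvature is insensitive to K_C", {
  cl <- sphere_cloud(50000, R = 20, seed = 23)
  pts <- as.matrix(cl[, c("x", "y", "z")])
  rad <- unitize(pts)
  eval_pts <- seq(1, nrow(pts), length.out = 300)
  Hs <- vapply(c(50, 800, 3200), function(kc) {
    nn <- embryoforce:::cpp_knn(pts, pts[eval_pts, ], kc, FALSE)
    ks <- vapply(seq_along(eval_pts), function(j) {
      i <- eval_pts[j]
      fit <- fit_quadric(pts[i, ], pts[nn$idx[j, ], ], rad[i, ])
      mean_curvature_from_fit(fit)$kappa_m
    }, numeric(1))
    mean(ks)
  }, numeric(1))
  expect_lt(max(abs(Hs - Hs[1]) / abs(Hs[1])), 0.10)
})

test_that("smoothing contracts: a second pass moves points less", {
  cl <- sphere_cloud(3000, R = 20, sigma = 0.4, seed = 29)
  s1 <- smooth_cloud(cl, k = 50)
  s2 <- smooth_cloud(s1[, c("face", "x", "y", "z", "nx", "ny", "nz")], k = 50)
  expect_lt(mean(abs(s2$shift)), mean(abs(s1$shift)))
})

test_that("sphere pipeline recovers curvature within 5 percent", {
  run <- shared_sphere()
  H <- run$curvatures$H[1]
  # face {0,1} normals point into the cell, so H = -1/R
  expect_equal(H, -1 / 20, tolerance = 0.05)
})
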