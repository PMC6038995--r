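#' Gather junction point clouds from membrane faces
#'
#' A membrane point belongs to a junction when it lies within the distance
#' threshold `d_T` of both other member faces of that junction (point-to-cloud
#' distance = distance to the nearest point). The three member faces each
#' contribute their qualifying points.
#'
#' @param cloud smoothed membrane cloud (output of [smooth_cloud()] or later
#'   stages), with a `face` column.
#' @param topology an `embryo_topology` from [build_topology()].
#' @param d_T distance threshold in voxels (converted to physical units with
#'   the largest voxel dimension).
#' @param voxel_size physical voxel size used for the conversion.
#' @return Tibble `junction`, `face_from`, `x`, `y`, `z`, `point` (row index
#'   into `cloud`).
#' @export
extract_junction_points <- function(cloud, topology, d_T = 2,
                                    voxel_size = c(1, 1, 1)) {
  stopifnot(inherits(topology, "embryo_topology"))
  d_phys <- d_T * max(voxel_size)
  if (d_phys <= 0) abort("d_T must be positive")
  face_rows <- split(seq_len(nrow(cloud)), cloud$face)
  face_pts <- lapply(face_rows, function(r) as_xyz_matrix(cloud[r, ]))
  res <- list()
  for (ji in seq_len(nrow(topology$junctions))) {
    jr <- topology$junctions[ji, ]
    fs <- c(jr$f1, jr$f2, jr$f3)
    n_before <- length(res)
    for (a in 1:3) {
      others <- fs[-a]
      pa <- face_pts[[as.character(fs[a])]]
      d1 <- cpp_nn_dist(pa, face_pts[[as.character(others[1])]], d_phys)$dist
      d2 <- cpp_nn_dist(pa, face_pts[[as.character(others[2])]], d_phys)$dist
      keep <- is.finite(d1) & is.finite(d2)
      if (any(keep)) {
        rows <- face_rows[[as.character(fs[a])]][keep]
        res[[length(res) + 1]] <- tibble::tibble(
          junction = jr$junction, face_from = fs[a],
          x = pa[keep, 1], y = pa[keep, 2], z = pa[keep, 3],
          point = rows)
      }
    }
    if (length(res) == n_before) {
      abort(sprintf("junction %d: faces do not meet within d_T = %g voxels",
                    jr$junction, d_T))
    }
  }
  dplyr::bind_rows(res)
}

#' Thin a junction cloud into a curve
#'
#' Each junction point is replaced by the centroid of its `k_J` nearest
#' neighbours within the same junction cloud (single pass, neighbourhood
#' includes the point itself). This collapses the band of membrane points
#' around the junction onto a thin curve; the point count is unchanged.
#'
#' @param jpoints output of [extract_junction_points()].
#' @param k_J neighbourhood size; junctions with fewer points use all of them
#'   (with a warning).
#' @return `jpoints` with thinned coordinates (raw kept as `x0,y0,z0`).
#' @export
thin_junction_points <- function(jpoints, k_J = 50) {
  out <- jpoints
  out$x0 <- jpoints$x; out$y0 <- jpoints$y; out$z0 <- jpoints$z
  for (rows in split(seq_len(nrow(jpoints)), jpoints$junction)) {
    pts <- as_xyz_matrix(jpoints[rows, ])
    k <- k_J
    if (nrow(pts) < k_J) {
      warn(sprintf("junction %d has %d < K_J = %d points; using all",
                   jpoints$junction[rows[1]], nrow(pts), k_J))
      k <- nrow(pts)
    }
    nn <- cpp_knn(pts, pts, k, FALSE) # includes self
    for (a in 1:3) {
      coords <- matrix(pts[, a][nn$idx], nrow = nrow(pts))
      out[rows, c("x", "y", "z")[a]] <- rowMeans(coords)
    }
  }
  out
}

#' Junction tangent from the three membrane normals
#'
#' The junction tangent is approximated by
#' `m = (n1 x n2 + n2 x n3 + n3 x n1) / ||...||`, using the surface normals of
#' the three member faces evaluated at their closest points. Each cross
#' product is orthogonal to two of the normals, and all three normals are
#' orthogonal to the junction direction, so their sum estimates the tangent
#' robustly even when two normals are nearly parallel.
#'
#' @param n1,n2,n3 unit normals of the three faces.
#' @return Unit tangent vector.
#' @export
junction_tangent <- function(n1, n2, n3) {
  m <- vcross(n1, n2) + vcross(n2, n3) + vcross(n3, n1)
  nm <- sqrt(sum(m^2))
  if (nm < 1e-8) abort("tangent undefined: normal cross products cancel")
  m / nm
}

#' Dihedral sector angles between three membranes at a junction point
#'
#' Projects each face normal into the plane normal to the junction tangent
#' (`n'_i = n_i - m (m . n_i)`), forms the in-plane surface tangents
#' `t_i = m x n'_i`, and measures the three sector angles that the tangent
#' directions cut out of the normal plane. When `away1..3` are given
#' (directions from the junction point towards each membrane's interior), each
#' `t_i` is flipped to point along its membrane, which makes the three sectors
#' partition 2 pi exactly; otherwise the `t_i` are used as constructed.
#'
#' @param m unit junction tangent.
#' @param n1,n2,n3 unit face normals (any sign).
#' @param away1,away2,away3 optional pull directions used to disambiguate the
#'   tangent signs.
#' @return Named vector `theta_12`, `theta_13`, `theta_23` (radians).
#' @export
dihedral_angles <- function(m, n1, n2, n3,
                            away1 = NULL, away2 = NULL, away3 = NULL) {
  proj <- function(n) {
    np <- n - m * sum(m * n)
    nn <- sqrt(sum(np^2))
    if (nn < 1e-8) abort("membrane tangent to junction: projected normal vanishes")
    np / nn
  }
  ts <- list(vcross(m, proj(n1)), vcross(m, proj(n2)), vcross(m, proj(n3)))
  aways <- list(away1, away2, away3)
  for (i in 1:3) {
    if (!is.null(aways[[i]])) {
      aw <- aways[[i]] - m * sum(m * aways[[i]])
      if (sum(ts[[i]] * aw) < 0) ts[[i]] <- -ts[[i]]
    }
  }
  e1 <- ts[[1]]
  e2 <- vcross(m, e1)
  phi <- vapply(ts, function(t) atan2(sum(t * e2), sum(t * e1)), numeric(1))
  sector <- function(a, b, cc) {
    delta <- (phi[b] - phi[a]) %% (2 * pi)
    inside <- ((phi[cc] - phi[a]) %% (2 * pi)) < delta
    if (inside) 2 * pi - delta else delta
  }
  c(theta_12 = sector(1, 2, 3), theta_13 = sector(1, 3, 2),
    theta_23 = sector(2, 3, 1))
}

#' Evaluate fitted-surface normals at arbitrary nearby points
#'
#' Each membrane point of [estimate_curvature()] carries a local quadric
#' `z = a u + b v + c/2 u^2 + d u v + e/2 v^2` in its fit frame
#' `(t1, t2, eta)`. The surface normal of that patch at the in-frame
#' projection of a target point is `(-z_u t1 - z_v t2 + eta)`, normalised.
#' This transports a face's normal field to a junction point from an anchor
#' outside the junction zone, where local estimates are not distorted by the
#' overlap of the three membranes' intensity profiles.
#'
#' @param anchors,frame_normals,coefs anchor positions (n x 3), their fit
#'   frame normals and Taylor coefficient matrix (columns a, b, c, d, e).
#' @param targets n x 3 evaluation points.
#' @return n x 3 unit normals (hemisphere of the frame normals).
#' @export
quadric_normal_at <- function(anchors, frame_normals, coefs, targets) {
  eta <- as.matrix(frame_normals)
  # frame reconstruction must match the curvature fit: axis least aligned
  # with eta, orthogonalised, then t2 = eta x t1
  ax <- apply(abs(eta), 1, which.min)
  t1 <- matrix(0, nrow(eta), 3)
  t1[cbind(seq_len(nrow(eta)), ax)] <- 1
  t1 <- t1 - rowSums(t1 * eta) * eta
  t1 <- t1 / sqrt(rowSums(t1^2))
  t2 <- cbind(eta[, 2] * t1[, 3] - eta[, 3] * t1[, 2],
              eta[, 3] * t1[, 1] - eta[, 1] * t1[, 3],
              eta[, 1] * t1[, 2] - eta[, 2] * t1[, 1])
  rel <- as.matrix(targets) - as.matrix(anchors)
  u <- rowSums(rel * t1)
  v <- rowSums(rel * t2)
  zu <- coefs[, 1] + coefs[, 3] * u + coefs[, 4] * v
  zv <- coefs[, 2] + coefs[, 4] * u + coefs[, 5] * v
  n <- -zu * t1 - zv * t2 + eta
  n / sqrt(rowSums(n^2))
}

#' Per-point junction geometry: tangents and dihedral angles
#'
#' For each thinned junction point, evaluates the normal of each member face
#' at the junction point, estimates the junction tangent with
#' [junction_tangent()], and computes the three dihedral sector angles with
#' [dihedral_angles()], using the local direction towards each face (mean of
#' the `k_local` nearest face points) to resolve tangent signs.
#'
#' Face normals are taken from the nearest face point by default scheme
#' `anchor_dist = 0`; with a positive `anchor_dist` they are instead
#' transported from the nearest face point at least that far away (in
#' physical units) via its local quadric ([quadric_normal_at()]). Within a
#' few blur widths of a junction all three membranes contribute intensity, so
#' positions and local fits there are systematically distorted; anchoring the
#' normal evaluation outside that zone and extrapolating along the fitted
#' patch removes the bias at a cost that vanishes quadratically with surface
#' radius over anchor distance.
#'
#' Tangent signs along each junction are made consistent by nearest-neighbour
#' chaining of the thinned curve. The angle ordering follows the junction's
#' sorted face ids: `theta_12` is the angle between the sector tangents of
#' faces `f1` and `f2`, etc.
#'
#' @param jthin thinned junction points from [thin_junction_points()].
#' @param cloud the curvature-annotated membrane cloud.
#' @param topology the `embryo_topology`.
#' @param k_local face points averaged for the sign-resolving direction.
#' @param anchor_dist minimum anchor distance for the normal evaluation
#'   (physical units); 0 uses each face's nearest point directly.
#' @return Tibble with per-point tangent `mx,my,mz` and angles
#'   `theta_12`, `theta_13`, `theta_23`; dropped degenerate points counted in
#'   attribute `"dropped"`.
#' @export
junction_point_geometry <- function(jthin, cloud, topology, k_local = 20,
                                    anchor_dist = 12) {
  face_rows <- split(seq_len(nrow(cloud)), cloud$face)
  face_pts <- lapply(face_rows, function(r) as_xyz_matrix(cloud[r, ]))
  has_fit <- all(c("fnx", "qa") %in% names(cloud))
  out <- list()
  dropped <- 0L
  for (ji in seq_len(nrow(topology$junctions))) {
    jr <- topology$junctions[ji, ]
    fs <- c(jr$f1, jr$f2, jr$f3)
    rows <- which(jthin$junction == jr$junction)
    if (length(rows) == 0) next
    pts <- as_xyz_matrix(jthin[rows, ])
    # per face: normal evaluated at each junction point + pull direction
    near <- lapply(1:3, function(a) {
      fp <- face_pts[[as.character(fs[a])]]
      frows <- face_rows[[as.character(fs[a])]]
      k <- min(max(k_local, 800, ceiling(2.5 * (anchor_dist + 6)^2)), nrow(fp))
      nn <- cpp_knn(fp, pts, k, FALSE)
      aw <- vapply(1:3, function(cc) {
        rowMeans(matrix(fp[, cc][nn$idx[, seq_len(min(k_local, k)), drop = FALSE]],
                        nrow = nrow(pts))) - pts[, cc]
      }, numeric(nrow(pts)))
      valid <- if ("valid" %in% names(cloud)) cloud$valid[frows] else
        rep(TRUE, length(frows))
      n_anchor <- 8L
      picks <- matrix(NA_integer_, nrow(pts), n_anchor)
      for (p in seq_len(nrow(pts))) {
        cand <- nn$idx[p, ]
        ok <- valid[cand]
        far <- which(ok & nn$dist[p, ] >= anchor_dist)
        sel <- if (anchor_dist > 0 && length(far) > 0) {
          cand[far[seq_len(min(n_anchor, length(far)))]]
        } else if (any(ok)) cand[which(ok)[1]] else cand[1]
        picks[p, seq_along(sel)] <- sel
      }
      if (has_fit && anchor_dist > 0) {
        # average the transported normals over several anchors to suppress
        # per-anchor fit noise
        acc <- matrix(0, nrow(pts), 3)
        cnt <- numeric(nrow(pts))
        ref <- NULL
        for (s in seq_len(n_anchor)) {
          use <- which(!is.na(picks[, s]))
          if (length(use) == 0) next
          arows <- frows[picks[use, s]]
          nmat <- quadric_normal_at(
            cloud[arows, c("x", "y", "z")],
            cloud[arows, c("fnx", "fny", "fnz")],
            as.matrix(cloud[arows, c("qa", "qb", "qc", "qd", "qe")]),
            pts[use, , drop = FALSE])
          good <- is.finite(nmat[, 1])
          if (s == 1) {
            ref <- matrix(NA_real_, nrow(pts), 3)
            ref[use[good], ] <- nmat[good, ]
          } else if (!is.null(ref)) {
            # align hemispheres before averaging
            flip <- rowSums(nmat * ref[use, , drop = FALSE]) < 0
            flip[!is.finite(flip)] <- FALSE
            nmat[which(flip), ] <- -nmat[which(flip), ]
          }
          acc[use[good], ] <- acc[use[good], ] + nmat[good, ]
          cnt[use[good]] <- cnt[use[good]] + 1
        }
        bad <- cnt == 0
        nmat <- acc / pmax(cnt, 1)
        nmat <- nmat / sqrt(rowSums(nmat^2))
        if (any(bad)) {
          nmat[bad, ] <- as.matrix(cloud[frows[nn$idx[bad, 1]],
                                         c("nx", "ny", "nz")])
        }
      } else {
        nmat <- as.matrix(cloud[frows[nn$idx[, 1]], c("nx", "ny", "nz")])
      }
      list(normal = nmat, away = matrix(aw, ncol = 3))
    })
    res <- matrix(NA_real_, nrow(pts), 6)
    for (p in seq_len(nrow(pts))) {
      n1 <- near[[1]]$normal[p, ]
      n2 <- near[[2]]$normal[p, ]
      n3 <- near[[3]]$normal[p, ]
      m <- tryCatch(junction_tangent(n1, n2, n3), error = function(e) NULL)
      if (is.null(m)) { dropped <- dropped + 1L; next }
      th <- tryCatch(
        dihedral_angles(m, n1, n2, n3,
                        away1 = near[[1]]$away[p, ],
                        away2 = near[[2]]$away[p, ],
                        away3 = near[[3]]$away[p, ]),
        error = function(e) NULL)
      if (is.null(th)) { dropped <- dropped + 1L; next }
      res[p, ] <- c(m, th)
    }
    # canonicalise tangent signs along the chained curve
    ord <- chain_order(pts)
    prev <- NULL
    for (p in ord) {
      if (any(is.na(res[p, 1:3]))) next
      if (!is.null(prev) && sum(res[p, 1:3] * prev) < 0) {
        res[p, 1:3] <- -res[p, 1:3]
      }
      prev <- res[p, 1:3]
    }
    out[[length(out) + 1]] <- tibble::tibble(
      junction = jr$junction,
      x = pts[, 1], y = pts[, 2], z = pts[, 3],
      mx = res[, 1], my = res[, 2], mz = res[, 3],
      theta_12 = res[, 4], theta_13 = res[, 5], theta_23 = res[, 6])
  }
  geom <- dplyr::bind_rows(out) |> dplyr::filter(!is.na(.data$theta_12))
  attr(geom, "dropped") <- dropped
  geom
}

# greedy nearest-neighbour chaining of curve points; returns a visiting order
chain_order <- function(pts) {
  n <- nrow(pts)
  if (n <= 2) return(seq_len(n))
  k <- min(10, n - 1)
  nn <- cpp_knn(pts, pts, k, TRUE)
  visited <- logical(n)
  ord <- integer(n)
  cur <- 1L
  for (step in seq_len(n)) {
    ord[step] <- cur
    visited[cur] <- TRUE
    nxt <- nn$idx[cur, ][!visited[nn$idx[cur, ]]]
    if (length(nxt) > 0) {
      cur <- nxt[1]
    } else {
      rem <- which(!visited)
      if (length(rem) == 0) break
      d2 <- rowSums(sweep(pts[rem, , drop = FALSE], 2, pts[cur, ])^2)
      cur <- rem[which.min(d2)]
    }
  }
  ord
}

#' Junction-averaged dihedral angles
#'
#' Arithmetic means of the per-point sector angles along each junction, in the
#' consistent sorted-face ordering; these averages enter the junction balance
#' rows of the force system. The per-point spread is reported alongside.
#'
#' @param jgeom output of [junction_point_geometry()].
#' @return Tibble `junction`, `theta_12`, `theta_13`, `theta_23`, spreads and
#'   `n_points`.
#' @export
average_junction_angles <- function(jgeom) {
  if (nrow(jgeom) == 0) abort("no valid junction points")
  jgeom |>
    dplyr::group_by(.data$junction) |>
    dplyr::summarise(
      sd_12 = sd(.data$theta_12), sd_13 = sd(.data$theta_13),
      sd_23 = sd(.data$theta_23),
      theta_12 = mean(.data$theta_12),
      theta_13 = mean(.data$theta_13),
      theta_23 = mean(.data$theta_23),
      n_points = dplyr::n(), .groups = "drop") |>
    dplyr::relocate("junction", "theta_12", "theta_13", "theta_23")
}
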