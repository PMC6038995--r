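#' Watershed segmentation of a membrane probability volume
#'
#' Floods the probability landscape (Meyer's algorithm on a 256-level
#' quantisation, 26-connectivity) from regional-minimum seeds. Seed plateaus
#' whose centroids are closer than `min_seed_distance` voxels are merged
#' before flooding. The watershed front-collision voxels form the
#' one-voxel-thick membrane ridge, stored as label `-1`; regions are the
#' exterior (label 0) and cells `1..n_c`.
#'
#' Exterior detection: among border-touching regions whose mean probability is
#' below `exterior_threshold`, the largest is relabelled 0. More than one such
#' candidate is an error (it indicates a broken volume); none is an error too.
#' Cells are numbered by ascending centroid position (x, then y, then z) so
#' that labels are reproducible across resolutions.
#'
#' @param vol a [prob_volume()].
#' @param min_seed_distance minimum seed separation in voxels; closer seed
#'   plateaus are merged (single linkage on centroids).
#' @param exterior_threshold mean-probability guard for the exterior region.
#' @param seeds optional n x 3 integer matrix of voxel coordinates to use as
#'   cell seeds instead of automatic minima; an exterior seed is added at the
#'   lowest-probability border corner.
#' @return A `cell_labels` object: the label array (`-1` membrane ridge, `0`
#'   exterior, `1..n_c` cells), a `cells` tibble with voxel counts and
#'   physical centroids, and the voxel size.
#' @export
segment_cells <- function(vol, min_seed_distance = 5, exterior_threshold = 0.5,
                          seeds = NULL) {
  stopifnot(inherits(vol, "prob_volume"), min_seed_distance >= 1)
  dims <- dim(vol$data)
  nlevels <- 256L
  q <- cpp_quantize(vol$data, nlevels)

  if (is.null(seeds)) {
    mins <- cpp_regional_minima(q, as.integer(dims))
    if (mins$n == 0) abort("no cells found: volume has no regional minima")
    seedlab <- merge_close_seeds(mins, vol, dims, min_seed_distance)
    rm(mins)
  } else {
    seeds <- as.matrix(seeds)
    storage.mode(seeds) <- "integer"
    seedlab <- integer(prod(dims))
    lin <- (seeds[, 1] - 1L) + dims[1] * (seeds[, 2] - 1L) +
      dims[1] * dims[2] * (seeds[, 3] - 1L) + 1L
    seedlab[lin] <- seq_len(nrow(seeds))
    corner <- which.min(vol$data[1, 1, ]) # border column at (1,1,k)
    seedlab[(corner - 1L) * dims[1] * dims[2] + 1L] <- nrow(seeds) + 1L
  }
  nseed <- max(seedlab)
  if (nseed < 2) abort("no cells found: need at least an exterior and one cell seed")

  ws <- cpp_watershed(q, seedlab, as.integer(dims), nlevels)
  rm(q, seedlab)
  st <- cpp_label_stats(ws, vol$data, as.integer(dims), nseed)

  candidates <- which(st$border & st$mean_prob < exterior_threshold)
  if (length(candidates) == 0) {
    abort("no exterior region found (no border-touching low-probability region)")
  }
  if (length(candidates) > 1) {
    # several low-probability regions touch the border: ambiguous exterior
    abort(paste0("multiple exterior candidates: regions ",
                 paste(candidates, collapse = ", "),
                 " (sizes ", paste(st$n_voxels[candidates], collapse = ", "), ")"))
  }
  exterior <- candidates[1]

  cells_old <- setdiff(seq_len(nseed), exterior)
  ord <- order(st$cx[cells_old], st$cy[cells_old], st$cz[cells_old])
  cells_old <- cells_old[ord]
  map <- integer(nseed)
  map[exterior] <- 0L
  map[cells_old] <- seq_along(cells_old)


  labels <- cpp_apply_label_map(ws, map)
  rm(ws)
  dim(labels) <- dims

  vs <- vol$voxel_size
  cells <- tibble::tibble(
    cell = seq_along(cells_old),
    n_voxels = st$n_voxels[cells_old],
    volume = st$n_voxels[cells_old] * prod(vs),
    x = st$cx[cells_old] * vs[1],
    y = st$cy[cells_old] * vs[2],
    z = st$cz[cells_old] * vs[3]
  )

  structure(list(
    labels = labels,
    voxel_size = vs,
    n_cells = length(cells_old),
    cells = cells,
    exterior = tibble::tibble(n_voxels = st$n_voxels[exterior],
                              mean_prob = st$mean_prob[exterior])
  ), class = "cell_labels")
}

# Single-linkage merge of seed plateaus whose voxel sets come within
# min_seed_distance of each other (set distance on plateau boundary voxels).
merge_close_seeds <- function(mins, vol, dims, min_seed_distance) {
  n <- mins$n
  group <- seq_len(n)
  if (n > 1) {
    bd <- cpp_component_boundaries(mins$labels, as.integer(dims))
    pts <- cbind(bd$i, bd$j, bd$k)
    storage.mode(pts) <- "double"
    by_comp <- split(seq_len(nrow(pts)), bd$label)
    parent <- seq_len(n)
    find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
    comps <- as.integer(names(by_comp))
    for (ai in seq_along(comps)) {
      for (bi in seq_len(ai - 1L)) {
        pa <- pts[by_comp[[ai]], , drop = FALSE]
        pb <- pts[by_comp[[bi]], , drop = FALSE]
        if (ai != bi &&
            any(is.finite(cpp_nn_dist(pa, pb, min_seed_distance)$dist))) {
          ra <- find(comps[ai]); rb <- find(comps[bi])
          if (ra != rb) parent[ra] <- rb
        }
      }
    }
    roots <- vapply(seq_len(n), find, integer(1))
    group <- match(roots, unique(roots))
  }
  cpp_apply_label_map(mins$labels, as.integer(group))
}

#' @export
print.cell_labels <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<cell_labels> %d x %d x %d voxels, %d cell(s) + exterior\n",
              d[1], d[2], d[3], x$n_cells))
  print(x$cells)
  invisible(x)
}

#' Extract one-voxel-thick membrane faces from a label volume
#'
#' A membrane-ridge voxel belongs to face `{i, j}` when its 26-neighbourhood
#' contains exactly the two region labels i and j (exterior 0 allowed). Ridge
#' voxels seeing three or more labels are junction-candidate voxels: they are
#' assigned to no face and retained to seed junction topology. Faces are
#' numbered by lexicographic order of their sorted cell pair.
#'
#' @param labels a `cell_labels` object from [segment_cells()].
#' @return A `face_map`: tibbles `faces` (face id, cell pair, voxel count),
#'   `voxels` (face voxel coordinates) and `junction_candidates`.
#' @export
extract_membrane_faces <- function(labels) {
  stopifnot(inherits(labels, "cell_labels"))
  dims <- dim(labels$labels)
  cl <- cpp_face_classify(labels$labels, as.integer(dims))

  vox <- tibble::tibble(cell_i = cl$cell_a, cell_j = cl$cell_b,
                        i = cl$face_i, j = cl$face_j, k = cl$face_k)
  faces <- vox |>
    dplyr::count(.data$cell_i, .data$cell_j, name = "n_voxels") |>
    dplyr::arrange(.data$cell_i, .data$cell_j) |>
    dplyr::mutate(face = dplyr::row_number(), .before = 1)
  vox <- vox |>
    dplyr::inner_join(faces[, c("face", "cell_i", "cell_j")],
                      by = c("cell_i", "cell_j")) |>
    dplyr::relocate("face")

  jc <- tibble::tibble(i = cl$junc_i, j = cl$junc_j, k = cl$junc_k,
                       lab1 = cl$lab1, lab2 = cl$lab2, lab3 = cl$lab3,
                       n_labels = cl$nlab)

  structure(list(
    faces = faces,
    voxels = vox,
    junction_candidates = jc,
    orphans = cl$orphans,
    voxel_size = labels$voxel_size,
    dim = dims,
    n_cells = labels$n_cells
  ), class = "face_map")
}

#' @export
print.face_map <- function(x, ...) {
  cat(sprintf("<face_map> %d faces, %d membrane voxels, %d junction-candidate voxels\n",
              nrow(x$faces), nrow(x$voxels), nrow(x$junction_candidates)))
  print(x$faces)
  invisible(x)
}

#' Build the face/junction topology of the embryo
#'
#' Enumerates triple junctions from junction-candidate voxels: a candidate
#' seeing exactly the three region labels `{a, b, c}` votes for the junction
#' formed by faces `{a,b}, {a,c}, {b,c}`. Junctions supported by fewer than
#' `min_voxels` candidates are dropped as noise; candidates seeing four or
#' more labels (four-fold vertices) do not define triple junctions.
#'
#' The returned topology is checked against the overdeterminedness inequality
#' `n_m + n_c + 1 <= n_m + 2 n_j + 2` that makes the force-balance system
#' solvable in the least-squares sense.
#'
#' @param face_map a `face_map` from [extract_membrane_faces()].
#' @param min_voxels minimum candidate-voxel support per junction.
#' @return An `embryo_topology` with counts and tibbles `faces`, `junctions`
#'   (face triples `f1 < f2 < f3` and their cell triple).
#' @export
build_topology <- function(face_map, min_voxels = 1) {
  stopifnot(inherits(face_map, "face_map"))
  if (nrow(face_map$faces) == 0) abort("empty face map")
  faces <- face_map$faces
  jc <- face_map$junction_candidates |> dplyr::filter(.data$n_labels == 3)

  face_id <- function(a, b) {
    key <- paste(pmin(a, b), pmax(a, b))
    idx <- match(key, paste(faces$cell_i, faces$cell_j))
    faces$face[idx]
  }

  junctions <- jc |>
    dplyr::count(.data$lab1, .data$lab2, .data$lab3, name = "n_voxels") |>
    dplyr::filter(.data$n_voxels >= min_voxels) |>
    dplyr::mutate(
      f1 = face_id(.data$lab1, .data$lab2),
      f2 = face_id(.data$lab1, .data$lab3),
      f3 = face_id(.data$lab2, .data$lab3)
    )
  if (any(is.na(junctions$f1) | is.na(junctions$f2) | is.na(junctions$f3))) {
    abort("junction candidate refers to a cell pair with no extracted face")
  }
  junctions <- if (nrow(junctions) == 0) {
    tibble::tibble(junction = integer(), f1 = integer(), f2 = integer(),
                   f3 = integer(), cell_1 = integer(), cell_2 = integer(),
                   cell_3 = integer(), n_voxels = integer())
  } else {
    junctions |>
      dplyr::rowwise() |>
      dplyr::mutate(fa = min(.data$f1, .data$f2, .data$f3),
                    fc = max(.data$f1, .data$f2, .data$f3),
                    fb = sum(.data$f1, .data$f2, .data$f3) - .data$fa - .data$fc) |>
      dplyr::ungroup() |>
      dplyr::transmute(junction = dplyr::row_number(),
                       f1 = .data$fa, f2 = .data$fb, f3 = .data$fc,
                       cell_1 = .data$lab1, cell_2 = .data$lab2,
                       cell_3 = .data$lab3, n_voxels = .data$n_voxels)
  }

  n_c <- face_map$n_cells
  n_m <- nrow(faces)
  n_j <- nrow(junctions)
  if (!(n_m + n_c + 1 <= n_m + 2 * n_j + 2)) {
    abort(sprintf(
      "topology fails the overdeterminedness inequality (n_c = %d, n_j = %d): broken junction extraction",
      n_c, n_j))
  }
  structure(list(
    n_cells = n_c, n_faces = n_m, n_junctions = n_j,
    faces = faces, junctions = junctions
  ), class = "embryo_topology")
}

#' @export
print.embryo_topology <- function(x, ...) {
  cat(sprintf("<embryo_topology> n_c = %d cells, n_m = %d faces, n_j = %d junctions\n",
              x$n_cells, x$n_faces, x$n_junctions))
  invisible(x)
}
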