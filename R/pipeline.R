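#' Run the full reconstruction and force-inference pipeline
#'
#' Chains every stage on a probability volume: watershed segmentation,
#' membrane-face extraction and topology, PCA smoothing with oriented
#' normals, quadric mean curvatures, junction extraction/thinning/angles,
#' assembly and least-squares solution of the force-balance system, residual
#' reports, the sensitivity spectrum, and per-cell stress and shape tensors.
#' A manifest capturing all parameters, per-stage entity counts and wall
#' times is attached; identical inputs and parameters give identical outputs
#' (no stage is stochastic).
#'
#' @param vol a [prob_volume()] (or anything [prob_volume()] accepts).
#' @param k_s,k_c smoothing / curvature neighbourhood sizes (`K_S`, `K_C`).
#' @param k_j junction thinning neighbourhood (`K_J`).
#' @param d_T junction distance threshold, voxels.
#' @param anchor_dist anchor distance (voxels) for junction normal
#'   evaluation; see [junction_point_geometry()].
#' @param min_seed_distance,exterior_threshold segmentation parameters.
#' @param refine_crest refine membrane points to the sub-voxel probability
#'   crest before smoothing (see [refine_cloud_crest()]).
#' @param P_b exterior pressure.
#' @param length_scale physical length per voxel for the pressure scale.
#' @param tensors compute stress/shape tensors (skippable for speed).
#' @param out_dir if non-NULL, write stage outputs (CSV/JSON/TIFF) there.
#' @param verbose print stage progress.
#' @return A `pipeline_run` list with every stage result and `manifest`.
#' @export
run_pipeline <- function(vol, k_s = 50, k_c = 50, k_j = 50, d_T = 2,
                         anchor_dist = 12, min_seed_distance = 5,
                         exterior_threshold = 0.5, refine_crest = TRUE,
                         P_b = 0, length_scale = 1, tensors = TRUE,
                         out_dir = NULL, verbose = FALSE) {
  stopifnot(k_s >= 4, k_c >= 5, k_j >= 1, d_T > 0)
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- round(t1 - tail(c(t0, cumsum(timings) + t0), 1), 3)
    if (verbose) inform(sprintf("[%s] %.1fs", stage, timings[[stage]]))
  }

  labels <- segment_cells(vol, min_seed_distance = min_seed_distance,
                          exterior_threshold = exterior_threshold)
  tick("segment")
  face_map <- extract_membrane_faces(labels)
  topology <- build_topology(face_map)
  tick("topology")
  cloud <- reconstruct_surfaces(face_map, labels,
                                vol = if (refine_crest) vol else NULL,
                                k_s = k_s, k_c = k_c)
  curvatures <- face_curvatures(cloud)
  tick("surfaces")
  if (topology$n_junctions > 0) {
    jpoints <- extract_junction_points(cloud, topology, d_T = d_T,
                                       voxel_size = vol$voxel_size)
    jthin <- thin_junction_points(jpoints, k_J = k_j)
    jgeom <- junction_point_geometry(jthin, cloud, topology,
                                     anchor_dist = anchor_dist *
                                       max(vol$voxel_size))
    angles <- average_junction_angles(jgeom)
  } else {
    jpoints <- jthin <- jgeom <- NULL
    angles <- tibble::tibble(junction = integer(), theta_12 = numeric(),
                             theta_13 = numeric(), theta_23 = numeric())
  }
  tick("junctions")
  system <- assemble_force_system(topology, curvatures, angles,
                                  P_b = P_b, length_scale = length_scale)
  fit <- solve_forces(system)
  mres <- membrane_residuals(fit)
  jres <- junction_residuals(fit)
  spectrum <- sensitivity_spectrum(system)
  tick("inference")
  stress <- shape <- NULL
  if (tensors) {
    cloud <- point_area_weights(cloud)
    stress <- cell_stress_tensors(fit, cloud, labels)
    shape <- cell_shape_tensors(cloud, labels)
    tick("tensors")
  }

  manifest <- list(
    package = as.character(utils::packageVersion("embryoforce")),
    parameters = list(k_s = k_s, k_c = k_c, k_j = k_j, d_T = d_T,
                      min_seed_distance = min_seed_distance,
                      exterior_threshold = exterior_threshold,
                      P_b = P_b, length_scale = length_scale),
    voxel_size = vol$voxel_size,
    dim = dim(vol$data),
    counts = list(n_cells = topology$n_cells, n_faces = topology$n_faces,
                  n_junctions = topology$n_junctions,
                  n_membrane_points = nrow(cloud),
                  n_junction_points = if (is.null(jgeom)) 0L else nrow(jgeom)),
    timings = as.list(timings)
  )

  run <- structure(list(
    labels = labels, face_map = face_map, topology = topology,
    cloud = cloud, junction_points = jpoints, junction_geometry = jgeom,
    angles = angles, curvatures = curvatures,
    system = system, fit = fit,
    membrane_residuals = mres, junction_residuals = jres,
    spectrum = spectrum, stress = stress, shape = shape,
    manifest = manifest
  ), class = "pipeline_run")
  if (!is.null(out_dir)) write_pipeline_outputs(run, out_dir)
  run
}

#' @export
print.pipeline_run <- function(x, ...) {
  m <- x$manifest$counts
  cat(sprintf("<pipeline_run> n_c = %d, n_m = %d, n_j = %d (%d membrane points)\n",
              m$n_cells, m$n_faces, m$n_junctions, m$n_membrane_points))
  print(x$fit)
  invisible(x)
}

#' Run the pipeline on a rendered two-cell configuration
#'
#' Generates the analytic ground truth, renders its probability volume, runs
#' [run_pipeline()], and compares the inferred quantities against the truth.
#'
#' @inheritParams two_cell_truth
#' @inheritParams render_two_cell
#' @param ... passed to [run_pipeline()].
#' @return A `pipeline_run` with extra elements `truth` and `errors`
#'   (tension error, pressure-ratio error, angle error, curvature errors).
#' @export
run_two_cell <- function(L = 20, pressure_ratio = 0.8, blur_width = NULL, ...) {
  truth <- two_cell_truth(L, pressure_ratio)
  if (is.null(blur_width)) blur_width <- 0.15 * L
  vol <- render_two_cell(truth, blur_width = blur_width)
  args <- list(...)
  if (is.null(args$anchor_dist)) args$anchor_dist <- 8 * blur_width
  run <- do.call(run_pipeline, c(list(vol), args))
  run$truth <- truth
  run$errors <- two_cell_errors(run, truth)
  run
}

#' Compare a two-cell pipeline run against its analytic truth
#'
#' Cells are matched by the canonical ordering (cell 1 = larger cap at lower
#' x, which the centroid-ordered labelling reproduces); faces follow the
#' sorted-pair order {0,1}, {0,2}, {1,2}.
#'
#' @param run a `pipeline_run` on a rendered two-cell volume.
#' @param truth the matching [two_cell_truth()].
#' @return List of scalar error summaries.
#' @export
two_cell_errors <- function(run, truth) {
  stopifnot(run$topology$n_faces == 3, run$topology$n_cells == 2)
  T_hat <- run$fit$tensions$tension
  T_true <- truth$tensions
  p <- run$fit$pressures$pressure
  H_hat <- run$curvatures$H
  th_hat <- unlist(run$angles[1, c("theta_12", "theta_13", "theta_23")])
  list(
    tension_error = sum(abs(T_hat - T_true)),
    pressure_ratio = (p[3] - p[1]) / (p[2] - p[1]),
    pressure_ratio_error = (p[3] - p[1]) / (p[2] - p[1]) - truth$pressure_ratio,
    angle_error = sum(abs(th_hat - truth$angles)) / (2 * pi),
    H_error = abs(H_hat - truth$H),
    H3 = H_hat[3],
    membrane_residual = mean(abs(run$membrane_residuals$rel_residual)),
    junction_residual = mean(run$junction_residuals$rel_residual)
  )
}

#' Write pipeline outputs to a directory
#'
#' Emits the label volume (16-bit TIFF, membrane ridge as the top label),
#' face map and solution/residual/spectrum tables as CSV, the junction curves
#' as CSV, the membrane cloud as PLY, and the manifest as JSON.
#'
#' @param run a `pipeline_run`.
#' @param dir output directory (created if needed).
#' @export
write_pipeline_outputs <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  w(run$face_map$faces, "faces.csv")
  w(run$face_map$voxels, "face_voxels.csv")
  w(run$curvatures, "curvatures.csv")
  w(run$angles, "junction_angles.csv")
  w(tidy(run$fit), "solution.csv")
  w(run$membrane_residuals, "membrane_residuals.csv")
  w(run$junction_residuals, "junction_residuals.csv")
  w(as.data.frame(run$spectrum), "spectrum.csv")
  if (!is.null(run$junction_geometry)) w(run$junction_geometry, "junction_curves.csv")
  if (!is.null(run$stress)) {
    w(dplyr::select(run$stress, -"vectors"), "stress_tensors.csv")
    w(dplyr::select(run$shape, -"vectors"), "shape_tensors.csv")
  }
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  if (requireNamespace("tiff", quietly = TRUE)) {
    lab <- run$labels$labels
    lab[lab < 0] <- run$labels$n_cells + 1L
    write_volume_tiff(lab, file.path(dir, "labels.tif"))
  }
  write_cloud_ply(run$cloud, file.path(dir, "membrane_cloud.ply"))
  invisible(dir)
}

#' Pipeline run configuration
#'
#' A validated, serialisable bundle of every stage parameter plus the input
#' specification: either a TIFF volume path (`input`) or a simulation spec
#' (`simulate = list(mode, L, pressure_ratio, radius, blur_width)`). Configs
#' round-trip losslessly through JSON, so a run is fully described by its
#' config and the package version.
#'
#' @param input path to a single-channel TIFF probability volume, or NULL.
#' @param simulate simulation spec list (used when `input` is NULL).
#' @param voxel_size physical voxel dimensions of the input.
#' @param k_s,k_c,k_j,d_T,anchor_dist,min_seed_distance,exterior_threshold,refine_crest,P_b,length_scale
#'   stage parameters, as in [run_pipeline()].
#' @param seed integer seed recorded in the manifest.
#' @param out_dir output directory or NULL.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, simulate = NULL,
                            voxel_size = c(1, 1, 1),
                            k_s = 50, k_c = 50, k_j = 50, d_T = 2,
                            anchor_dist = 12, min_seed_distance = 5,
                            exterior_threshold = 0.5, refine_crest = TRUE,
                            P_b = 0, length_scale = 1, seed = 1L,
                            out_dir = NULL) {
  if (is.null(input) && is.null(simulate)) {
    abort("config needs either an input path or a simulation spec")
  }
  if (k_s < 4 || k_c < 4 || k_j < 4) abort("all K parameters must be >= 4")
  if (d_T <= 0) abort("d_T must be positive")
  if (length(voxel_size) == 1) voxel_size <- rep(voxel_size, 3)
  structure(list(
    input = input, simulate = simulate, voxel_size = as.numeric(voxel_size),
    k_s = as.integer(k_s), k_c = as.integer(k_c), k_j = as.integer(k_j),
    d_T = d_T, anchor_dist = anchor_dist,
    min_seed_distance = min_seed_distance,
    exterior_threshold = exterior_threshold,
    refine_crest = isTRUE(refine_crest), P_b = P_b,
    length_scale = length_scale, seed = as.integer(seed), out_dir = out_dir
  ), class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path JSON file path.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw[!vapply(raw, is.null, logical(1))])
}

#' Execute a pipeline configuration
#'
#' Loads or simulates the configured input volume and runs [run_pipeline()]
#' with the configured parameters.
#'
#' @param config a [pipeline_config()].
#' @param verbose print stage progress.
#' @return A `pipeline_run`.
#' @export
run_pipeline_config <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  if (!is.null(config$input)) {
    vol <- read_volume_tiff(config$input, voxel_size = config$voxel_size)
  } else {
    sim <- config$simulate
    vol <- if (identical(sim$mode, "sphere")) {
      render_sphere(R = sim$radius %||% 20,
                    blur_width = sim$blur_width %||% 1.5)
    } else {
      L <- sim$L %||% 20
      render_two_cell(two_cell_truth(L, sim$pressure_ratio %||% 0.8),
                      blur_width = sim$blur_width %||% (0.15 * L))
    }
  }
  run <- run_pipeline(vol, k_s = config$k_s, k_c = config$k_c,
                      k_j = config$k_j, d_T = config$d_T,
                      anchor_dist = config$anchor_dist,
                      min_seed_distance = config$min_seed_distance,
                      exterior_threshold = config$exterior_threshold,
                      refine_crest = config$refine_crest,
                      P_b = config$P_b, length_scale = config$length_scale,
                      out_dir = config$out_dir, verbose = verbose)
  run$manifest$config <- unclass(config)
  run
}
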