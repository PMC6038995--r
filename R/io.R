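#' Write a point cloud as ASCII PLY
#'
#' Positions plus, when present, per-point normals and mean curvature (as a
#' `quality` scalar property), readable by standard point-cloud viewers.
#'
#' @param cloud tibble with `x`, `y`, `z` and optionally `nx,ny,nz`, `kappa`.
#' @param path output file.
#' @export
write_cloud_ply <- function(cloud, path) {
  has_n <- all(c("nx", "ny", "nz") %in% names(cloud))
  has_k <- "kappa" %in% names(cloud)
  n <- nrow(cloud)
  hdr <- c("ply", "format ascii 1.0",
           sprintf("element vertex %d", n),
           "property float x", "property float y", "property float z")
  cols <- c("x", "y", "z")
  if (has_n) {
    hdr <- c(hdr, "property float nx", "property float ny", "property float nz")
    cols <- c(cols, "nx", "ny", "nz")
  }
  if (has_k) {
    hdr <- c(hdr, "property float quality")
    cols <- c(cols, "kappa")
  }
  hdr <- c(hdr, "end_header")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  m <- as.matrix(cloud[, cols])
  m[is.na(m)] <- 0
  utils::write.table(format(m, trim = TRUE, digits = 8, scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}
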