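# Legacy-VTK ASCII unstructured-grid I/O for labelled tet meshes: cells as
# VTK_TETRA with an integer cell-data array "region", landmarks and
# attachment points as field data. Point-data scalar fields (e.g. stress
# snapshots) can be attached on write.

#' Write a labelled tet mesh as legacy VTK
#' @param mesh A `labelled_tet_mesh`.
#' @param path Output file.
#' @param point_data Optional named list of per-node numeric vectors.
#' @export
write_mesh_vtk <- function(mesh, path, point_data = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes); e <- nrow(mesh$elems)
  writeLines(c("# vtk DataFile Version 3.0",
               "jawgrowth labelled tetrahedral mesh",
               "ASCII", "DATASET UNSTRUCTURED_GRID"), con)
  writeLines(sprintf("POINTS %d double", n), con)
  writeLines(apply(format(mesh$nodes, digits = 10, trim = TRUE,
                          scientific = FALSE), 1, paste, collapse = " "), con)
  writeLines(sprintf("CELLS %d %d", e, 5 * e), con)
  writeLines(paste(4, mesh$elems[, 1] - 1, mesh$elems[, 2] - 1,
                   mesh$elems[, 3] - 1, mesh$elems[, 4] - 1), con)
  writeLines(sprintf("CELL_TYPES %d", e), con)
  writeLines(rep("10", e), con)
  writeLines(sprintf("CELL_DATA %d", e), con)
  writeLines("SCALARS region int 1", con)
  writeLines("LOOKUP_TABLE default", con)
  writeLines(as.character(mesh$region), con)
  if (!is.null(point_data)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (nm in names(point_data)) {
      writeLines(sprintf("SCALARS %s double 1", nm), con)
      writeLines("LOOKUP_TABLE default", con)
      writeLines(format(point_data[[nm]], digits = 10, trim = TRUE), con)
    }
  }
  # landmarks / attachments as a JSON sidecar (legacy VTK has no clean slot)
  meta <- list(region_labels = mesh$region_labels, h = mesh$h,
               landmarks = mesh$landmarks,
               attachments = if (!is.null(mesh$attachments))
                 as.data.frame(mesh$attachments) else NULL)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_mesh_vtk
#' @export
read_mesh_vtk <- function(path) {
  lines <- readLines(path)
  ip <- grep("^POINTS", lines)[1]
  n <- as.integer(strsplit(lines[ip], " +")[[1]][2])
  pts <- utils::read.table(text = lines[(ip + 1):(ip + n)])
  ic <- grep("^CELLS", lines)[1]
  e <- as.integer(strsplit(lines[ic], " +")[[1]][2])
  cells <- utils::read.table(text = lines[(ic + 1):(ic + e)])
  ir <- grep("^SCALARS region", lines)[1]
  region <- as.integer(lines[(ir + 2):(ir + 1 + e)])
  mesh <- list(nodes = as.matrix(pts), elems = as.matrix(cells[, 2:5]) + 1L,
               region = region, frame = default_frame())
  meta_path <- paste0(path, ".json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    mesh$region_labels <- meta$region_labels
    mesh$h <- meta$h
    mesh$landmarks <- lapply(meta$landmarks, as.numeric)
    if (!is.null(meta$attachments)) {
      mesh$attachments <- tibble::as_tibble(meta$attachments)
    }
  } else {
    mesh$region_labels <- c("MC", "PQ", "CH", "interzone")
  }
  dimnames(mesh$nodes) <- NULL
  dimnames(mesh$elems) <- NULL
  class(mesh) <- "labelled_tet_mesh"
  mesh
}

#' Write a stress history as a VTK point-data series
#' @param history A `stress_history`.
#' @param mesh The mesh it was computed on.
#' @param dir Output directory (one file per increment).
#' @export
write_stress_history_vtk <- function(history, mesh, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (k in seq_along(history$increments)) {
    write_mesh_vtk(mesh, file.path(dir, sprintf("increment_%02d.vtk", k)),
                   point_data = list(sigma_h = history$increments[[k]]))
  }
  invisible(dir)
}
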