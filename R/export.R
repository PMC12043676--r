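#' Write a grid-shaped scalar field as legacy ASCII VTK
#'
#' Structured-points dataset with the voxel spacing (mm) and origin recorded
#' in the header; values are written as cell-centred point data so any VTK
#' viewer renders them directly.
#'
#' @param arr array shaped like the grid (e.g. `phi`, `|E|`, AF).
#' @param grid the `voxel_grid`.
#' @param path output `.vtk` file.
#' @param name scalar name embedded in the file.
#' @export
write_vtk <- function(arr, grid, path, name = "scalar") {
  stopifnot(all(dim(arr) == grid$shape))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               sprintf("tensdepth %s (spacing in mm)", name),
               "ASCII", "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", grid$shape[1], grid$shape[2], grid$shape[3]),
               sprintf("ORIGIN %g %g %g",
                       grid$origin[1] + grid$spacing[1] / 2,
                       grid$origin[2] + grid$spacing[2] / 2,
                       grid$origin[3] + grid$spacing[3] / 2),
               sprintf("SPACING %g %g %g", grid$spacing[1], grid$spacing[2], grid$spacing[3]),
               sprintf("POINT_DATA %d", length(arr)),
               sprintf("SCALARS %s double 1", name),
               "LOOKUP_TABLE default"), con)
  writeLines(paste(format(as.vector(arr), trim = TRUE, digits = 9)), con)
  invisible(path)
}

#' Export a membrane trace as CSV
#'
#' Time (ms) by node voltage matrix (mV), one column per node of Ranvier.
#'
#' @param trace a `membrane_trace`.
#' @param path output file.
#' @export
write_trace_csv <- function(trace, path) {
  tab <- data.frame(time_ms = trace$time_ms, trace$V)
  names(tab) <- c("time_ms", sprintf("node_%03d", seq_len(ncol(trace$V))))
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Dump axon parameters as JSON for auditability
#' @param axon an `mrg_axon`.
#' @param path output file.
#' @export
write_axon_json <- function(axon, path) {
  jsonlite::write_json(unclass(axon), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
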