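# Snapshot output: legacy ASCII VTK unstructured grids with point data,
# readable by ParaView/VisIt and by meshio-style loaders.

#' Write a mesh snapshot with point-data fields
#'
#' @param mesh a `ws_mesh`.
#' @param path output `.vtk` file.
#' @param point_data named list of length-n numeric vectors (scalars) or
#'   n x 2 matrices (vectors, written with a zero z-component).
#' @export
write_vtk_snapshot <- function(mesh, path, point_data = list()) {
  n <- nrow(mesh$nodes)
  m <- nrow(mesh$tri)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "woundsim snapshot", "ASCII",
               "DATASET UNSTRUCTURED_GRID", sprintf("POINTS %d double", n)), con)
  writeLines(sprintf("%.10g %.10g 0", mesh$nodes[, 1], mesh$nodes[, 2]), con)
  writeLines(sprintf("CELLS %d %d", m, 4L * m), con)
  writeLines(sprintf("3 %d %d %d", mesh$tri[, 1] - 1L, mesh$tri[, 2] - 1L,
                     mesh$tri[, 3] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(rep("5", m), con)
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      if (is.matrix(v)) {
        writeLines(sprintf("VECTORS %s double", nm), con)
        writeLines(sprintf("%.10g %.10g 0", v[, 1], v[, 2]), con)
      } else {
        writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
        writeLines(sprintf("%.10g", v), con)
      }
    }
  }
  invisible(path)
}
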