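# Legacy ASCII VTK writers for the tissue grid and the vascular polylines.
# Output is bit-stable for identical state (fixed %.17g formatting).

vtkNum <- function(x) formatC(x, digits = 17, format = "g")

#' Write tissue mesh and nodal fields as a VTK unstructured grid
#'
#' @param mesh an \code{angio_mesh}.
#' @param fields named list of nodal scalar vectors (length = number of mesh
#'   nodes) written as point data.
#' @param path output \code{.vtk} file.
#' @param pos optional deformed node coordinates.
#' @export
writeTissueVTK <- function(mesh, fields, path, pos = mesh$nodes) {
  N <- nrow(pos); E <- nrow(mesh$elems)
  for (nm in names(fields))
    if (length(fields[[nm]]) != N)
      stopf("field '%s' has length %d, mesh has %d nodes", nm,
            length(fields[[nm]]), N)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "angiomech tissue state", "ASCII",
               "DATASET UNSTRUCTURED_GRID", sprintf("POINTS %d double", N)), con)
  writeLines(paste(vtkNum(pos[, 1]), vtkNum(pos[, 2]), vtkNum(pos[, 3])), con)
  writeLines(sprintf("CELLS %d %d", E, 9 * E), con)
  writeLines(paste(8, mesh$elems[, 1] - 1L, mesh$elems[, 2] - 1L,
                   mesh$elems[, 3] - 1L, mesh$elems[, 4] - 1L,
                   mesh$elems[, 5] - 1L, mesh$elems[, 6] - 1L,
                   mesh$elems[, 7] - 1L, mesh$elems[, 8] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", E), con)
  writeLines(rep("12", E), con)
  if (length(fields)) {
    writeLines(sprintf("POINT_DATA %d", N), con)
    for (nm in names(fields)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
      writeLines(vtkNum(fields[[nm]]), con)
    }
  }
  invisible(path)
}

#' Write the vascular network as VTK polylines
#'
#' Point data: lumen radius (um), vascular pressure (mm-Hg), node state;
#' cell data: wall shear stress per segment (mm-Hg).
#'
#' @param net an \code{angio_network}.
#' @param path output \code{.vtk} file.
#' @param p_vsc per-node vascular pressure (mm-Hg).
#' @param wss per-segment wall shear stress (mm-Hg).
#' @param pos optional deformed node positions.
#' @export
writeNetworkVTK <- function(net, path, p_vsc = NULL, wss = NULL, pos = net$pos) {
  n <- nNodes(net); m <- nrow(net$segs)
  p_vsc <- p_vsc %||% rep(0, n)
  wss <- wss %||% rep(0, m)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "angiomech vascular network",
               "ASCII", "DATASET POLYDATA", sprintf("POINTS %d double", n)), con)
  writeLines(paste(vtkNum(pos[, 1]), vtkNum(pos[, 2]), vtkNum(pos[, 3])), con)
  writeLines(sprintf("LINES %d %d", m, 3 * m), con)
  writeLines(paste(2, net$segs$a - 1L, net$segs$b - 1L), con)
  writeLines(sprintf("POINT_DATA %d", n), con)
  writeLines(c("SCALARS radius_um double 1", "LOOKUP_TABLE default"), con)
  writeLines(vtkNum(net$R * 1000), con)
  writeLines(c("SCALARS p_vsc_mmhg double 1", "LOOKUP_TABLE default"), con)
  writeLines(vtkNum(p_vsc), con)
  writeLines(c("SCALARS state int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(net$state), con)
  writeLines(sprintf("CELL_DATA %d", m), con)
  writeLines(c("SCALARS wss_mmhg double 1", "LOOKUP_TABLE default"), con)
  writeLines(vtkNum(wss), con)
  invisible(path)
}

#' Write the full simulation state (tissue VTK, network VTK, network CSV)
#'
#' @param mesh,fields,net as in the individual writers; \code{fields} is the
#'   named list of nodal tissue fields.
#' @param flow a flow solution (see \code{\link{solveCoupledPressures}}) or
#'   NULL.
#' @param prefix output path prefix; writes \code{<prefix>_tissue.vtk},
#'   \code{<prefix>_network.vtk} and \code{<prefix>_network.csv}.
#' @export
writeState <- function(mesh, fields, net, flow = NULL, prefix = "state") {
  writeTissueVTK(mesh, fields, paste0(prefix, "_tissue.vtk"))
  writeNetworkVTK(net, paste0(prefix, "_network.vtk"),
                  p_vsc = flow$p_vsc, wss = flow$seg_tauf)
  writeNetworkCSV(net, paste0(prefix, "_network.csv"))
  invisible(prefix)
}
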