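#' Heatmap, contour and parameter tables on disk
#'
#' Tidy CSV interchange formats: heatmaps as one row per grid cell
#' (`row, col, x_um, y_um, vasculature_pct, perfusion_pct, diameter_um,
#' masked`), contour series as `x_um, y_um, time_day`, nodal parameters as
#' one row per node.
#'
#' @param heatmap,series,params the tibble to write.
#' @param path file path.
#' @return the written/read tibble, invisibly for writers.
#' @export
write_heatmap_csv <- function(heatmap, path) {
  cols <- c("row", "col", "x_um", "y_um", "vasculature_pct",
            "perfusion_pct", "diameter_um", "masked")
  if (!all(cols %in% names(heatmap))) abort("Not a heatmap tibble.")
  readr::write_csv(heatmap[, cols], path)
  invisible(heatmap)
}

#' @rdname write_heatmap_csv
#' @export
read_heatmap_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    row = "i", col = "i", masked = "l",
                    .default = readr::col_double()))
}

#' @rdname write_heatmap_csv
#' @export
write_contours_csv <- function(series, path) {
  if (!all(c("time_day", "x", "y") %in% names(series))) {
    abort("A contour series needs time_day, x, y.")
  }
  readr::write_csv(
    tibble(x_um = series$x, y_um = series$y, time_day = series$time_day),
    path)
  invisible(series)
}

#' @rdname write_heatmap_csv
#' @export
read_contours_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  tibble(time_day = d$time_day, x = d$x_um, y = d$y_um)
}

#' @rdname write_heatmap_csv
#' @export
write_params_csv <- function(params, path) {
  readr::write_csv(as_tibble(params), path)
  invisible(params)
}

#' Mesh read/write as CSV node/element tables
#'
#' @param mesh a `perfusion_mesh`.
#' @param nodes_path,elements_path file paths for the two tables.
#' @param h_z thickness to attach on read (um).
#' @return the mesh, invisibly for the writer.
#' @export
write_mesh_csv <- function(mesh, nodes_path, elements_path) {
  readr::write_csv(mesh$nodes, nodes_path)
  readr::write_csv(mesh$elements, elements_path)
  invisible(mesh)
}

#' @rdname write_mesh_csv
#' @export
read_mesh_csv <- function(nodes_path, elements_path, h_z = 1) {
  nodes <- readr::read_csv(nodes_path, show_col_types = FALSE)
  elements <- readr::read_csv(elements_path, show_col_types = FALSE)
  mesh <- structure(
    list(nodes = as_tibble(nodes), elements = as_tibble(elements),
         h_z = h_z, centroid = c(mean(nodes$x), mean(nodes$y))),
    class = "perfusion_mesh")
  check_mesh_jacobians(mesh)
  mesh
}

#' Legacy-VTK export of meshes and solved fields
#'
#' Writes an ASCII legacy VTK unstructured grid (viewable in ParaView):
#' nodes, quad/triangle cells, and — for a solved field — the two nodal
#' pressures as point scalars and the element-centre Darcy velocities as
#' cell vectors.
#'
#' @param mesh a `perfusion_mesh`.
#' @param field a `perfusion_field` (velocities added if absent).
#' @param path output `.vtk` path.
#' @return the path, invisibly.
#' @export
write_mesh_vtk <- function(mesh, path) {
  writeLines(vtk_lines(mesh), path)
  invisible(path)
}

#' @rdname write_mesh_vtk
#' @export
write_field_vtk <- function(field, path) {
  if (is.null(field$velocity)) field <- darcy_velocity(field)
  mesh <- field$system$mesh
  pr <- field$pressure
  vel <- field$velocity
  lines <- c(
    vtk_lines(mesh),
    sprintf("POINT_DATA %d", nrow(mesh$nodes)),
    "SCALARS p_cap_pa float 1", "LOOKUP_TABLE default",
    sprintf("%.9g", pr$p_cap_pa),
    "SCALARS p_ex_pa float 1", "LOOKUP_TABLE default",
    sprintf("%.9g", pr$p_ex_pa),
    "SCALARS wall_flux float 1", "LOOKUP_TABLE default",
    sprintf("%.9g", pr$wall_flux),
    sprintf("CELL_DATA %d", nrow(vel)),
    "VECTORS velocity_ex float",
    sprintf("%.9g %.9g 0", vel$vx_ex, vel$vy_ex),
    "VECTORS velocity_cap float",
    sprintf("%.9g %.9g 0", vel$vx_cap, vel$vy_cap)
  )
  writeLines(lines, path)
  invisible(path)
}

vtk_lines <- function(mesh) {
  nd <- mesh$nodes; el <- mesh$elements
  cells <- vapply(seq_len(nrow(el)), function(e) {
    nn <- element_node_ids(el[e, ]) - 1L
    paste(c(length(nn), nn), collapse = " ")
  }, character(1))
  sizes <- vapply(seq_len(nrow(el)), function(e) {
    length(element_node_ids(el[e, ])) + 1L
  }, integer(1))
  types <- ifelse(el$type == "quad4", 9L, 5L)
  c("# vtk DataFile Version 3.0",
    "perfusim unstructured grid (lengths in um)",
    "ASCII",
    "DATASET UNSTRUCTURED_GRID",
    sprintf("POINTS %d float", nrow(nd)),
    sprintf("%.9g %.9g 0", nd$x, nd$y),
    sprintf("CELLS %d %d", nrow(el), sum(sizes)),
    cells,
    sprintf("CELL_TYPES %d", nrow(el)),
    sprintf("%d", types))
}

#' Two-channel image read/write as TIFF
#'
#' Writes the vascular and perfusion channels as two pages of one TIFF
#' (8-bit); `read_image_tiff()` restores the named channel list.
#'
#' @param image a `synthetic_if_image` or list with `channels` and
#'   `pixel_size_um`.
#' @param path `.tif` path.
#' @param pixel_size_um pixel size to attach on read (not stored in the
#'   TIFF).
#' @return the path / an image list.
#' @export
write_image_tiff <- function(image, path) {
  ch <- image$channels
  tiff::writeTIFF(list(ch$vascular, ch$perfusion), path,
                  bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path, pixel_size_um = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) < 2L) abort("Expected a two-page (two-channel) TIFF.")
  list(channels = list(vascular = pages[[1]], perfusion = pages[[2]]),
       pixel_size_um = pixel_size_um)
}
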