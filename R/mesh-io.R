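# Minimal legacy-ASCII VTK unstructured-grid I/O, sufficient to exchange
# simplex meshes with point-data (nodal fields) and cell-data (element
# fields) arrays with standard visualisation tools.

vtk_cell_type <- function(d) switch(d, `1` = 3L, `2` = 5L, `3` = 10L,
                                    stop("unsupported dimension"))

#' Write a mesh with attached fields to a legacy-ASCII VTK file
#'
#' Nodal fields become POINT_DATA scalars, per-element fields CELL_DATA
#' scalars. Node-set membership and the material label are always written
#' as cell/point data so the labelling survives a round trip.
#'
#' @param mesh a [simplex_mesh()].
#' @param path output file (conventionally `.vtk`).
#' @param point_data named list of length-N numeric vectors.
#' @param cell_data named list of length-M numeric vectors.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, path, point_data = list(), cell_data = list()) {
  n <- nrow(mesh$nodes); m <- nrow(mesh$elements); d <- mesh$dim
  xyz <- cbind(mesh$nodes, matrix(0, n, 3L - d))
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(c(...), con)
  w("# vtk DataFile Version 3.0", "osteorom simplex mesh", "ASCII",
    "DATASET UNSTRUCTURED_GRID", sprintf("POINTS %d double", n))
  w(apply(format(xyz, digits = 17, scientific = TRUE, trim = TRUE), 1L,
          paste, collapse = " "))
  nv <- d + 1L
  w(sprintf("CELLS %d %d", m, m * (nv + 1L)))
  w(apply(cbind(nv, mesh$elements - 1L), 1L, paste, collapse = " "))
  w(sprintf("CELL_TYPES %d", m), rep(as.character(vtk_cell_type(d)), m))

  set_id <- integer(n)                 # 1 fixed boundary, 2 implant, 0 interior
  set_id[mesh$node_sets$fixed_boundary] <- 1L
  set_id[mesh$node_sets$implant] <- 2L
  point_data <- c(point_data, list(node_set = set_id))
  w(sprintf("POINT_DATA %d", n))
  for (nm in names(point_data)) {
    w(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default")
    w(format(point_data[[nm]], digits = 17, scientific = TRUE, trim = TRUE))
  }
  cell_data <- c(cell_data,
                 list(material = as.integer(mesh$element_material == "implant")))
  w(sprintf("CELL_DATA %d", m))
  for (nm in names(cell_data)) {
    w(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default")
    w(format(cell_data[[nm]], digits = 17, scientific = TRUE, trim = TRUE))
  }
  invisible(path)
}

#' Read a legacy-ASCII VTK unstructured grid written by [write_vtk()]
#'
#' Reconstructs the mesh (including node sets and material labels from the
#' persisted `node_set` / `material` arrays) and returns the remaining
#' data arrays alongside it.
#'
#' @param path a VTK file produced by [write_vtk()].
#' @return list with `mesh`, `point_data` and `cell_data`.
#' @export
read_vtk <- function(path) {
  lines <- readLines(path)
  toks <- function(s) strsplit(trimws(s), "\\s+")[[1]]
  i_pts <- grep("^POINTS ", lines)[1]
  n <- as.integer(toks(lines[i_pts])[2])
  pts <- matrix(scan(text = lines[(i_pts + 1L):(i_pts + n)], quiet = TRUE),
                nrow = n, byrow = TRUE)
  i_cells <- grep("^CELLS ", lines)[1]
  m <- as.integer(toks(lines[i_cells])[2])
  cell_rows <- lapply(lines[(i_cells + 1L):(i_cells + m)],
                      function(s) as.integer(toks(s)))
  nv <- cell_rows[[1]][1]
  d <- nv - 1L
  elements <- do.call(rbind, lapply(cell_rows, function(r) r[-1] + 1L))
  nodes <- pts[, seq_len(d), drop = FALSE]

  read_scalars <- function(start, count, upto) {
    out <- list()
    i <- start
    while (i <= upto) {
      if (grepl("^SCALARS ", lines[i])) {
        nm <- toks(lines[i])[2]
        vals <- scan(text = lines[(i + 2L):(i + 1L + count)], quiet = TRUE)
        out[[nm]] <- vals
        i <- i + 2L + count
      } else i <- i + 1L
    }
    out
  }
  i_pd <- grep("^POINT_DATA ", lines)[1]
  i_cd <- grep("^CELL_DATA ", lines)[1]
  point_data <- read_scalars(i_pd + 1L, n, i_cd - 1L)
  cell_data <- read_scalars(i_cd + 1L, m, length(lines))

  set_id <- as.integer(round(point_data$node_set))
  material <- ifelse(as.integer(round(cell_data$material)) == 1L,
                     "implant", "bone")
  mesh <- simplex_mesh(nodes, elements,
                       node_sets = list(fixed_boundary = which(set_id == 1L),
                                        implant = which(set_id == 2L),
                                        interior = which(set_id == 0L)),
                       element_material = material)
  point_data$node_set <- NULL
  cell_data$material <- NULL
  list(mesh = mesh, point_data = point_data, cell_data = cell_data)
}
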