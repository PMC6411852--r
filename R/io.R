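# Persistence: complex volumes as paired 32-bit float TIFF stacks with a
# JSON sidecar, tables as CSV, surface meshes as ASCII PLY, volumetric
# meshes as Gmsh MSH v2 (with facet labels), nodal/traction fields as
# legacy VTK. Write-then-read equals the original within float precision
# for volumes and exactly (up to vertex order) for meshes and tables.

.need_tiff <- function() {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for volume persistence")
}

#' Write / read a complex volume
#'
#' The field is stored as a multi-page 32-bit float TIFF: all z-planes of
#' the real part followed by all z-planes of the imaginary part. Geometry,
#' corrections and focal depth go to a JSON sidecar `<file>.json`.
#'
#' @param vol a `tfocm_volume`.
#' @param path output TIFF path.
#' @return `path`, invisibly (`read_volume` returns the `tfocm_volume`).
#' @export
write_volume <- function(vol, path) {
  .need_tiff()
  d <- dim(vol$field)
  pages <- vector("list", 2L * d[1])
  sc <- max(abs(vol$field), 1e-30)
  # TIFF samples live in [0, 1]: map [-sc, sc] onto it
  for (iz in seq_len(d[1])) {
    pages[[iz]] <- Re(vol$field[iz, , ]) / (2 * sc) + 0.5
    pages[[d[1] + iz]] <- Im(vol$field[iz, , ]) / (2 * sc) + 0.5
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(dim = d, scale = sc,
               geometry = unclass(vol$geometry),
               corrections_applied = vol$corrections_applied,
               focal_depth = vol$focal_depth,
               voxel_pitch = vol$voxel_pitch)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  .need_tiff()
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- as.integer(meta$dim)
  field <- array(0 + 0i, d)
  for (iz in seq_len(d[1])) {
    field[iz, , ] <- complex(real = pages[[iz]] - 0.5,
                             imaginary = pages[[d[1] + iz]] - 0.5) *
      (2 * meta$scale)
  }
  g <- meta$geometry
  geometry <- do.call(acquisition_geometry, g[c(
    "center_wavelength_nm", "bandwidth_nm", "n_k_samples", "fov_um",
    "n_voxels", "refractive_index", "transverse_resolution_um", "na",
    "focal_plane", "coherence_gate", "carrier", "phase_jitter_std",
    "noise_floor_db", "falloff_db_per_mm", "dispersion_quadratic")])
  if (!is.null(g$offset_um)) geometry$offset_um <- g$offset_um
  if (!is.null(g$parent_fov_um)) geometry$parent_fov_um <- g$parent_fov_um
  new_complex_volume(field, geometry,
                     corrections = meta$corrections_applied,
                     focal_depth = meta$focal_depth)
}

#' Write / read a bead track table as CSV
#'
#' Columns: bead_id, t_index, t_minutes, x, y, z, ux, uy, uz, confidence
#' (positions and displacements in um; x = fast axis, y = slow axis,
#' z = depth).
#'
#' @param tracks a `tfocm_tracks` data.frame.
#' @param path CSV path.
#' @return `path` invisibly; `read_tracks` returns the data.frame.
#' @export
write_tracks <- function(tracks, path) {
  out <- tracks[, c("bead_id", "t_index", "t_minutes", "x", "y", "z",
                    "ux", "uy", "uz", "confidence")]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  tr <- utils::read.csv(path)
  class(tr) <- c("tfocm_tracks", "data.frame")
  tr
}

#' Write / read a triangle surface mesh as ASCII PLY
#'
#' @param mesh a `tfocm_surface`.
#' @param path output path (.ply).
#' @return `path` invisibly; `read_ply` returns the `tfocm_surface`.
#' @export
write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  v <- mesh$vertices; f <- mesh$faces
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(v)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nrow(f)),
               "property list uchar int vertex_indices", "end_header"), con)
  utils::write.table(format(v, digits = 17, scientific = TRUE, trim = TRUE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  utils::write.table(cbind(3L, f - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ply
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "ply") stop("not a PLY file: ", path)
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex",
                                                   lines, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face",
                                                 lines, value = TRUE)))
  hdr <- which(lines == "end_header")
  v <- matrix(as.numeric(unlist(strsplit(lines[(hdr + 1):(hdr + nv)],
                                         "\\s+"))), ncol = 3, byrow = TRUE)
  fr <- matrix(as.integer(unlist(strsplit(lines[(hdr + nv + 1):(hdr + nv + nf)],
                                          "\\s+"))), ncol = 4, byrow = TRUE)
  new_surface(v, fr[, 2:4] + 1L)
}

#' Write / read a labeled volumetric mesh as Gmsh MSH v2
#'
#' Tetrahedra carry physical tag 1; boundary triangles carry tag 2 (outer
#' box) or 3 (cell surface). Facet labels survive the round trip.
#'
#' @param mesh a `tfocm_mesh3d`.
#' @param path output path (.msh).
#' @return `path` invisibly; `read_msh` returns a list with `nodes`,
#'   `tets`, `outer_facets`, `cell_facets`.
#' @export
write_msh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat"), con)
  n <- nrow(mesh$nodes)
  writeLines(c("$Nodes", as.character(n)), con)
  utils::write.table(cbind(seq_len(n),
                           format(mesh$nodes, digits = 17, trim = TRUE)),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines("$EndNodes", con)
  nt <- nrow(mesh$tets)
  no <- nrow(mesh$outer_facets %||% matrix(0, 0, 3))
  nc <- nrow(mesh$cell_facets)
  writeLines(c("$Elements", as.character(nt + no + nc)), con)
  id <- 0L
  if (nt) {
    utils::write.table(cbind(seq_len(nt), 4L, 2L, 1L, 1L, mesh$tets), con,
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
    id <- nt
  }
  if (no) {
    utils::write.table(cbind(id + seq_len(no), 2L, 2L, 2L, 2L,
                             mesh$outer_facets), con,
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
    id <- id + no
  }
  if (nc) {
    utils::write.table(cbind(id + seq_len(nc), 2L, 2L, 3L, 3L,
                             mesh$cell_facets), con,
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  writeLines("$EndElements", con)
  invisible(path)
}

#' @rdname write_msh
#' @export
read_msh <- function(path) {
  lines <- readLines(path)
  i_n <- which(lines == "$Nodes")
  nn <- as.integer(lines[i_n + 1L])
  ntab <- matrix(as.numeric(unlist(strsplit(trimws(
    lines[(i_n + 2L):(i_n + 1L + nn)]), "\\s+"))), ncol = 4, byrow = TRUE)
  nodes <- ntab[order(ntab[, 1]), 2:4, drop = FALSE]
  i_e <- which(lines == "$Elements")
  ne <- as.integer(lines[i_e + 1L])
  rows <- strsplit(trimws(lines[(i_e + 2L):(i_e + 1L + ne)]), "\\s+")
  tets <- list(); outer <- list(); cellf <- list()
  for (r in rows) {
    r <- as.integer(r)
    typ <- r[2]; ntags <- r[3]; tag <- r[4]
    conn <- r[(4 + ntags):length(r)]
    if (typ == 4L) tets[[length(tets) + 1L]] <- conn
    else if (typ == 2L && tag == 2L) outer[[length(outer) + 1L]] <- conn
    else if (typ == 2L && tag == 3L) cellf[[length(cellf) + 1L]] <- conn
  }
  list(nodes = nodes,
       tets = do.call(rbind, tets),
       outer_facets = do.call(rbind, outer) %||% matrix(0L, 0, 3),
       cell_facets = do.call(rbind, cellf) %||% matrix(0L, 0, 3))
}

#' Write a nodal vector field (or traction glyphs) as legacy VTK
#'
#' @param nodes n x 3 points (um).
#' @param vectors n x 3 vectors.
#' @param path output path (.vtk).
#' @param name field name in the VTK file.
#' @export
write_vtk_points <- function(nodes, vectors, path, name = "displacement") {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(nodes)
  writeLines(c("# vtk DataFile Version 3.0", "tfocm field", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d double", n)), con)
  utils::write.table(format(nodes, digits = 10, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(c(sprintf("POINT_DATA %d", n),
               sprintf("VECTORS %s double", name)), con)
  utils::write.table(format(vectors, digits = 10, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a per-facet traction table as CSV
#'
#' Columns: facet id, centroid (um), area (um^2), traction vector (Pa).
#' @param traction a `tfocm_traction`.
#' @param path CSV path.
#' @export
write_traction <- function(traction, path) {
  out <- data.frame(facet = seq_len(nrow(traction$vectors)),
                    cz = traction$centroids[, 1], cx = traction$centroids[, 2],
                    cy = traction$centroids[, 3], area = traction$areas,
                    tz = traction$vectors[, 1], tx = traction$vectors[, 2],
                    ty = traction$vectors[, 3])
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traction
#' @export
read_traction <- function(path) {
  df <- utils::read.csv(path)
  structure(list(vectors = unname(as.matrix(df[, c("tz", "tx", "ty")])),
                 areas = df$area,
                 centroids = unname(as.matrix(df[, c("cz", "cx", "cy")])),
                 normals = NULL),
            class = "tfocm_traction")
}
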