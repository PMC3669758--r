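#' Export a mesh to OBJ, OFF or ASCII PLY
#'
#' Plain-text writers with fixed `%.9g` formatting so identical meshes always
#' produce byte-identical files. OBJ uses 1-based indices per the format.
#'
#' @param mesh a [trimesh()].
#' @param path output file path; the format is also inferred from its
#'   extension when `format` is missing.
#' @param format one of `"obj"`, `"off"`, `"ply"`.
#' @return `path`, invisibly.
#' @export
export_mesh <- function(mesh, path, format = NULL) {
  if (!inherits(mesh, "trimesh")) nm_arg_error("mesh must be a trimesh")
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  format <- match.arg(format, c("obj", "off", "ply"))
  lines <- switch(format,
    obj = format_obj(mesh),
    off = format_off(mesh),
    ply = format_ply(mesh))
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

fmt_coords <- function(v, prefix = "") {
  sprintf("%s%.9g %.9g %.9g", prefix, v[, 1], v[, 2], v[, 3])
}

format_obj <- function(mesh) {
  c(fmt_coords(mesh$vertices, "v "),
    sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3]))
}

format_off <- function(mesh) {
  e <- mesh_edges(mesh)
  c("OFF",
    sprintf("%d %d %d", n_vertices(mesh), n_faces(mesh), nrow(e)),
    fmt_coords(mesh$vertices),
    sprintf("3 %d %d %d", mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
            mesh$faces[, 3] - 1L))
}

format_ply <- function(mesh) {
  c("ply", "format ascii 1.0",
    sprintf("element vertex %d", n_vertices(mesh)),
    "property float x", "property float y", "property float z",
    sprintf("element face %d", n_faces(mesh)),
    "property list uchar int vertex_indices", "end_header",
    fmt_coords(mesh$vertices),
    sprintf("3 %d %d %d", mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
            mesh$faces[, 3] - 1L))
}

#' Read a Wavefront OBJ mesh
#'
#' Minimal reader for the subset [export_mesh()] writes: `v` and triangular
#' `f` records (texture/normal sub-indices after `/` are ignored).
#'
#' @param path OBJ file path.
#' @return a [trimesh()].
#' @export
read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  if (length(vl) == 0L) nm_parse_error("OBJ file contains no vertices")
  verts <- do.call(rbind, lapply(strsplit(sub("^v\\s+", "", vl), "\\s+"),
                                 function(x) as.numeric(x[1:3])))
  faces <- do.call(rbind, lapply(strsplit(sub("^f\\s+", "", fl), "\\s+"),
    function(x) {
      idx <- as.integer(sub("/.*$", "", x))
      if (length(idx) != 3L) nm_parse_error("only triangular OBJ faces supported")
      idx
    }))
  trimesh(verts, faces)
}
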