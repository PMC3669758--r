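#' Indexed triangle mesh
#'
#' `trimesh()` is the geometry currency of the package: a matrix of vertex
#' positions (micrometres) and a matrix of 1-based vertex-index triples.
#' Faces are wound counter-clockwise seen from outside, so a closed mesh has
#' positive enclosed volume. Meshes may carry named *ports*: ordered boundary
#' or attachment loops used by the stitching stages.
#'
#' @param vertices numeric n x 3 matrix of positions.
#' @param faces integer m x 3 matrix of vertex indices (1-based).
#' @param ports optional named list of port records (internal bookkeeping).
#' @return an object of class `trimesh`.
#' @export
trimesh <- function(vertices, faces, ports = list()) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  if (ncol(vertices) != 3L) nm_arg_error("vertices must be an n x 3 matrix")
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (nrow(faces) > 0L) {
    if (ncol(faces) != 3L) nm_arg_error("faces must be an m x 3 matrix")
    if (min(faces) < 1L || max(faces) > nrow(vertices))
      nm_arg_error("face indices out of range")
    if (any(faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
              faces[, 1] == faces[, 3]))
      nm_arg_error("a face repeats a vertex")
  }
  structure(list(vertices = vertices, faces = faces, ports = ports),
            class = "trimesh")
}

#' @export
print.trimesh <- function(x, ...) {
  cat(sprintf("<trimesh: %d vertices, %d faces, %d ports>\n",
              nrow(x$vertices), nrow(x$faces), length(x$ports)))
  invisible(x)
}

n_vertices <- function(mesh) nrow(mesh$vertices)
n_faces <- function(mesh) nrow(mesh$faces)

# undirected edge keys of all face edges: i*(n+1)+j with i < j
face_edge_keys <- function(mesh) {
  f <- mesh$faces
  n <- n_vertices(mesh)
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  pmin(e[, 1], e[, 2]) * (n + 1) + pmax(e[, 1], e[, 2])
}

# unique undirected edges as a 2-column matrix (i < j), sorted
mesh_edges <- function(mesh) {
  if (nrow(mesh$faces) == 0L) return(matrix(integer(0), 0, 2))
  n <- n_vertices(mesh)
  uk <- sort(unique(face_edge_keys(mesh)))
  cbind(as.integer(uk %/% (n + 1)), as.integer(uk %% (n + 1)))
}

# per-undirected-edge incident face count; list(keys, counts)
edge_face_counts <- function(mesh) {
  key <- face_edge_keys(mesh)
  uk <- unique(key)
  list(keys = uk, counts = tabulate(match(key, uk), nbins = length(uk)))
}

# adjacency list of the vertex-edge graph
vertex_adjacency <- function(mesh) {
  e <- mesh_edges(mesh)
  adj <- vector("list", n_vertices(mesh))
  if (nrow(e) > 0L) {
    both <- rbind(e, e[, 2:1, drop = FALSE])
    sp <- split(both[, 2], both[, 1])
    for (k in names(sp)) adj[[as.integer(k)]] <- sp[[k]]
  }
  adj
}

#' Enclosed volume of a closed mesh
#'
#' Signed volume by the divergence theorem (sum of signed tetrahedra against
#' the origin); positive when faces are wound outward.
#'
#' @param mesh a closed [trimesh()].
#' @param signed if `FALSE`, error when the mesh is open; if `TRUE` the signed
#'   sum is returned regardless.
#' @return volume in cubic micrometres.
#' @export
measure_volume <- function(mesh, signed = TRUE) {
  if (!inherits(mesh, "trimesh")) nm_arg_error("mesh must be a trimesh")
  if (n_faces(mesh) == 0L) nm_geometry_error("empty mesh has no volume")
  cnt <- edge_face_counts(mesh)$counts
  if (any(cnt != 2L))
    nm_geometry_error("measure_volume requires a closed mesh (boundary or non-manifold edges present)")
  signed_mesh_volume(mesh)
}

signed_mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  cr <- cbind(b[, 2] * cc[, 3] - b[, 3] * cc[, 2],
              b[, 3] * cc[, 1] - b[, 1] * cc[, 3],
              b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
  sum(rowSums(a * cr)) / 6
}

#' Mesh quality report
#'
#' Exact structural audit of a mesh: boundary edges (1 incident face),
#' non-manifold edges (3 or more), connected components, Euler characteristic
#' V - E + F, closedness, triangle count, and enclosed volume (divergence
#' theorem; meaningful only when closed).
#'
#' @param mesh a [trimesh()].
#' @return an object of class `mesh_quality_report` (a named list).
#' @export
validate_mesh <- function(mesh) {
  if (!inherits(mesh, "trimesh")) nm_arg_error("mesh must be a trimesh")
  if (n_vertices(mesh) == 0L || n_faces(mesh) == 0L)
    nm_arg_error("cannot validate an empty mesh")
  cnt <- edge_face_counts(mesh)$counts
  boundary <- sum(cnt == 1L)
  nonmanifold <- sum(cnt >= 3L)
  e <- mesh_edges(mesh)
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n_vertices(mesh) - igraph::vcount(g)))
  comp <- igraph::components(g)$no
  chi <- n_vertices(mesh) - nrow(e) + n_faces(mesh)
  closed <- boundary == 0L && nonmanifold == 0L
  structure(list(
    boundary_edges = as.integer(boundary),
    nonmanifold_edges = as.integer(nonmanifold),
    components = as.integer(comp),
    euler_characteristic = as.integer(chi),
    closed = closed,
    volume = if (closed) signed_mesh_volume(mesh) else NA_real_,
    triangles = n_faces(mesh)
  ), class = "mesh_quality_report")
}

#' @export
print.mesh_quality_report <- function(x, ...) {
  cat(sprintf(paste0(
    "mesh quality: %d triangles | boundary edges %d | non-manifold edges %d | ",
    "components %d | V-E+F = %d | closed: %s | volume %s um^3\n"),
    x$triangles, x$boundary_edges, x$nonmanifold_edges, x$components,
    x$euler_characteristic, x$closed,
    if (is.na(x$volume)) "NA" else format(x$volume, digits = 6)))
  invisible(x)
}

#' Icosphere
#'
#' Geodesic sphere by recursive midpoint subdivision of an icosahedron, the
#' starting shape for soma reconstruction. `20 * 4^subdivisions` faces; every
#' vertex lies exactly at distance `radius` from `center`.
#'
#' @param center 3-vector, micrometres.
#' @param radius positive scalar, micrometres.
#' @param subdivisions non-negative integer.
#' @return a closed [trimesh()].
#' @export
make_icosphere <- function(center = c(0, 0, 0), radius = 1, subdivisions = 3L) {
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0)
    nm_arg_error("radius must be a positive scalar")
  if (subdivisions < 0L) nm_arg_error("subdivisions must be >= 0")
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(1 + phi^2)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  s <- 0L
  while (s < subdivisions) {
    nv <- nrow(v)
    midkey <- new.env(hash = TRUE, parent = emptyenv())
    verts <- v
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      idx <- midkey[[key]]
      if (!is.null(idx)) return(idx)
      p <- (verts[i, ] + verts[j, ]) / 2
      p <- p / sqrt(sum(p * p))
      verts <<- rbind(verts, p)
      idx <- nrow(verts)
      midkey[[key]] <- idx
      idx
    }
    nf <- matrix(0L, nrow(f) * 4L, 3L)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; cc <- f[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      nf[(t - 1L) * 4L + 1L, ] <- c(a, ab, ca)
      nf[(t - 1L) * 4L + 2L, ] <- c(b, bc, ab)
      nf[(t - 1L) * 4L + 3L, ] <- c(cc, ca, bc)
      nf[(t - 1L) * 4L + 4L, ] <- c(ab, bc, ca)
    }
    v <- verts
    f <- nf
    s <- s + 1L
  }
  v <- sweep(v * radius, 2, center, "+")
  trimesh(v, f)
}

#' Uniformly scale a sphere mesh about its center
#'
#' The reduction step of soma building: shrinking the bounding sphere fixes
#' the minimum volume of the final deformed soma. Topology is untouched.
#'
#' @param sphere a [trimesh()] (closed, centered).
#' @param reduction_fraction scalar in (0, 1].
#' @return the scaled [trimesh()].
#' @export
reduce_sphere <- function(sphere, reduction_fraction) {
  if (!is.numeric(reduction_fraction) || length(reduction_fraction) != 1L ||
        reduction_fraction <= 0 || reduction_fraction > 1)
    nm_arg_error("reduction_fraction must lie in (0, 1]")
  ctr <- colMeans(sphere$vertices)
  v <- sweep(sweep(sphere$vertices, 2, ctr, "-") * reduction_fraction, 2, ctr, "+")
  out <- sphere
  out$vertices <- v
  out
}

#' Laplacian smoothing
#'
#' Moves each unprotected vertex toward the centroid of its one-ring by
#' `factor`, `iterations` times. Connectivity is untouched, so V, E, F and the
#' Euler characteristic are preserved; junction rings are typically protected
#' so stitched bands keep their shape.
#'
#' @param mesh a [trimesh()].
#' @param iterations non-negative integer.
#' @param factor scalar in (0, 1).
#' @param protected integer vector of vertex indices to leave unmoved.
#' @return the smoothed [trimesh()].
#' @export
laplacian_smooth <- function(mesh, iterations = 2L, factor = 0.3,
                             protected = integer(0)) {
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 0 || factor >= 1)
    nm_arg_error("factor must lie in (0, 1)")
  if (iterations < 0L) nm_arg_error("iterations must be >= 0")
  if (iterations == 0L) return(mesh)
  e <- mesh_edges(mesh)
  both <- rbind(e, e[, 2:1, drop = FALSE])
  ord <- order(both[, 1])
  src <- both[ord, 1]
  dst <- both[ord, 2]
  deg <- tabulate(src, nbins = n_vertices(mesh))
  free <- setdiff(which(deg > 0L), protected)
  v <- mesh$vertices
  for (it in seq_len(iterations)) {
    centroid <- rowsum(v[dst, , drop = FALSE], src,
                       reorder = TRUE) / deg[deg > 0L]
    idx <- sort(unique(src))
    cen <- matrix(NA_real_, n_vertices(mesh), 3L)
    cen[idx, ] <- centroid
    v[free, ] <- (1 - factor) * v[free, , drop = FALSE] +
      factor * cen[free, , drop = FALSE]
  }
  mesh$vertices <- v
  mesh
}

# --- internal structural editing helpers ------------------------------------

# concatenate two meshes; returns merged mesh and the index offset of b
merge_meshes <- function(a, b) {
  off <- n_vertices(a)
  faces <- rbind(a$faces, b$faces + off)
  ports <- c(a$ports, lapply(b$ports, function(p) offset_port(p, off)))
  list(mesh = trimesh(rbind(a$vertices, b$vertices), faces, ports), offset = off)
}

offset_port <- function(p, off) {
  for (fld in c("loop", "center_vertex")) {
    if (!is.null(p[[fld]])) p[[fld]] <- p[[fld]] + off
  }
  p
}

# drop vertices not referenced by any face; returns mesh and old->new map
drop_unreferenced <- function(mesh) {
  used <- sort(unique(as.vector(mesh$faces)))
  vmap <- rep(NA_integer_, n_vertices(mesh))
  vmap[used] <- seq_along(used)
  faces <- matrix(vmap[mesh$faces], ncol = 3L)
  ports <- lapply(mesh$ports, function(p) {
    for (fld in c("loop", "center_vertex")) {
      if (!is.null(p[[fld]])) p[[fld]] <- vmap[p[[fld]]]
    }
    p
  })
  list(mesh = trimesh(mesh$vertices[used, , drop = FALSE], faces, ports),
       vmap = vmap)
}

# Ordered directed boundary loops of an open mesh. Each loop follows the
# orientation induced by the incident faces (edge a->b appears in exactly one
# face); for a mesh of outward-wound faces this orientation is canonical and
# is what the stitching code relies on.
boundary_loops <- function(mesh) {
  f <- mesh$faces
  n <- n_vertices(mesh)
  dir_e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- pmin(dir_e[, 1], dir_e[, 2]) * (n + 1) + pmax(dir_e[, 1], dir_e[, 2])
  uk <- unique(key)
  idx <- match(key, uk)
  cnt <- tabulate(idx, nbins = length(uk))
  bidx <- cnt[idx] == 1L
  if (!any(bidx)) return(list())
  be <- dir_e[bidx, , drop = FALSE]
  nxt <- integer(n)
  if (anyDuplicated(be[, 1]))
    nm_geometry_error("non-disc boundary: a vertex has two outgoing boundary edges")
  nxt[be[, 1]] <- be[, 2]
  visited <- logical(n)
  loops <- list()
  for (s in be[, 1]) {
    if (visited[s]) next
    loop <- integer(0)
    cur <- s
    repeat {
      if (visited[cur]) nm_geometry_error("boundary walk failed: non-simple loop")
      visited[cur] <- TRUE
      loop <- c(loop, cur)
      cur <- nxt[cur]
      if (cur == 0L) nm_geometry_error("boundary walk failed: broken loop")
      if (cur == s) break
    }
    loops[[length(loops) + 1L]] <- loop
  }
  loops
}
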