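#' Geodesic distances over the mesh edge graph
#'
#' Surface distance approximated as shortest paths on the vertex-edge graph
#' with Euclidean edge lengths (Dijkstra). On near-uniform icospheres the
#' edge-graph approximation overestimates the true polyhedral geodesic by
#' under 10 percent, which is sufficient to delimit regions of influence.
#'
#' @param mesh a [trimesh()].
#' @param source vertex index (1-based).
#' @return numeric vector of distances per vertex; `distance[source] == 0`.
#' @export
geodesic_distances <- function(mesh, source) {
  if (!inherits(mesh, "trimesh")) nm_arg_error("mesh must be a trimesh")
  n <- n_vertices(mesh)
  if (!is.numeric(source) || length(source) != 1L || source < 1L || source > n)
    nm_arg_error("source vertex index out of range")
  e <- mesh_edges(mesh)
  w <- rowwise_norm(mesh$vertices[e[, 1], , drop = FALSE] -
                      mesh$vertices[e[, 2], , drop = FALSE])
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  as.numeric(igraph::distances(g, v = as.integer(source), weights = w))
}

#' Region of influence of a first-order neurite on the soma sphere
#'
#' The set of sphere vertices a stem will pull during deformation: the mesh
#' vertex nearest (Euclidean) to the stem start is the seed, and every vertex
#' within geodesic distance `threshold` of the seed is a member. The
#' `boundary` is the cyclically ordered one-ring frontier just outside the
#' member set (the hole contour left if all member-incident faces were
#' removed). Ties in the seed search break to the lowest vertex index.
#'
#' @param mesh the (reduced) soma sphere, a [trimesh()].
#' @param stem_start 3-vector: first morphological point of the stem.
#' @param stem_diameter non-negative scalar; used as the geodesic threshold.
#' @return an object of class `region_of_influence`: list with `seed`,
#'   `members`, `boundary`, `threshold`, `stem_start`.
#' @export
compute_region_of_influence <- function(mesh, stem_start, stem_diameter) {
  if (n_vertices(mesh) == 0L) nm_arg_error("mesh is empty")
  if (stem_diameter < 0) nm_arg_error("stem_diameter must be >= 0")
  d2 <- rowSums(sweep(mesh$vertices, 2, stem_start, "-")^2)
  seed <- which.min(d2)  # lowest index on ties
  gd <- geodesic_distances(mesh, seed)
  members <- which(gd <= stem_diameter + 1e-12)
  boundary <- region_frontier_loop(mesh, members)
  structure(list(
    seed = as.integer(seed),
    members = as.integer(members),
    boundary = as.integer(boundary),
    threshold = stem_diameter,
    geodesic = gd[members],
    stem_start = as.numeric(stem_start)
  ), class = "region_of_influence")
}

# ordered frontier loop: boundary of the mesh after removing every face
# incident to a member vertex; errors when the frontier is not a single
# simple loop (non-disc region).
region_frontier_loop <- function(mesh, members) {
  inc <- matrix(mesh$faces %in% members, ncol = 3L)
  removed <- rowSums(inc) > 0L
  if (!any(removed)) nm_geometry_error("region has no incident faces")
  if (all(removed))
    nm_geometry_error("region of influence covers the whole mesh")
  kept <- trimesh(mesh$vertices, mesh$faces[!removed, , drop = FALSE])
  loops <- boundary_loops(kept)
  if (length(loops) != 1L)
    nm_geometry_error(sprintf(
      "region frontier is not a single loop (%d loops): non-disc region; increase sphere subdivisions",
      length(loops)))
  loops[[1L]]
}
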