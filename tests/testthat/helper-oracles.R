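# Independent oracles, coded from scratch so they never share a code path
# with the package implementation they check.

# plain O(n^2) Dijkstra over a weighted undirected edge list
ref_dijkstra <- function(n_vertices, edges, weights, source) {
  adj <- vector("list", n_vertices)
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1]; j <- edges[k, 2]; w <- weights[k]
    adj[[i]] <- rbind(adj[[i]], c(j, w))
    adj[[j]] <- rbind(adj[[j]], c(i, w))
  }
  dist <- rep(Inf, n_vertices)
  dist[source] <- 0
  done <- rep(FALSE, n_vertices)
  for (it in seq_len(n_vertices)) {
    u <- which(!done & dist == min(dist[!done]))[1]
    if (!is.finite(dist[u])) break
    done[u] <- TRUE
    nb <- adj[[u]]
    if (is.null(nb)) next
    for (r in seq_len(nrow(nb))) {
      v <- nb[r, 1]
      if (dist[u] + nb[r, 2] < dist[v]) dist[v] <- dist[u] + nb[r, 2]
    }
  }
  dist
}

# segment-triangle intersection (barycentric solve); open tolerance so
# touching at shared vertices does not count
seg_tri_intersect <- function(p, q, a, b, cc, eps = 1e-9) {
  M <- cbind(q - p, -(b - a), -(cc - a))
  if (abs(det(M)) < 1e-14) return(FALSE)
  sol <- solve(M, a - p)
  t <- sol[1]; u <- sol[2]; v <- sol[3]
  t > eps && t < 1 - eps && u > eps && v > eps && (u + v) < 1 - eps
}

tri_tri_intersect <- function(t1, t2) {
  for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
    if (seg_tri_intersect(t1[e[1], ], t1[e[2], ], t2[1, ], t2[2, ], t2[3, ]))
      return(TRUE)
    if (seg_tri_intersect(t2[e[1], ], t2[e[2], ], t1[1, ], t1[2, ], t1[3, ]))
      return(TRUE)
  }
  FALSE
}

# brute-force count of intersecting face pairs among faces whose centroids
# lie within `radius` of `point`; pairs sharing a vertex are skipped
count_local_intersections <- function(mesh, point, radius) {
  cent <- (mesh$vertices[mesh$faces[, 1], , drop = FALSE] +
             mesh$vertices[mesh$faces[, 2], , drop = FALSE] +
             mesh$vertices[mesh$faces[, 3], , drop = FALSE]) / 3
  near <- which(sqrt(rowSums(sweep(cent, 2, point, "-")^2)) <= radius)
  bad <- 0L
  if (length(near) < 2L) return(0L)
  for (ii in seq_len(length(near) - 1L)) {
    for (jj in (ii + 1L):length(near)) {
      f1 <- mesh$faces[near[ii], ]
      f2 <- mesh$faces[near[jj], ]
      if (length(intersect(f1, f2)) > 0L) next
      t1 <- mesh$vertices[f1, , drop = FALSE]
      t2 <- mesh$vertices[f2, , drop = FALSE]
      if (tri_tri_intersect(t1, t2)) bad <- bad + 1L
    }
  }
  bad
}

mesh_stats <- function(mesh) {
  r <- validate_mesh(mesh)
  c(V = nrow(mesh$vertices), E = nrow(mesh$vertices) - r$euler_characteristic +
      r$triangles, F = r$triangles)
}

# axis-aligned unit cube as 12 outward-wound triangles
cube_mesh <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  # vertices: 1:(0,0,0) 2:(1,0,0) 3:(0,1,0) 4:(1,1,0) 5:(0,0,1) 6:(1,0,1)
  #           7:(0,1,1) 8:(1,1,1)
  f <- rbind(
    c(1, 3, 4), c(1, 4, 2),   # bottom (z=0), normal -z
    c(5, 6, 8), c(5, 8, 7),   # top (z=1), normal +z
    c(1, 2, 6), c(1, 6, 5),   # y=0
    c(3, 7, 8), c(3, 8, 4),   # y=1
    c(1, 5, 7), c(1, 7, 3),   # x=0
    c(2, 4, 8), c(2, 8, 6))   # x=1
  trimesh(v, f)
}

# regular tetrahedron with unit edge length
unit_tetrahedron <- function() {
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / (2 * sqrt(2))
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4))
  trimesh(v, f)
}

# an open two-ring tube used by spine tests
simple_closed_tube <- function(len = 12, r = 1, p = 8L, cs = 6L) {
  m <- neuron_morphology(
    soma_sphere(c(0, 0, 0), 3),
    data.frame(id = 1:2, type = "basal_dendrite",
               x = c(4, 4 + len), y = 0, z = 0,
               radius = r, parent = c(-1L, 1L)),
    stems = 1L)
  assemble_neuron(m, res = resolution_params(cs, p))
}
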