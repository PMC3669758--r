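# Stitching: every junction in the neuron (consecutive tubes, forks, soma
# ports, spines) is closed by one primitive — a triangulated band zipped
# between two open boundary loops. Winding is derived from the loops'
# directed boundary orientation so the merged surface stays orientable and
# 2-manifold by construction.

# set of directed boundary edges of the mesh, as a key vector
directed_boundary_edges <- function(mesh) {
  f <- mesh$faces
  n <- n_vertices(mesh)
  dir_e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- pmin(dir_e[, 1], dir_e[, 2]) * (n + 1) + pmax(dir_e[, 1], dir_e[, 2])
  uk <- unique(key)
  idx <- match(key, uk)
  cnt <- tabulate(idx, nbins = length(uk))
  dir_e[cnt[idx] == 1L, , drop = FALSE]
}

# return `loop` ordered along the mesh's directed boundary orientation
orient_loop <- function(mesh, loop, bedges = directed_boundary_edges(mesh)) {
  n <- n_vertices(mesh)
  keyset <- bedges[, 1] * (n + 1) + bedges[, 2]
  fwd <- (loop[1] * (n + 1) + loop[2]) %in% keyset
  rev_ <- (loop[2] * (n + 1) + loop[1]) %in% keyset
  if (fwd) loop else if (rev_) rev(loop) else
    nm_geometry_error("loop is not a boundary loop of the mesh")
}

loop_circulation <- function(verts, loop, center, axis) {
  e1 <- orthogonal_vector(axis)
  e2 <- vcross(axis, e1)
  rel <- sweep(verts[loop, , drop = FALSE], 2, center, "-")
  ang <- atan2(rel %*% e2, rel %*% e1)
  d <- diff(c(ang, ang[1]))
  d <- (d + pi) %% (2 * pi) - pi
  sum(d)
}

# add a zipped triangle band between two directed boundary loops of `mesh`.
# Loops are re-oriented to the canonical boundary direction; B is traversed
# against its direction so both advance the same angular way about `axis`.
stitch_loops <- function(mesh, loopA, loopB, axis = NULL) {
  v <- mesh$vertices
  cA <- colMeans(v[loopA, , drop = FALSE])
  cB <- colMeans(v[loopB, , drop = FALSE])
  if (is.null(axis)) {
    d <- cB - cA
    axis <- if (vnorm(d) > 1e-9) vunit(d) else newell_normal(v, loopA)
  }
  bedges <- directed_boundary_edges(mesh)
  A <- orient_loop(mesh, loopA, bedges)
  B2 <- rev(orient_loop(mesh, loopB, bedges))
  # project both loops along A's own Newell (vector-area) normal: A winds
  # positively about it by construction, and a mating loop must do the same
  nv <- newell_area(v, A)
  axis <- if (vnorm(nv) > 1e-12) nv / vnorm(nv) else vunit(axis)
  sB <- loop_circulation(v, B2, cB, axis)
  if (sB <= 0)
    nm_geometry_error("loop correspondence crosses angularly; cannot build a simple band")
  # angular correspondence: both loops are walked strictly monotonically in
  # azimuth about the axis, which keeps the band simple even when the loop
  # sizes are very unequal or one contour is irregular
  e1 <- orthogonal_vector(axis)
  e2 <- vcross(axis, e1)
  orient <- 1
  loop_angles <- function(loop, center) {
    rel <- sweep(v[loop, , drop = FALSE], 2, center, "-")
    as.numeric(atan2(rel %*% e2, rel %*% e1)) * orient
  }
  angA <- loop_angles(A, cA)
  angB <- loop_angles(B2, cB)
  # seam: start B2 at the vertex angularly closest to A's start
  dang <- (angB - angA[1] + pi) %% (2 * pi) - pi
  j0 <- which.min(abs(dang))
  B2 <- B2[c(j0:length(B2), seq_len(j0 - 1L))]
  angB <- angB[c(j0:length(angB), seq_len(j0 - 1L))]
  monotone_param <- function(ang) {
    d <- diff(ang)
    d <- (d + pi) %% (2 * pi) - pi
    cumsum(c(0, pmax(d, 0)))
  }
  tA <- monotone_param(angA)
  tB <- monotone_param(angB) + ((angB[1] - angA[1] + pi) %% (2 * pi) - pi)
  nA <- length(A)
  nB <- length(B2)
  Ae <- c(A, A[1])
  Be <- c(B2, B2[1])
  tAe <- c(tA, 2 * pi)
  tBe <- c(tB, tB[1] + 2 * pi)
  tris <- matrix(0L, nA + nB, 3L)
  i <- 1L; j <- 1L; t <- 0L
  while (i <= nA || j <= nB) {
    canA <- i <= nA
    canB <- j <= nB
    t <- t + 1L
    if (canA && (!canB || tAe[i + 1L] <= tBe[j + 1L])) {
      tris[t, ] <- c(Ae[i + 1L], Ae[i], Be[j])
      i <- i + 1L
    } else {
      tris[t, ] <- c(Be[j], Be[j + 1L], Ae[i])
      j <- j + 1L
    }
  }
  trimesh(mesh$vertices, rbind(mesh$faces, tris), mesh$ports)
}

newell_area <- function(verts, loop) {
  p <- verts[loop, , drop = FALSE]
  q <- p[c(2:nrow(p), 1L), , drop = FALSE]
  c(sum((p[, 2] - q[, 2]) * (p[, 3] + q[, 3])),
    sum((p[, 3] - q[, 3]) * (p[, 1] + q[, 1])),
    sum((p[, 1] - q[, 1]) * (p[, 2] + q[, 2])))
}

newell_normal <- function(verts, loop) vunit(newell_area(verts, loop))

# remove every face incident to `vertex`; returns mesh (vertex dropped),
# the ordered hole loop, and the old->new vertex map
open_hole_at <- function(mesh, vertex) {
  inc <- rowSums(matrix(mesh$faces == vertex, ncol = 3L)) > 0L
  if (!any(inc)) nm_geometry_error("vertex has no incident faces")
  n <- n_vertices(mesh)
  before <- directed_boundary_edges(mesh)
  if (vertex %in% before)
    nm_geometry_error("anchor vertex lies on a boundary edge; choose a finer resolution")
  kept <- trimesh(mesh$vertices, mesh$faces[!inc, , drop = FALSE], mesh$ports)
  after <- directed_boundary_edges(kept)
  kb <- if (nrow(before)) before[, 1] * (n + 1) + before[, 2] else numeric(0)
  ka <- after[, 1] * (n + 1) + after[, 2]
  newe <- after[!(ka %in% kb), , drop = FALSE]
  if (nrow(newe) < 3L || anyDuplicated(newe[, 1]))
    nm_geometry_error("opening the hole did not create a single simple loop")
  nxt <- integer(n)
  nxt[newe[, 1]] <- newe[, 2]
  loop <- integer(nrow(newe))
  cur <- newe[1L, 1L]
  for (k in seq_len(nrow(newe))) {
    loop[k] <- cur
    cur <- nxt[cur]
    if (cur == 0L) nm_geometry_error("hole boundary walk failed")
  }
  if (cur != loop[1L] || anyDuplicated(loop))
    nm_geometry_error("opening the hole did not create a single simple loop")
  dropped <- drop_unreferenced(kept)
  list(mesh = dropped$mesh,
       loop = dropped$vmap[loop],
       vmap = dropped$vmap)
}

#' Link two consecutive open tubes
#'
#' Bridges the end cross-section of `tube_a` to the start cross-section of
#' `tube_b` with a zipped band of exactly `2 * points_per_section` triangles.
#' When the tubes meet at a sharp angle the first tube is shortened (its end
#' ring pulled back along its axis) and both mating rings are re-oriented to
#' the angle-bisector plane so the band cannot fold through the surface.
#'
#' @param tube_a,tube_b open [trimesh()] tubes with `end` / `start` ports and
#'   equal ring sizes.
#' @param angle_threshold bend angle (radians) beyond which shortening and
#'   re-orientation engage.
#' @return the linked [trimesh()].
#' @export
link_consecutive <- function(tube_a, tube_b, angle_threshold = pi / 9) {
  pa <- tube_a$ports$end
  pb <- tube_b$ports$start
  if (is.null(pa) || is.null(pb))
    nm_arg_error("tubes must carry 'end' and 'start' ports")
  if (length(pa$loop) != length(pb$loop))
    nm_arg_error("ring sizes differ; resolution must agree along a branch")
  ang <- acos(max(-1, min(1, sum(pa$axis * pb$axis))))
  if (ang > angle_threshold) {
    bis <- vunit(pa$axis + pb$axis)
    r <- max(pa$radius, pb$radius)
    delta <- r * tan(ang / 2)
    # shorten the first cone: pull its end ring back along its axis
    tube_a$vertices[pa$loop, ] <-
      sweep(tube_a$vertices[pa$loop, , drop = FALSE], 2, pa$axis * delta, "-")
    newcen <- pa$center - pa$axis * delta
    tube_a$vertices[pa$loop, ] <- reorient_ring(
      tube_a$vertices[pa$loop, , drop = FALSE], newcen, pa$axis, bis)
    # re-orient the initial base of the second cone
    tube_b$vertices[pb$loop, ] <- reorient_ring(
      tube_b$vertices[pb$loop, , drop = FALSE], pb$center, pb$axis, bis)
  }
  mm <- merge_meshes(tube_a, tube_b)
  merged <- mm$mesh
  loopA <- pa$loop
  loopB <- pb$loop + mm$offset
  merged$ports[["end"]] <- NULL
  merged$ports[["start"]] <- NULL
  stitch_loops(merged, loopA, loopB,
               axis = vunit(pa$axis + pb$axis))
}

reorient_ring <- function(ringv, center, from_axis, to_axis) {
  rel <- sweep(ringv, 2, center, "-")
  rot <- t(apply(rel, 1, rotate_between, a = from_axis, b = to_axis))
  sweep(rot, 2, center, "+")
}

#' Connect the second child of a bifurcation by hole-and-sew
#'
#' The mesh vertex nearest `child2_centroid` (ties to the lowest index) is
#' chosen as the anchor; its incident triangles are erased, opening a hole of
#' the anchor's valence d, and the hole contour is sewn to the starting
#' cross-section of `child2` with a band of d + p triangles.
#'
#' @param parent_child1 a [trimesh()]: the parent segment already linked with
#'   the first child.
#' @param child2 an open [trimesh()] with a `start` port.
#' @param child2_centroid 3-vector: centroid of `child2`'s start ring
#'   (defaults to its start port center).
#' @return the sewn [trimesh()].
#' @export
connect_bifurcation <- function(parent_child1, child2, child2_centroid = NULL) {
  pb <- child2$ports$start
  if (is.null(pb)) nm_arg_error("child2 must carry a 'start' port")
  if (is.null(child2_centroid)) child2_centroid <- pb$center
  d2 <- rowSums(sweep(parent_child1$vertices, 2, child2_centroid, "-")^2)
  anchor <- which.min(d2)
  hole <- open_hole_at(parent_child1, anchor)
  mm <- merge_meshes(hole$mesh, child2)
  merged <- mm$mesh
  merged$ports[["start"]] <- NULL
  stitch_loops(merged, hole$loop, pb$loop + mm$offset, axis = pb$axis)
}

#' Attach a first-order neurite tube to a soma port
#'
#' Erases the port's fan triangles (opening the hole the fan had closed) and
#' sews the contour to the tube's first cross-section by angular
#' correspondence about the stem axis; the band adds
#' `|port contour| + |ring|` triangles and removes both boundary loops.
#'
#' @param soma a ported soma [trimesh()] (see [build_soma()]).
#' @param tube an open [trimesh()] with a `start` port.
#' @param port name (or index) of the soma port to consume.
#' @param max_diameter_ratio largest tolerated ratio between port and ring
#'   diameters before erroring.
#' @return the joined [trimesh()].
#' @export
attach_to_soma <- function(soma, tube, port, max_diameter_ratio = 2) {
  p <- soma$ports[[port]]
  if (is.null(p)) nm_arg_error(sprintf("soma has no port '%s'", port))
  pb <- tube$ports$start
  if (is.null(pb)) nm_arg_error("tube must carry a 'start' port")
  ratio <- max(p$radius, pb$radius) / min(p$radius, pb$radius)
  if (ratio > max_diameter_ratio)
    nm_geometry_error(sprintf(
      "port and tube diameters mismatch beyond tolerance at stem '%s' (ratio %.2f)",
      as.character(port), ratio))
  hole <- open_hole_at(soma, p$center_vertex)
  hole$mesh$ports[[port]] <- NULL
  mm <- merge_meshes(hole$mesh, tube)
  merged <- mm$mesh
  merged$ports[["start"]] <- NULL
  stitch_loops(merged, hole$loop, pb$loop + mm$offset, axis = p$axis)
}

#' Assemble a complete watertight neuron mesh
#'
#' Runs soma building, per-stem tube sweeping, and all stitching (soma
#' attachment, consecutive links, bifurcation hole-and-sew, terminal caps)
#' into one closed 2-manifold mesh, optionally Laplacian-smoothed with
#' junction rings protected.
#'
#' @param m a [neuron_morphology()].
#' @param res a [resolution_params()].
#' @param params a [deform_params()].
#' @param smooth_iterations,smooth_factor smoothing controls (0 iterations
#'   disables smoothing).
#' @param min_radius clamp for zero radii in the tracing, micrometres.
#' @return a closed [trimesh()]; `attr(, "junction_vertices")` holds the
#'   protected ring vertices.
#' @export
assemble_neuron <- function(m, res = resolution_params(),
                            params = deform_params(),
                            smooth_iterations = 0L, smooth_factor = 0.3,
                            min_radius = 0.05) {
  mesh <- build_soma(m, params)
  junction <- integer(0)
  remap <- function(idx, vmap) {
    out <- vmap[idx]
    out[!is.na(out)]
  }
  for (s in seq_along(m$stems)) {
    strips <- build_chain_strips(m, m$stems[s], res, min_radius)
    chain_ports <- vector("list", length(strips))  # per-chain start/end loops
    for (ci in seq_along(strips)) {
      st <- strips[[ci]]
      tube <- st$mesh
      start_port <- tube$ports$start
      end_port <- tube$ports$end  # NULL when capped terminal
      tube$ports <- list()
      ch <- st$chain
      remap_ports <- function(vmap) {
        junction <<- remap(junction, vmap)
        chain_ports <<- lapply(chain_ports, function(cp) {
          if (is.null(cp) || is.null(cp$end_loop)) return(cp)
          cp$end_loop <- remap(cp$end_loop, vmap)
          cp
        })
      }
      if (is.na(ch$parent_chain)) {
        # root chain: consume the soma port
        pname <- paste0("stem", s)
        p <- mesh$ports[[pname]]
        hole <- open_hole_at(mesh, p$center_vertex)
        remap_ports(hole$vmap)
        mesh <- hole$mesh
        mesh$ports[[pname]] <- NULL
        mm <- merge_meshes(mesh, tube)
        mesh <- mm$mesh
        sl <- start_port$loop + mm$offset
        el <- if (!is.null(end_port)) end_port$loop + mm$offset else NULL
        mesh <- stitch_loops(mesh, hole$loop, sl, axis = p$axis)
        junction <- c(junction, hole$loop, sl)
      } else {
        parent <- chain_ports[[ch$parent_chain]]
        mm <- merge_meshes(mesh, tube)
        mesh <- mm$mesh
        sl <- start_port$loop + mm$offset
        el <- if (!is.null(end_port)) end_port$loop + mm$offset else NULL
        if (isTRUE(ch$is_first_child)) {
          mesh <- stitch_loops(mesh, parent$end_loop, sl,
                               axis = start_port$axis)
          junction <- c(junction, parent$end_loop, sl)
        } else {
          d2 <- rowSums(sweep(mesh$vertices, 2, start_port$center, "-")^2)
          # the hole must open in the existing closed wall, never in the
          # child's own (still open) tube
          d2[seq(mm$offset + 1L, n_vertices(mesh))] <- Inf
          anchor <- which.min(d2)
          hole <- open_hole_at(mesh, anchor)
          remap_ports(hole$vmap)
          sl <- remap(sl, hole$vmap)
          el <- if (!is.null(el)) remap(el, hole$vmap) else NULL
          mesh <- hole$mesh
          mesh <- stitch_loops(mesh, hole$loop, sl)
          junction <- c(junction, hole$loop, sl)
        }
      }
      chain_ports[[ci]] <- list(end_loop = el)
    }
  }
  if (smooth_iterations > 0L) {
    mesh <- laplacian_smooth(mesh, iterations = smooth_iterations,
                             factor = smooth_factor,
                             protected = unique(junction))
  }
  attr(mesh, "junction_vertices") <- sort(unique(junction))
  mesh
}
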