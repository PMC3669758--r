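#' Tube resolution parameters
#'
#' The two level-of-detail knobs of the tube mesher: the number of
#' intermediate cross-sections between a cone's two bases, and the number of
#' points used to approximate the circular shape of each section.
#'
#' @param cross_sections non-negative integer.
#' @param points_per_section integer >= 3.
#' @return an object of class `resolution_params`.
#' @export
resolution_params <- function(cross_sections = 4L, points_per_section = 6L) {
  cross_sections <- as.integer(cross_sections)
  points_per_section <- as.integer(points_per_section)
  if (is.na(cross_sections) || cross_sections < 0L)
    nm_arg_error("cross_sections must be a non-negative integer")
  if (is.na(points_per_section) || points_per_section < 3L)
    nm_arg_error("points_per_section must be >= 3")
  structure(list(cross_sections = cross_sections,
                 points_per_section = points_per_section),
            class = "resolution_params")
}

#' Radius of an intermediate cross-section
#'
#' Linear interpolation in arc length between the two base radii of a
#' truncated cone: `r0 + t (r1 - r0)`.
#'
#' @param t position along the axis in `[0, 1]` (vectorized).
#' @param r0,r1 base radii.
#' @return interpolated radius (same length as `t`).
#' @export
interpolate_radius <- function(t, r0, r1) {
  if (any(t < 0 | t > 1)) nm_arg_error("t must lie in [0, 1]")
  r0 + t * (r1 - r0)
}

# vertices of one polygonal ring; frame (e1, e2, normal) right-handed
ring_vertices <- function(center, e1, e2, radius, p) {
  phi <- 2 * pi * (seq_len(p) - 1L) / p
  sweep(outer(cos(phi), e1) * radius + outer(sin(phi), e2) * radius,
        2, center, "+")
}

# side faces between consecutive rings a (indices) and b (further along the
# axis), outward winding for a right-handed frame
ring_band_faces <- function(a, b) {
  p <- length(a)
  nxt <- c(2:p, 1L)
  rbind(cbind(a, a[nxt], b[nxt]),
        cbind(a, b[nxt], b))
}

#' Mesh a truncated cone
#'
#' Swept frustum for one skeleton segment: `cross_sections + 2` rings (the
#' two bases plus intermediates), `points_per_section` vertices per ring with
#' a shared reference direction (no twist), ring radii linearly interpolated
#' along the axis. The tube is open at both bases.
#'
#' @param p0,p1 axis endpoints, 3-vectors (micrometres).
#' @param r0,r1 positive base radii.
#' @param res a [resolution_params()].
#' @return an open [trimesh()] with ports `start` and `end`.
#' @export
build_truncated_cone <- function(p0, p1, r0, r1, res = resolution_params()) {
  if (r0 <= 0 || r1 <= 0) nm_arg_error("base radii must be positive")
  axis <- as.numeric(p1) - as.numeric(p0)
  if (vnorm(axis) < 1e-12) nm_geometry_error("degenerate zero-length cone axis")
  u <- axis / vnorm(axis)
  e1 <- orthogonal_vector(u)
  e2 <- vcross(u, e1)
  R <- res$cross_sections + 2L
  p <- res$points_per_section
  t <- (seq_len(R) - 1L) / (R - 1L)
  verts <- do.call(rbind, lapply(seq_len(R), function(i) {
    ring_vertices(p0 + t[i] * axis, e1, e2, interpolate_radius(t[i], r0, r1), p)
  }))
  faces <- do.call(rbind, lapply(seq_len(R - 1L), function(i) {
    ring_band_faces((i - 1L) * p + seq_len(p), i * p + seq_len(p))
  }))
  ring_start <- seq_len(p)
  ring_end <- (R - 1L) * p + seq_len(p)
  trimesh(verts, faces, ports = list(
    start = list(loop = ring_start, center = as.numeric(p0), axis = u,
                 radius = r0),
    end = list(loop = ring_end, center = as.numeric(p1), axis = u,
               radius = r1)))
}

#' Place tube cross-sections along a skeleton path
#'
#' Rings are not spread evenly: one ring sits at every path point (tilted to
#' the bisector plane at interior joints so adjacent segments meet without
#' crossing), and each segment's intermediate rings are confined to the
#' interior span that stays at least `max(local radius, 0.1 L)` away from
#' either end. Segments too short for their end gaps get zero intermediate
#' rings (logged fallback). Frames are parallel-transported so rings do not
#' twist.
#'
#' @param path data.frame with columns `x`, `y`, `z`, `radius` (>= 2 rows);
#'   an optional logical column `at_point` is ignored on input.
#' @param res a [resolution_params()].
#' @param start_offset optional distance by which the first ring is pushed
#'   along the first segment (used for fork children), 0 for none.
#' @return data.frame of ring placements: center (`x,y,z`), `normal.*`,
#'   `ref.*` (transported reference direction), `radius`, `at_point`
#'   (TRUE when the ring realizes a morphological point), `point_row`.
#' @export
place_cross_sections <- function(path, res = resolution_params(),
                                 start_offset = 0) {
  pos <- as.matrix(path[, c("x", "y", "z")])
  rad <- path$radius
  n <- nrow(pos)
  if (n < 2L) nm_arg_error("path needs at least 2 points")
  if (start_offset > 0) {
    d <- pos[2L, ] - pos[1L, ]
    L <- vnorm(d)
    off <- min(start_offset, 0.49 * L)
    t <- off / L
    pos[1L, ] <- pos[1L, ] + d * t
    rad[1L] <- interpolate_radius(t, rad[1L], rad[2L])
  }
  segdir <- t(vapply(seq_len(n - 1L),
                     function(i) vunit(pos[i + 1L, ] - pos[i, ]),
                     numeric(3)))
  # per-path-point ring normals: segment dir at the ends, bisector inside
  normals <- matrix(0, n, 3L)
  normals[1L, ] <- segdir[1L, ]
  normals[n, ] <- segdir[n - 1L, ]
  if (n > 2L) for (i in 2:(n - 1L)) {
    s <- segdir[i - 1L, ] + segdir[i, ]
    normals[i, ] <- if (vnorm(s) < 1e-9) orthogonal_vector(segdir[i - 1L, ]) else vunit(s)
  }
  rows <- list()
  add_ring <- function(center, normal, radius, at_point, point_row) {
    rows[[length(rows) + 1L]] <<- data.frame(
      x = center[1], y = center[2], z = center[3],
      nx = normal[1], ny = normal[2], nz = normal[3],
      radius = radius, at_point = at_point, point_row = point_row)
  }
  add_ring(pos[1L, ], normals[1L, ], rad[1L],
           at_point = start_offset == 0, point_row = 1L)
  for (i in seq_len(n - 1L)) {
    L <- vnorm(pos[i + 1L, ] - pos[i, ])
    cs <- res$cross_sections
    if (cs > 0L) {
      g0 <- max(rad[i], 0.1 * L)
      g1 <- max(rad[i + 1L], 0.1 * L)
      if (g0 + g1 >= L) {
        nm_fallback(sprintf(
          "segment %d too short (%.3g um) for cross-section end gaps; placing 0 intermediate sections",
          i, L))
        cs <- 0L
      } else {
        tpos <- if (cs == 1L) (g0 + (L - g1)) / 2 else
          seq(g0, L - g1, length.out = cs)
        for (s in tpos / L) {
          add_ring(pos[i, ] + s * (pos[i + 1L, ] - pos[i, ]), segdir[i, ],
                   interpolate_radius(s, rad[i], rad[i + 1L]),
                   at_point = FALSE, point_row = NA_integer_)
        }
      }
    }
    add_ring(pos[i + 1L, ], normals[i + 1L, ], rad[i + 1L],
             at_point = TRUE, point_row = i + 1L)
  }
  out <- do.call(rbind, rows)
  # parallel-transport a reference direction down the ring stack
  ref <- matrix(0, nrow(out), 3L)
  nrm <- as.matrix(out[, c("nx", "ny", "nz")])
  ref[1L, ] <- orthogonal_vector(nrm[1L, ])
  if (nrow(out) > 1L) for (i in 2:nrow(out)) {
    r <- rotate_between(ref[i - 1L, ], nrm[i - 1L, ], nrm[i, ])
    r <- r - sum(r * nrm[i, ]) * nrm[i, ]
    ref[i, ] <- vunit(r)
  }
  out$rx <- ref[, 1]; out$ry <- ref[, 2]; out$rz <- ref[, 3]
  out
}

# sweep a placed ring stack into an open tube mesh
sweep_ring_stack <- function(placements, p, cap_end = FALSE) {
  nr <- nrow(placements)
  verts <- do.call(rbind, lapply(seq_len(nr), function(i) {
    nrm <- as.numeric(placements[i, c("nx", "ny", "nz")])
    e1 <- as.numeric(placements[i, c("rx", "ry", "rz")])
    e2 <- vcross(nrm, e1)
    ring_vertices(as.numeric(placements[i, c("x", "y", "z")]), e1, e2,
                  placements$radius[i], p)
  }))
  faces <- do.call(rbind, lapply(seq_len(nr - 1L), function(i) {
    ring_band_faces((i - 1L) * p + seq_len(p), i * p + seq_len(p))
  }))
  ports <- list(
    start = list(loop = seq_len(p),
                 center = as.numeric(placements[1L, c("x", "y", "z")]),
                 axis = as.numeric(placements[1L, c("nx", "ny", "nz")]),
                 radius = placements$radius[1L]),
    end = list(loop = (nr - 1L) * p + seq_len(p),
               center = as.numeric(placements[nr, c("x", "y", "z")]),
               axis = as.numeric(placements[nr, c("nx", "ny", "nz")]),
               radius = placements$radius[nr]))
  if (cap_end) {
    apex <- nrow(verts) + 1L
    verts <- rbind(verts, as.numeric(placements[nr, c("x", "y", "z")]))
    loop <- ports$end$loop
    nxt <- c(2:p, 1L)
    faces <- rbind(faces, cbind(rep(apex, p), loop, loop[nxt]))
    ports$end <- NULL
  }
  trimesh(verts, faces, ports = ports)
}

# decompose the subtree rooted at a stem into unbranched chains.
# Returns a list of chains: each has $rows (row indices into m$points along
# the chain; fork-child chains start at the fork point so the fork->child
# segment is meshed), $parent_chain, $is_first_child, $first_child_row (row
# of the first child point when the chain ends at a fork, NA when terminal).
stem_chains <- function(m, stem_id) {
  pts <- m$points
  kids <- split(seq_len(nrow(pts)), factor(pts$parent, levels = pts$id))
  child_rows <- function(id) {
    k <- kids[[as.character(id)]]
    if (is.null(k)) integer(0) else k[order(pts$id[k])]
  }
  pos <- as.matrix(pts[, c("x", "y", "z")])
  chains <- list()
  walk <- function(rows, parent_chain, is_first_child) {
    repeat {
      ch <- child_rows(pts$id[rows[length(rows)]])
      if (length(ch) == 1L) {
        rows <- c(rows, ch)
      } else break
    }
    idx <- length(chains) + 1L
    ch <- child_rows(pts$id[rows[length(rows)]])
    fork_row <- rows[length(rows)]
    chains[[idx]] <<- list(rows = rows, parent_chain = parent_chain,
                           is_first_child = is_first_child,
                           first_child_row = if (length(ch)) ch[1L] else NA_integer_)
    for (k in seq_along(ch)) walk(c(fork_row, ch[k]), idx, k == 1L)
  }
  walk(match(stem_id, pts$id), NA_integer_, NA)
  chains
}

#' Mesh the arbor of one stem as unstitched tube strips
#'
#' One open tube strip per unbranched fork-to-fork chain, swept with
#' parallel-transported frames; ring radii equal the stored morphological
#' radii exactly at morphological points, terminal tips are closed with a
#' flat triangle-fan cap. Zero radii at non-terminal points are clamped to
#' `min_radius` (logged). Strips are returned merged but unstitched — see
#' [assemble_neuron()] for the watertight assembly.
#'
#' @param m a [neuron_morphology()].
#' @param stem_id id of the stem's first point (an element of `m$stems`).
#' @param res a [resolution_params()].
#' @param min_radius clamp for zero/absent radii, micrometres.
#' @return an open [trimesh()]; strips carry ports `chain<i>.start` /
#'   `chain<i>.end` (terminal chains are capped and have no end port).
#' @export
build_branch_mesh <- function(m, stem_id, res = resolution_params(),
                              min_radius = 0.05) {
  strips <- build_chain_strips(m, stem_id, res, min_radius)
  out <- NULL
  for (i in seq_along(strips)) {
    s <- strips[[i]]$mesh
    names(s$ports) <- paste0("chain", i, ".", names(s$ports))
    out <- if (is.null(out)) s else merge_meshes(out, s)$mesh
  }
  out
}

# internal: strips plus chain metadata for assembly
build_chain_strips <- function(m, stem_id, res, min_radius = 0.05) {
  chains <- stem_chains(m, stem_id)
  pts <- m$points
  lapply(seq_along(chains), function(ci) {
    ch <- chains[[ci]]
    path <- pts[ch$rows, c("x", "y", "z", "radius")]
    terminal_row <- ch$rows[length(ch$rows)]
    is_terminal <- !any(pts$parent == pts$id[terminal_row])
    clamp <- path$radius < min_radius
    if (any(clamp)) {
      nm_fallback(sprintf("clamped %d radii below %g um to the minimum",
                          sum(clamp), min_radius))
      path$radius[clamp] <- min_radius
    }
    off <- if (is.na(ch$parent_chain)) 0 else {
      p0 <- as.numeric(path[1L, c("x", "y", "z")])
      p1 <- as.numeric(path[2L, c("x", "y", "z")])
      L1 <- vnorm(p1 - p0)
      base <- max(path$radius[1L], 0.1 * L1)
      if (isTRUE(ch$is_first_child)) base else {
        # sewn child: displace its base until the start ring clears the
        # parent tube wall (the fork point lies on the parent axis, so a
        # child leaving at angle theta needs ~ r_parent / sin(theta))
        ppid <- pts$parent[ch$rows[1L]]
        prow <- match(ppid, pts$id)
        clearance <- if (!is.na(prow)) {
          din <- vunit(p0 - as.numeric(pts[prow, c("x", "y", "z")]))
          sint <- sqrt(max(1 - sum(din * vunit(p1 - p0))^2, 0.04))
          (path$radius[1L] + 0.3 * path$radius[2L]) / sint
        } else base
        min(max(base, clearance), 0.49 * L1)
      }
    }
    pl <- place_cross_sections(path, res, start_offset = off)
    if (!is_terminal && !is.na(ch$first_child_row)) {
      # tilt the end ring to the bisector of the incoming segment and the
      # first child's outgoing segment so the fork band does not fold
      fpos <- as.numeric(path[nrow(path), c("x", "y", "z")])
      cpos <- as.numeric(pts[ch$first_child_row, c("x", "y", "z")])
      dir_out <- vunit(cpos - fpos)
      last <- nrow(pl)
      dir_in <- as.numeric(pl[last, c("nx", "ny", "nz")])
      bis <- dir_in + dir_out
      if (vnorm(bis) > 1e-9) {
        bis <- vunit(bis)
        refv <- rotate_between(as.numeric(pl[last, c("rx", "ry", "rz")]),
                               dir_in, bis)
        refv <- vunit(refv - sum(refv * bis) * bis)
        pl[last, c("nx", "ny", "nz")] <- bis
        pl[last, c("rx", "ry", "rz")] <- refv
      }
    }
    mesh <- sweep_ring_stack(pl, res$points_per_section, cap_end = is_terminal)
    list(mesh = mesh, chain = ch, placements = pl, terminal = is_terminal)
  })
}
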