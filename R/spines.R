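#' Spine density profile
#'
#' Linear spine densities (spines per micrometre of dendritic arc) by
#' dendrite type and distance-from-soma bin. The packaged defaults are
#' synthetic placeholders in the plausible cortical range; laboratories
#' should load their own measured table with [read_density_profile()].
#'
#' @param table data.frame with columns `type` (point type or `"all"`),
#'   `bin_start`, `bin_end` (path distance from soma, um; non-overlapping,
#'   ordered) and `density` (spines/um, >= 0).
#' @return an object of class `spine_density_profile`.
#' @export
spine_density_profile <- function(table = default_density_table()) {
  table <- as.data.frame(table)
  needed <- c("type", "bin_start", "bin_end", "density")
  if (!all(needed %in% names(table)))
    nm_arg_error("profile needs columns type, bin_start, bin_end, density")
  if (any(table$density < 0)) nm_arg_error("densities must be >= 0")
  if (any(table$bin_end <= table$bin_start))
    nm_arg_error("bins must be ordered (bin_end > bin_start)")
  for (ty in unique(table$type)) {
    b <- table[table$type == ty, , drop = FALSE]
    b <- b[order(b$bin_start), , drop = FALSE]
    if (nrow(b) > 1L && any(b$bin_start[-1] < b$bin_end[-nrow(b)]))
      nm_arg_error(sprintf("overlapping bins for type '%s'", ty))
  }
  structure(list(table = table), class = "spine_density_profile")
}

# synthetic default densities (spines/um), flagged as such: not a measured
# dataset, just plausible magnitudes for exercising the machinery
default_density_table <- function() {
  data.frame(
    type = "all",
    bin_start = c(0, 30, 100),
    bin_end = c(30, 100, 1e6),
    density = c(0.3, 1.2, 0.8))
}

#' Read a spine density profile from a tabular text file
#'
#' Whitespace- or tab-delimited with a header line
#' `type bin_start bin_end density`.
#'
#' @param path file path.
#' @return a [spine_density_profile()].
#' @export
read_density_profile <- function(path) {
  spine_density_profile(utils::read.table(path, header = TRUE,
                                          stringsAsFactors = FALSE))
}

profile_density <- function(profile, type, distance) {
  tb <- profile$table
  cand <- tb[(tb$type == type | tb$type == "all") &
               tb$bin_start <= distance & distance < tb$bin_end, , drop = FALSE]
  if (nrow(cand) == 0L) return(0)
  # exact type match wins over "all"
  if (any(cand$type == type)) cand$density[cand$type == type][1] else
    cand$density[1]
}

#' Sample spine anchor positions along the dendrites
#'
#' Per unbranched branch (fork-to-fork chain), the spine count is exactly
#' `round(density * branch length)` with the density looked up at the
#' branch's midpoint path distance from the soma; arc-length positions are
#' uniform along the branch, azimuths uniform on [0, 2 pi). Fully
#' reproducible from `seed`. The axon is skipped (spines live on dendrites).
#'
#' @param m a [neuron_morphology()].
#' @param profile a [spine_density_profile()].
#' @param seed integer seed.
#' @return data.frame: `stem`, `chain`, `arc_pos` (um from branch start),
#'   `azimuth` (radians), `x`, `y`, `z`, `radius`, `nx,ny,nz` (local branch
#'   direction).
#' @export
sample_spine_positions <- function(m, profile = spine_density_profile(),
                                   seed = 1L) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)
  pts <- m$points
  path_dist <- morphology_path_distances(m)
  out <- list()
  for (s in seq_along(m$stems)) {
    stem_type <- pts$type[match(m$stems[s], pts$id)]
    if (stem_type == "axon") next
    chains <- stem_chains(m, m$stems[s])
    for (ci in seq_along(chains)) {
      rows <- chains[[ci]]$rows
      if (length(rows) < 2L) next
      pos <- as.matrix(pts[rows, c("x", "y", "z")])
      seglen <- rowwise_norm(pos[-1L, , drop = FALSE] - pos[-nrow(pos), , drop = FALSE])
      len <- sum(seglen)
      mid_dist <- path_dist[rows[1L]] + len / 2
      dens <- profile_density(profile, stem_type, mid_dist)
      count <- round(dens * len)
      if (count < 1L) next
      arc <- sort(stats::runif(count, 0, len))
      az <- stats::runif(count, 0, 2 * pi)
      cum <- c(0, cumsum(seglen))
      seg <- findInterval(arc, cum, rightmost.closed = TRUE)
      seg[seg > length(seglen)] <- length(seglen)
      t <- (arc - cum[seg]) / seglen[seg]
      p <- pos[seg, , drop = FALSE] +
        (pos[seg + 1L, , drop = FALSE] - pos[seg, , drop = FALSE]) * t
      r <- pts$radius[rows][seg] * (1 - t) + pts$radius[rows][seg + 1L] * t
      d <- (pos[seg + 1L, , drop = FALSE] - pos[seg, , drop = FALSE]) / seglen[seg]
      out[[length(out) + 1L]] <- data.frame(
        stem = s, chain = ci, arc_pos = arc, azimuth = az,
        x = p[, 1], y = p[, 2], z = p[, 3], radius = r,
        nx = d[, 1], ny = d[, 2], nz = d[, 3])
    }
  }
  if (length(out) == 0L)
    return(data.frame(stem = integer(0), chain = integer(0),
                      arc_pos = numeric(0), azimuth = numeric(0),
                      x = numeric(0), y = numeric(0), z = numeric(0),
                      radius = numeric(0), nx = numeric(0), ny = numeric(0),
                      nz = numeric(0)))
  do.call(rbind, out)
}

# path distance from the soma to every point (by id order of m$points rows)
morphology_path_distances <- function(m) {
  pts <- m$points
  idx <- match(pts$parent, pts$id)
  d <- rep(NA_real_, nrow(pts))
  resolve <- function(i) {
    if (!is.na(d[i])) return(d[i])
    p <- idx[i]
    val <- if (is.na(p)) 0 else {
      resolve(p) + vnorm(as.numeric(pts[i, c("x", "y", "z")]) -
                           as.numeric(pts[p, c("x", "y", "z")]))
    }
    d[i] <<- val
    val
  }
  for (i in seq_len(nrow(pts))) resolve(i)
  d
}

#' Parametric spine templates
#'
#' Two built-in shapes in canonical pose (attachment base ring in the z = 0
#' plane, axis +z, unit length): `"stubby"` (a hemisphere) and `"thin"` (a
#' sphere head on a cylindrical neck). Both are open only at the attachment
#' ring. These are parametric stand-ins, not segmented spine reconstructions.
#'
#' @param name `"stubby"` or `"thin"`.
#' @param points_per_ring ring resolution of the template.
#' @return list of class `spine_template`: `name`, `mesh` (open
#'   [trimesh()] with a `base` port), `length_scale` (um).
#' @export
spine_template <- function(name = c("stubby", "thin"), points_per_ring = 8L) {
  name <- match.arg(name)
  p <- as.integer(points_per_ring)
  prof <- if (name == "stubby") {
    # hemisphere: radius 1 at base shrinking to pole at z = 1
    th <- seq(0, pi / 2, length.out = 5L)
    data.frame(r = cos(th), z = sin(th))
  } else {
    # neck radius 0.28 to z = 0.45, sphere head radius 0.5 centered 0.95/1.45
    th <- seq(-0.98, 1, length.out = 7L) * (pi / 2)
    head <- data.frame(r = 0.5 * cos(th * 0.98), z = 0.72 + 0.5 * sin(th * 0.98))
    rbind(data.frame(r = c(0.28, 0.28), z = c(0, 0.35)), head)
  }
  prof$z <- prof$z / max(prof$z)  # unit length
  mesh <- lathe_mesh(prof, p)
  structure(list(name = name, mesh = mesh,
                 length_scale = if (name == "stubby") 0.7 else 1.3),
            class = "spine_template")
}

# revolve a (r, z) profile about +z; closed at the top (last r ~ 0), open at
# the base ring (port "base")
lathe_mesh <- function(prof, p) {
  nr <- nrow(prof)
  rings <- which(prof$r > 1e-9)
  verts <- NULL
  for (i in rings) {
    verts <- rbind(verts, ring_vertices(c(0, 0, prof$z[i]),
                                        c(1, 0, 0), c(0, 1, 0),
                                        prof$r[i], p))
  }
  nring <- length(rings)
  faces <- NULL
  for (i in seq_len(nring - 1L)) {
    faces <- rbind(faces, ring_band_faces((i - 1L) * p + seq_len(p),
                                          i * p + seq_len(p)))
  }
  # apex cap
  apex <- nring * p + 1L
  zt <- prof$z[nr]
  verts <- rbind(verts, c(0, 0, max(zt, prof$z[rings[nring]] + 1e-6)))
  top <- (nring - 1L) * p + seq_len(p)
  nxt <- c(2:p, 1L)
  faces <- rbind(faces, cbind(rep(apex, p), top, top[nxt]))
  trimesh(verts, faces, ports = list(
    base = list(loop = seq_len(p), center = c(0, 0, 0), axis = c(0, 0, 1),
                radius = prof$r[rings[1L]])))
}

#' Attach spines to a closed neuron mesh
#'
#' Each spine instance is scaled to its template's length scale (with
#' optional log-normal size jitter), oriented along the outward surface
#' normal at its anchor, and merged watertight by the same hole-and-sew
#' machinery used at bifurcations: the anchor vertex's triangle fan is
#' erased and the hole contour is sewn to the template's base ring. The
#' result stays closed and 2-manifold; each spine strictly adds enclosed
#' volume. Anchors that would fall on a junction band or another spine are
#' shifted to the nearest free vertex (logged).
#'
#' @param mesh closed neuron [trimesh()] (see [assemble_neuron()]).
#' @param placements data.frame from [sample_spine_positions()].
#' @param templates list of [spine_template()] objects.
#' @param weights sampling weights over `templates`.
#' @param seed integer seed (template choice + size jitter).
#' @param size_jitter_sd log-normal sigma of per-instance scale (0 disables).
#' @param protected vertex indices never used as anchors (junction rings);
#'   defaults to the mesh's recorded junction vertices.
#' @return the decorated closed [trimesh()].
#' @export
place_spines <- function(mesh, placements, templates = list(
                           spine_template("stubby"), spine_template("thin")),
                         weights = NULL, seed = 1L, size_jitter_sd = 0.1,
                         protected = NULL) {
  if (nrow(placements) == 0L) return(mesh)
  if (is.null(weights)) weights <- rep(1, length(templates))
  if (is.null(protected))
    protected <- attr(mesh, "junction_vertices") %||% integer(0)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)
  tchoice <- sample.int(length(templates), nrow(placements), replace = TRUE,
                        prob = weights)
  jit <- if (size_jitter_sd > 0)
    stats::rlnorm(nrow(placements), 0, size_jitter_sd) else
      rep(1, nrow(placements))
  used <- rep(FALSE, n_vertices(mesh))
  used[protected] <- TRUE
  for (k in seq_len(nrow(placements))) {
    pl <- placements[k, ]
    axis <- vunit(as.numeric(pl[c("nx", "ny", "nz")]))
    e1 <- orthogonal_vector(axis)
    e2 <- vcross(axis, e1)
    surf <- as.numeric(pl[c("x", "y", "z")]) +
      pl$radius * (cos(pl$azimuth) * e1 + sin(pl$azimuth) * e2)
    d2 <- rowSums(sweep(mesh$vertices, 2, surf, "-")^2)
    ord <- order(d2)
    anchor <- ord[!used[ord]][1L]
    if (is.na(anchor)) nm_geometry_error("no free anchor vertex left for spine")
    if (anchor != ord[1L])
      nm_fallback(sprintf(
        "spine %d anchor shifted off a junction/spine vertex to vertex %d",
        k, anchor))
    normal <- vertex_outward_normal(mesh, anchor)
    tmpl <- templates[[tchoice[k]]]
    inst <- instantiate_template(tmpl, at = mesh$vertices[anchor, ],
                                 normal = normal, scale = tmpl$length_scale * jit[k])
    hole <- open_hole_at(mesh, anchor)
    used <- used[-anchor]
    mm <- merge_meshes(hole$mesh, inst)
    mesh2 <- mm$mesh
    base_loop <- inst$ports$base$loop + mm$offset
    mesh2$ports[["base"]] <- NULL
    mesh <- stitch_loops(mesh2, hole$loop, base_loop, axis = normal)
    used <- c(used, rep(TRUE, n_vertices(inst)))
    used[hole$loop] <- TRUE
  }
  attr(mesh, "junction_vertices") <- which(used)
  mesh
}

vertex_outward_normal <- function(mesh, v) {
  inc <- which(rowSums(matrix(mesh$faces == v, ncol = 3L)) > 0L)
  n <- c(0, 0, 0)
  for (fi in inc) {
    f <- mesh$faces[fi, ]
    a <- mesh$vertices[f[1], ]
    b <- mesh$vertices[f[2], ]
    cc <- mesh$vertices[f[3], ]
    n <- n + vcross(b - a, cc - a)
  }
  vunit(n)
}

instantiate_template <- function(tmpl, at, normal, scale) {
  mesh <- tmpl$mesh
  base_r <- mesh$ports$base$radius
  v <- mesh$vertices * scale
  rot <- t(apply(v, 1, rotate_between, a = c(0, 0, 1), b = normal))
  mesh$vertices <- sweep(rot, 2, as.numeric(at), "+")
  mesh$ports$base$center <- as.numeric(at)
  mesh$ports$base$axis <- normal
  mesh$ports$base$radius <- base_r * scale
  mesh
}
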