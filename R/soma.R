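#' Soma deformation parameters
#'
#' Defaults for the mass-spring soma stage. `pull_distance_scale` scales how
#' far each region is driven toward its stem (1 = exactly to the stem's first
#' traced point); `roi_threshold_scale` scales the geodesic threshold that
#' delimits each region of influence (1 = the stem diameter).
#'
#' @param stiffness,internal_stiffness,damping,mass,dt mass-spring constants,
#'   see [build_spring_system()].
#' @param max_steps step budget of the relaxation.
#' @param kinetic_tolerance per-node kinetic-energy convergence threshold.
#' @param subdivisions icosphere subdivision level of the initial sphere.
#' @param reduction_fraction uniform shrink applied before deformation.
#' @param pull_distance_scale,roi_threshold_scale the two deformation knobs.
#' @return named list of class `deform_params`.
#' @export
deform_params <- function(stiffness = 10, internal_stiffness = 1,
                          damping = 0.5, mass = 1, dt = 0.01,
                          max_steps = 20000L, kinetic_tolerance = 1e-8,
                          subdivisions = 3L, reduction_fraction = 0.5,
                          pull_distance_scale = 1, roi_threshold_scale = 1) {
  structure(as.list(environment()), class = "deform_params")
}

#' Deform the reduced soma sphere toward its first-order neurites
#'
#' Each stem selects a geodesic region of influence on the sphere; those
#' vertices are pinned and driven (linearly over the first quarter of the
#' step budget) to the stem's starting cross-section: the seed to the disc
#' center, the other members onto the starting disc, preserving their angular
#' order about the stem axis. Free vertices then relax under the damped
#' mass-spring dynamics until the total kinetic energy falls below tolerance
#' — the discrete energy-minimization reading of a constrained elastic
#' surface. Internal springs to the sphere center prevent collapse. Topology
#' is never changed.
#'
#' @param sphere the reduced sphere, a closed [trimesh()].
#' @param stems data.frame from [first_order_stems()] (zero rows legal).
#' @param params a [deform_params()].
#' @return list with `mesh` (deformed [trimesh()]) and `regions` (list of
#'   `region_of_influence`, each annotated with its disc `center`, `axis` and
#'   `radius`, plus per-member `targets`).
#' @export
deform_soma <- function(sphere, stems, params = deform_params(),
                        cap_conflicts = FALSE) {
  ctr <- colMeans(sphere$vertices)
  nstem <- if (is.null(stems)) 0L else nrow(stems)
  regions <- list()
  if (nstem > 0L) {
    thr <- 2 * stems$radius * params$roi_threshold_scale
    make_roi <- function(s) {
      roi <- compute_region_of_influence(
        sphere, as.numeric(stems[s, c("x", "y", "z")]), thr[s])
      roi$stem_index <- s
      roi
    }
    for (s in seq_len(nstem)) regions[[s]] <- make_roi(s)
    conflicts <- function() {
      out <- NULL
      for (a in seq_len(max(nstem - 1L, 0L))) for (b in (a + 1L):nstem) {
        # members must be disjoint, and no region may reach into another's
        # frontier: ports one edge apart would share contour vertices
        zone_a <- c(regions[[a]]$members, regions[[a]]$boundary)
        zone_b <- c(regions[[b]]$members, regions[[b]]$boundary)
        if (length(intersect(zone_a, regions[[b]]$members)) ||
              length(intersect(zone_b, regions[[a]]$members)))
          out <- rbind(out, c(a, b))
      }
      out
    }
    bad <- conflicts()
    if (!is.null(bad) && cap_conflicts) {
      # geodesic-Voronoi fallback: conflicting stems split the separation
      # between their seeds instead of claiming the full stem diameter
      for (k in seq_len(nrow(bad))) {
        a <- bad[k, 1]; b <- bad[k, 2]
        sep <- geodesic_distances(sphere, regions[[a]]$seed)[regions[[b]]$seed]
        thr[a] <- min(thr[a], 0.45 * sep)
        thr[b] <- min(thr[b], 0.45 * sep)
        nm_fallback(sprintf(
          "regions of stems %d and %d overlap; capping their geodesic thresholds to %.3g um",
          a, b, 0.45 * sep))
      }
      for (s in unique(as.vector(bad))) regions[[s]] <- make_roi(s)
      bad <- conflicts()
    }
    if (!is.null(bad))
      nm_stop(sprintf(
        "regions of influence of stems %d and %d overlap or touch; increase sphere subdivisions",
        bad[1, 1], bad[1, 2]), "nm_region_conflict_error")
    for (s in seq_len(nstem)) {
      regions[[s]] <- annotate_region_targets(
        sphere, regions[[s]], ctr,
        axis = as.numeric(stems[s, c("dx", "dy", "dz")]),
        stem_start = as.numeric(stems[s, c("x", "y", "z")]),
        stem_radius = stems$radius[s],
        pull_scale = params$pull_distance_scale)
    }
  }
  if (nstem == 0L) {
    out <- sphere
    return(list(mesh = out, regions = regions))
  }
  sys <- build_spring_system(sphere, stiffness = params$stiffness,
                             internal_stiffness = params$internal_stiffness,
                             damping = params$damping, mass = params$mass,
                             dt = params$dt)
  pinned <- unlist(lapply(regions, `[[`, "members"))
  targets <- do.call(rbind, lapply(regions, `[[`, "targets"))
  res <- .relax_verlet(
    positions = sys$pos,
    spring_i = sys$springs$i, spring_j = sys$springs$j,
    L0 = sys$springs$L0, K = sys$springs$k,
    center = sys$center,
    mass = params$mass, damping = params$damping, dt = params$dt,
    pinned = as.integer(pinned),
    pin_from = sys$pos[pinned, , drop = FALSE],
    pin_to = targets,
    schedule_steps = as.integer(ceiling(params$max_steps * 0.25)),
    max_steps = as.integer(params$max_steps),
    ke_tol_per_node = params$kinetic_tolerance)
  if (!res$converged)
    nm_stop(sprintf(
      "soma relaxation did not converge in %d steps (kinetic energy %.3g)",
      params$max_steps, res$kinetic_energy), "nm_convergence_error",
      residual = res$kinetic_energy)
  out <- sphere
  out$vertices <- res$positions
  out$vertices[pinned, ] <- targets  # pins end exactly on their targets
  list(mesh = out, regions = regions)
}

# map a region's members onto the stem's starting disc: seed -> disc center,
# others -> radius proportional to their geodesic distance, at their original
# azimuth about the stem axis.
annotate_region_targets <- function(sphere, roi, sphere_center, axis,
                                    stem_start, stem_radius, pull_scale) {
  u <- vunit(axis)
  pull <- vnorm(stem_start - sphere_center) * pull_scale
  disc_center <- sphere_center + u * pull
  e1 <- orthogonal_vector(u)
  e2 <- vcross(u, e1)
  members <- roi$members
  targets <- matrix(0, length(members), 3L)
  for (k in seq_along(members)) {
    v <- members[k]
    if (v == roi$seed) {
      targets[k, ] <- disc_center
      next
    }
    rel <- sphere$vertices[v, ] - sphere_center
    phi <- atan2(sum(rel * e2), sum(rel * e1))
    rho <- stem_radius * min(1, roi$geodesic[k] / max(roi$threshold, 1e-12))
    targets[k, ] <- disc_center + rho * (cos(phi) * e1 + sin(phi) * e2)
  }
  roi$targets <- targets
  roi$center <- disc_center
  roi$axis <- u
  roi$radius <- stem_radius
  roi
}

#' Re-arrange a region's contour to the stem diameter
#'
#' After deformation, the frontier vertices of a region of influence are
#' scaled radially about the stem axis so the contour's circumscribed
#' diameter equals the first-order neurite's initial thickness — this is what
#' lets the soma port mate cleanly with the dendrite tube. Interior
#' connectivity is untouched.
#'
#' @param mesh the deformed soma, a [trimesh()].
#' @param region an annotated `region_of_influence` (from [deform_soma()]).
#' @param target_diameter positive scalar, micrometres.
#' @return the adjusted [trimesh()].
#' @export
rearrange_region_contour <- function(mesh, region, target_diameter) {
  if (target_diameter <= 0) nm_arg_error("target_diameter must be positive")
  loop <- region$boundary
  if (length(loop) < 3L)
    nm_geometry_error("region boundary has fewer than 3 vertices")
  u <- region$axis
  p0 <- region$center
  v <- mesh$vertices[loop, , drop = FALSE]
  rel <- sweep(v, 2, p0, "-")
  along <- as.numeric(rel %*% u)
  radial <- rel - outer(along, u)
  rr <- rowwise_norm(radial)
  cur <- max(rr)
  if (cur < 1e-12) nm_geometry_error("region contour collapsed onto its axis")
  scale <- (target_diameter / 2) / cur
  mesh$vertices[loop, ] <- sweep(outer(along, u) + radial * scale, 2, p0, "+")
  mesh
}

#' Fan-tessellate a region of influence into an attachment port
#'
#' Erases every face incident to the region's members, keeps the seed as the
#' single central vertex, and closes the hole with a triangle fan from the
#' seed to the ordered contour. The mesh stays closed and 2-manifold (Euler
#' characteristic 2); the fan is later erased again when the dendrite tube is
#' attached. Unreferenced interior vertices are dropped, so vertex indices
#' are remapped (`attr(, "vertex_map")`).
#'
#' @param mesh the (re-arranged) soma, a [trimesh()].
#' @param region an annotated `region_of_influence`.
#' @param port_name name under which the port is recorded in `mesh$ports`.
#' @return the ported [trimesh()]; `attr(, "vertex_map")` maps old to new
#'   vertex indices (NA for removed vertices).
#' @export
fan_tessellate_region <- function(mesh, region, port_name = "port") {
  members <- region$members
  if (length(members) > n_vertices(mesh) / 2)
    nm_geometry_error("region covers more than half the mesh: non-disc complement")
  inc <- matrix(mesh$faces %in% members, ncol = 3L)
  removed <- rowSums(inc) > 0L
  kept_faces <- mesh$faces[!removed, , drop = FALSE]
  loops <- boundary_loops(trimesh(mesh$vertices, kept_faces))
  loops <- Filter(function(l) !any(l %in% members), loops)
  if (length(loops) != 1L)
    nm_geometry_error("region does not bound a single disc; cannot fan-tessellate")
  loop <- loops[[1L]]
  seed <- region$seed
  # one fan triangle per directed contour edge a->b, wound (seed, b, a)
  nloop <- length(loop)
  nxt <- c(2:nloop, 1L)
  fan <- cbind(rep(seed, nloop), loop[nxt], loop)
  mesh2 <- trimesh(mesh$vertices, rbind(kept_faces, fan), mesh$ports)
  mesh2$ports[[port_name]] <- list(
    center_vertex = seed, loop = loop,
    center = region$center, axis = region$axis, radius = region$radius)
  dropped <- drop_unreferenced(mesh2)
  out <- dropped$mesh
  attr(out, "vertex_map") <- dropped$vmap
  out
}

#' Build a complete ported soma mesh from a morphology
#'
#' Runs the whole soma stage: icosphere around the soma sphere, reduction,
#' mass-spring deformation toward every first-order stem, contour
#' re-arrangement to each stem's diameter, and fan tessellation of each
#' region into a named attachment port.
#'
#' @param m a [neuron_morphology()].
#' @param params a [deform_params()].
#' @return a closed [trimesh()] with one port per stem (named
#'   `stem<k>`).
#' @export
build_soma <- function(m, params = deform_params()) {
  soma <- if (m$soma$variant == "sphere") m$soma else contour_to_sphere(m$soma)
  stems <- first_order_stems(m)
  attempts <- list(c(params$subdivisions, FALSE),
                   c(params$subdivisions + 1L, FALSE),
                   c(params$subdivisions + 1L, TRUE))
  def <- NULL
  for (k in seq_along(attempts)) {
    subdiv <- attempts[[k]][1]
    sphere <- reduce_sphere(make_icosphere(soma$center, soma$radius, subdiv),
                            params$reduction_fraction)
    def <- tryCatch(
      deform_soma(sphere, stems, params,
                  cap_conflicts = as.logical(attempts[[k]][2])),
      nm_region_conflict_error = function(e) e)
    if (!inherits(def, "error")) break
    if (k == length(attempts)) stop(def)
    nm_fallback(sprintf(
      "regions of influence conflict at subdivision %d; retrying %s",
      subdiv, if (as.logical(attempts[[k + 1L]][2]))
        "with geodesic-Voronoi capped thresholds" else "at a finer sphere"))
  }
  mesh <- def$mesh
  regions <- def$regions
  if (length(regions)) for (s in seq_along(regions)) {
    mesh <- rearrange_region_contour(mesh, regions[[s]], 2 * regions[[s]]$radius)
    mesh <- fan_tessellate_region(mesh, regions[[s]], paste0("stem", s))
    vmap <- attr(mesh, "vertex_map")
    if (s < length(regions)) for (t in (s + 1L):length(regions)) {
      regions[[t]]$seed <- vmap[regions[[t]]$seed]
      regions[[t]]$members <- vmap[regions[[t]]$members]
      regions[[t]]$boundary <- vmap[regions[[t]]$boundary]
      keep <- !is.na(regions[[t]]$members)
      regions[[t]]$targets <- regions[[t]]$targets[keep, , drop = FALSE]
      regions[[t]]$geodesic <- regions[[t]]$geodesic[keep]
      regions[[t]]$members <- regions[[t]]$members[keep]
    }
  }
  attr(mesh, "vertex_map") <- NULL
  mesh
}
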