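#' Mass-spring system over a triangle mesh
#'
#' The soma deformation model: one point mass per mesh vertex, one Hooke
#' spring per unique mesh edge (rest length = current edge length), plus one
#' internal anti-collapse spring from every vertex to a fixed virtual node at
#' the mesh center. Pinned nodes are position-constrained (they report zero
#' force and are moved along a prescribed schedule toward their targets).
#'
#' @param mesh a [trimesh()] (the reduced soma sphere).
#' @param stiffness surface spring constant (force per micrometre).
#' @param internal_stiffness constant of the center springs.
#' @param damping viscous coefficient c in the per-node force `-c v`.
#' @param mass uniform node mass.
#' @param dt integration time step.
#' @return an object of class `mass_spring_system`.
#' @export
build_spring_system <- function(mesh, stiffness = 10, internal_stiffness = 1,
                                damping = 0.5, mass = 1, dt = 0.01) {
  for (nm in c("stiffness", "internal_stiffness", "mass", "dt")) {
    val <- get(nm)
    if (!is.numeric(val) || length(val) != 1L || val <= 0)
      nm_arg_error(sprintf("%s must be a positive scalar", nm))
  }
  if (damping < 0) nm_arg_error("damping must be >= 0")
  e <- mesh_edges(mesh)
  len <- rowwise_norm(mesh$vertices[e[, 1], , drop = FALSE] -
                        mesh$vertices[e[, 2], , drop = FALSE])
  if (any(len < 1e-12))
    nm_geometry_error("degenerate zero-length mesh edge; springs need L0 > 0")
  center <- colMeans(mesh$vertices)
  clen <- rowwise_norm(sweep(mesh$vertices, 2, center, "-"))
  if (any(clen < 1e-12))
    nm_geometry_error("a vertex coincides with the mesh center")
  springs <- data.frame(
    i = c(e[, 1], seq_len(n_vertices(mesh))),
    j = c(e[, 2], rep(0L, n_vertices(mesh))),  # j = 0: virtual center node
    L0 = c(len, clen),
    k = c(rep(stiffness, nrow(e)), rep(internal_stiffness, n_vertices(mesh))))
  new_mass_spring_system(mesh$vertices, springs, center,
                         mass = mass, damping = damping, dt = dt)
}

# low-level constructor, also used directly for analytic test systems;
# L0 = 0 is legal here (a spring anchored at a point, F = -k x).
new_mass_spring_system <- function(positions, springs, center = c(0, 0, 0),
                                   mass = 1, damping = 0, dt = 0.01,
                                   velocities = NULL) {
  positions <- as.matrix(positions)
  if (is.null(velocities)) velocities <- matrix(0, nrow(positions), 3L)
  if (any(springs$L0 < 0)) nm_arg_error("spring rest lengths must be >= 0")
  structure(list(
    pos = positions, vel = as.matrix(velocities),
    prev = NULL,                     # lazily initialized by Verlet
    springs = springs, center = as.numeric(center),
    mass = mass, damping = damping, dt = dt,
    pinned = integer(0),
    pin_pos = matrix(0, 0, 3L)       # current constrained positions
  ), class = "mass_spring_system")
}

#' Pin nodes of a mass-spring system
#'
#' Pinned nodes are held at `at` (and later driven by the caller's schedule);
#' they report zero force in [compute_forces()] and are not integrated.
#'
#' @param sys a `mass_spring_system`.
#' @param idx integer node indices.
#' @param at numeric matrix of constrained positions (one row per index).
#' @return the updated system.
#' @export
pin_nodes <- function(sys, idx, at) {
  at <- matrix(as.numeric(at), length(idx), 3L)
  if (any(!is.finite(at))) nm_arg_error("pinned targets must be finite")
  sys$pinned <- as.integer(idx)
  sys$pin_pos <- at
  sys$pos[idx, ] <- at
  sys$vel[idx, ] <- 0
  sys
}

#' Per-node forces of a mass-spring system
#'
#' Hooke's law per spring: magnitude `k (L - L0)` along the spring axis,
#' applied equally and oppositely to both endpoints; viscous damping `-c v`
#' per node. Pinned nodes report zero force (they are position-constrained).
#'
#' @param sys a `mass_spring_system`.
#' @param pos,vel optional state overrides (defaults: current state).
#' @return numeric n x 3 matrix of forces.
#' @export
compute_forces <- function(sys, pos = sys$pos, vel = sys$vel) {
  sp <- sys$springs
  n <- nrow(pos)
  other <- matrix(rep(sys$center, each = nrow(sp)), ncol = 3L)
  has_j <- sp$j > 0L
  other[has_j, ] <- pos[sp$j[has_j], , drop = FALSE]
  d <- pos[sp$i, , drop = FALSE] - other
  len <- rowwise_norm(d)
  safe <- pmax(len, 1e-300)
  fmag <- -sp$k * (len - sp$L0) / safe       # scalar along d, toward rest
  fvec <- d * fmag
  f <- rowsum(rbind(fvec, -fvec[has_j, , drop = FALSE]),
              group = c(sp$i, sp$j[has_j]), reorder = TRUE)
  forces <- matrix(0, n, 3L)
  forces[as.integer(rownames(f)), ] <- f
  forces <- forces - sys$damping * vel
  if (length(sys$pinned)) forces[sys$pinned, ] <- 0
  forces
}

#' Advance a mass-spring system one time step
#'
#' Three explicit schemes sharing one force evaluation: forward `euler`,
#' midpoint `rk2`, and position `verlet` (the default used for soma
#' relaxation, favored for its stability and low amplitude drift).
#' Pinned nodes are held at their constrained positions.
#'
#' @param sys a `mass_spring_system`.
#' @param method `"verlet"`, `"euler"` or `"rk2"`.
#' @return the advanced system.
#' @export
integrate_step <- function(sys, method = c("verlet", "euler", "rk2")) {
  method <- match.arg(method)
  dt <- sys$dt
  if (dt <= 0) nm_arg_error("dt must be positive")
  m <- sys$mass
  free <- setdiff(seq_len(nrow(sys$pos)), sys$pinned)
  if (method == "euler") {
    a <- compute_forces(sys) / m
    pos <- sys$pos
    vel <- sys$vel
    pos[free, ] <- pos[free, ] + vel[free, , drop = FALSE] * dt
    vel[free, ] <- vel[free, ] + a[free, , drop = FALSE] * dt
    sys$pos <- pos; sys$vel <- vel
  } else if (method == "rk2") {
    a1 <- compute_forces(sys) / m
    posm <- sys$pos; velm <- sys$vel
    posm[free, ] <- posm[free, ] + velm[free, , drop = FALSE] * (dt / 2)
    velm[free, ] <- velm[free, ] + a1[free, , drop = FALSE] * (dt / 2)
    a2 <- compute_forces(sys, pos = posm, vel = velm) / m
    pos <- sys$pos; vel <- sys$vel
    pos[free, ] <- pos[free, ] + velm[free, , drop = FALSE] * dt
    vel[free, ] <- vel[free, ] + a2[free, , drop = FALSE] * dt
    sys$pos <- pos; sys$vel <- vel
  } else {
    if (is.null(sys$prev)) {
      a0 <- compute_forces(sys) / m
      sys$prev <- sys$pos - sys$vel * dt + 0.5 * a0 * dt^2
    }
    vest <- (sys$pos - sys$prev) / dt
    a <- compute_forces(sys, vel = vest) / m
    newpos <- 2 * sys$pos - sys$prev + a * dt^2
    newpos[sys$pinned, ] <- sys$pos[sys$pinned, , drop = FALSE]
    sys$vel <- (newpos - sys$prev) / (2 * dt)
    sys$vel[sys$pinned, ] <- 0
    sys$prev <- sys$pos
    sys$pos <- newpos
  }
  if (length(sys$pinned)) sys$pos[sys$pinned, ] <- sys$pin_pos
  if (any(!is.finite(sys$pos)))
    nm_stop("integration diverged (non-finite positions); reduce dt",
            "nm_divergence_error")
  sys
}

#' Total kinetic energy of a system
#' @param sys a `mass_spring_system`.
#' @return scalar `0.5 m sum |v|^2`.
#' @export
kinetic_energy <- function(sys) 0.5 * sys$mass * sum(sys$vel^2)
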