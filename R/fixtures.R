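#' Specification of a synthetic test morphology
#'
#' Parametric random neuron skeletons so every pipeline stage can be driven
#' without any traced dataset. Stems leave the soma along Fibonacci-sphere
#' directions (plus seed-controlled jitter) so their regions of influence
#' rarely overlap at the default sphere subdivisions; radii taper along each
#' branch and children start no thicker than their parent's end.
#'
#' @param seed integer RNG seed; the whole morphology is deterministic in it.
#' @param n_stems number of first-order neurites (0 legal: soma-only).
#' @param max_order maximum branch order (1 = unbranched stems).
#' @param segment_length range (min, max) of inter-point distances, um.
#' @param points_per_branch number of traced points per unbranched chain.
#' @param taper_rate radius loss per micrometre of arc, um/um.
#' @param soma_radius bounding-sphere radius, um.
#' @param bifurcation_angle range (min, max) of half-angles between the two
#'   children at a fork, degrees.
#' @param start_radius stem starting radius, um.
#' @param jitter direction jitter magnitude (0 = exact Fibonacci/star
#'   directions).
#' @param branch_prob probability that a chain below `max_order` bifurcates.
#' @return a list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_stems = 4L, max_order = 2L,
                         segment_length = c(4, 8), points_per_branch = 3L,
                         taper_rate = 0.02, soma_radius = 5,
                         bifurcation_angle = c(30, 70), start_radius = 0.8,
                         jitter = 0.15, branch_prob = 1) {
  if (any(segment_length <= 0) || diff(segment_length) < 0)
    nm_arg_error("segment_length must be a positive ordered range")
  if (any(bifurcation_angle < 0) || diff(bifurcation_angle) < 0)
    nm_arg_error("bifurcation_angle must be an ordered range")
  if (soma_radius <= 0 || start_radius <= 0)
    nm_arg_error("radii must be positive")
  min_terminal <- start_radius -
    taper_rate * segment_length[1] * points_per_branch * max_order
  if (min_terminal <= 0.05)
    nm_stop("infeasible spec: taper exhausts the radius before the minimum segment",
            "nm_spec_error")
  structure(as.list(environment())[
    c("seed", "n_stems", "max_order", "segment_length", "points_per_branch",
      "taper_rate", "soma_radius", "bifurcation_angle", "start_radius",
      "jitter", "branch_prob")], class = "fixture_spec")
}

fibonacci_directions <- function(n) {
  if (n == 0L) return(matrix(0, 0, 3L))
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  golden <- pi * (3 - sqrt(5))
  th <- golden * (seq_len(n) - 1L)
  cbind(r * cos(th), r * sin(th), z)
}

#' Generate a synthetic morphology
#'
#' Random tapering tree per stem, deterministic in the spec's seed. The
#' result always parses back through [parse_swc()] unchanged (round-trip
#' identity on ids, positions, radii and parents).
#'
#' @param spec a [fixture_spec()].
#' @return a [neuron_morphology()]; the SWC text is available via
#'   [write_swc()].
#' @export
generate_morphology <- function(spec = fixture_spec()) {
  if (!inherits(spec, "fixture_spec")) nm_arg_error("spec must be a fixture_spec")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(spec$seed)
  soma <- soma_sphere(center = c(0, 0, 0), radius = spec$soma_radius)
  dirs <- fibonacci_directions(spec$n_stems)
  rows <- list()
  next_id <- 1L
  add_point <- function(type, pos, radius, parent) {
    id <- next_id
    next_id <<- id + 1L
    rows[[length(rows) + 1L]] <<- data.frame(
      id = id, type = type,
      x = round(pos[1], 4), y = round(pos[2], 4), z = round(pos[3], 4),
      radius = round(radius, 4), parent = parent)
    id
  }
  grow_chain <- function(start_pos, dir, radius, parent, order, type) {
    pos <- start_pos
    for (k in seq_len(spec$points_per_branch)) {
      L <- stats::runif(1, spec$segment_length[1], spec$segment_length[2])
      if (spec$jitter > 0) {
        dir <- vunit(dir + stats::rnorm(3, 0, spec$jitter * 0.3))
      }
      pos <- pos + dir * L
      radius <- max(0.08, radius - spec$taper_rate * L)
      parent <- add_point(type, pos, radius, parent)
    }
    if (order < spec$max_order &&
          stats::runif(1) < spec$branch_prob) {
      half <- stats::runif(1, spec$bifurcation_angle[1],
                           spec$bifurcation_angle[2]) * pi / 180 / 2
      perp <- orthogonal_vector(dir)
      child_r <- radius * 0.85
      for (sgn in c(1, -1)) {
        cdir <- vunit(cos(half) * dir + sgn * sin(half) * perp)
        grow_chain(pos, cdir, child_r, parent, order + 1L, type)
      }
    }
  }
  stems <- integer(0)
  if (spec$n_stems > 0L) for (s in seq_len(spec$n_stems)) {
    dir <- dirs[s, ]
    if (spec$jitter > 0) dir <- vunit(dir + stats::rnorm(3, 0, spec$jitter))
    start <- soma$center + dir * spec$soma_radius * 1.15
    type <- if (s == 1L && spec$n_stems > 1L) "axon" else "basal_dendrite"
    id <- add_point(type, start, spec$start_radius, -1L)
    stems <- c(stems, id)
    grow_chain(start, dir, spec$start_radius, id, 1L, type)
  }
  points <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = integer(0), type = character(0), x = numeric(0),
               y = numeric(0), z = numeric(0), radius = numeric(0),
               parent = integer(0))
  neuron_morphology(soma, points, stems)
}

#' Exact star-shaped morphology
#'
#' Deterministic four-stem star along +x, -x, +y, -y: the symmetric fixture
#' used to check stem directions and region placement with no randomness.
#'
#' @param soma_radius,stem_length,radius geometry, micrometres.
#' @param n_points points per stem.
#' @return a [neuron_morphology()].
#' @export
star_morphology <- function(soma_radius = 5, stem_length = 6, radius = 0.8,
                            n_points = 2L) {
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0))
  rows <- list()
  id <- 0L
  stems <- integer(0)
  for (s in 1:4) {
    parent <- -1L
    for (k in seq_len(n_points)) {
      id <- id + 1L
      pos <- dirs[s, ] * (soma_radius * 1.15 + (k - 1L) * stem_length)
      rows[[length(rows) + 1L]] <- data.frame(
        id = id, type = "basal_dendrite", x = pos[1], y = pos[2], z = pos[3],
        radius = radius, parent = parent)
      if (k == 1L) stems <- c(stems, id)
      parent <- id
    }
  }
  neuron_morphology(soma_sphere(c(0, 0, 0), soma_radius),
                    do.call(rbind, rows), stems)
}
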