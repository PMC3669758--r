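#' Neuron morphology: a traced skeleton plus a soma descriptor
#'
#' The data model of a computer-aided tracing: typed 3D points with radii in
#' a parent-pointer forest, plus a soma known either as a sphere (center +
#' radius) or as a closed 2D contour polygon. All units are micrometres.
#'
#' @section Point types:
#' SWC type codes map to `soma` (1), `axon` (2), `basal_dendrite` (3),
#' `apical_dendrite` (4); any other code maps to `other` and is meshed like a
#' dendrite.
#'
#' @param soma a soma descriptor, see [soma_sphere()] / [soma_contour()].
#' @param points data.frame with columns `id`, `type`, `x`, `y`, `z`,
#'   `radius`, `parent` (`parent = -1` for roots; type is one of the codes
#'   above as character).
#' @param stems integer vector of point ids that root first-order neurites.
#' @return an object of class `neuron_morphology`.
#' @export
neuron_morphology <- function(soma, points, stems) {
  points <- as.data.frame(points)
  needed <- c("id", "type", "x", "y", "z", "radius", "parent")
  if (!all(needed %in% names(points)))
    nm_arg_error("points must have columns id, type, x, y, z, radius, parent")
  if (anyDuplicated(points$id))
    nm_structure_error("duplicate point ids in morphology")
  if (any(points$radius < 0)) nm_structure_error("negative radius in morphology")
  known <- points$parent == -1 | points$parent %in% points$id
  if (!all(known))
    nm_structure_error(sprintf("dangling parent id(s): %s",
      paste(unique(points$parent[!known]), collapse = ", ")))
  assert_acyclic(points)
  m <- structure(list(soma = soma, points = points,
                      stems = as.integer(stems)),
                 class = "neuron_morphology")
  m
}

assert_acyclic <- function(points) {
  idx <- match(points$parent, points$id)  # NA for roots
  n <- nrow(points)
  state <- integer(n)  # 0 unseen, 1 in progress, 2 done
  for (s in seq_len(n)) {
    cur <- s
    chain <- integer(0)
    while (!is.na(cur) && state[cur] == 0L) {
      state[cur] <- 1L
      chain <- c(chain, cur)
      cur <- idx[cur]
    }
    if (!is.na(cur) && state[cur] == 1L)
      nm_structure_error("cyclic parent chain in morphology")
    state[chain] <- 2L
  }
  invisible(TRUE)
}

#' @export
print.neuron_morphology <- function(x, ...) {
  cat(sprintf("<neuron_morphology: %d points, %d stems, soma: %s>\n",
              nrow(x$points), length(x$stems), x$soma$variant))
  invisible(x)
}

#' Soma descriptors
#'
#' A soma is known either as a bounding sphere (`soma_sphere`) or as a closed
#' traced contour polygon (`soma_contour`), the two forms tracing software
#' stores.
#'
#' @param center 3-vector, micrometres.
#' @param radius positive scalar, micrometres.
#' @return a list with a `variant` tag.
#' @export
soma_sphere <- function(center, radius) {
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0)
    nm_arg_error("soma radius must be positive")
  list(variant = "sphere", center = as.numeric(center), radius = radius)
}

#' @rdname soma_sphere
#' @param contour n x 3 matrix of ordered polygon vertices (n >= 3).
#' @export
soma_contour <- function(contour) {
  contour <- as.matrix(contour)
  if (nrow(contour) < 3L) nm_arg_error("soma contour needs at least 3 points")
  list(variant = "contour", contour = contour)
}

swc_type_names <- c("1" = "soma", "2" = "axon", "3" = "basal_dendrite",
                    "4" = "apical_dendrite")

swc_type_code <- function(type) {
  code <- match(type, swc_type_names)
  ifelse(is.na(code), 5L, code)
}

#' Parse an SWC skeleton file
#'
#' Standard 7-column whitespace-delimited SWC (`id type x y z radius parent`,
#' `#` comments, parent `-1` for roots). Soma samples (type 1) are collapsed
#' into a sphere descriptor: center = unweighted mean of soma sample
#' positions, radius = mean soma sample radius. Stems are the non-soma points
#' whose parent is a soma point (or -1).
#'
#' @param input path to an SWC file, or a character vector of lines via
#'   `text =`.
#' @param text optional character vector of SWC lines (overrides `input`).
#' @return a [neuron_morphology()].
#' @export
parse_swc <- function(input = NULL, text = NULL) {
  lines <- if (!is.null(text)) text else readLines(input, warn = FALSE)
  raw <- trimws(lines)
  keep <- nzchar(raw) & !startsWith(raw, "#")
  rows <- which(keep)
  if (length(rows) == 0L) nm_parse_error("SWC input has no sample rows")
  fields <- strsplit(raw[rows], "\\s+")
  bad_n <- lengths(fields) != 7L
  if (any(bad_n))
    nm_parse_error(sprintf("line %d: expected 7 columns, found %d",
                           rows[which(bad_n)[1]], lengths(fields)[which(bad_n)[1]]),
                   line = rows[which(bad_n)[1]])
  num <- suppressWarnings(
    matrix(as.numeric(unlist(fields)), ncol = 7L, byrow = TRUE))
  if (anyNA(num)) {
    bad <- which(rowSums(is.na(num)) > 0L)[1]
    nm_parse_error(sprintf("line %d: non-numeric field", rows[bad]),
                   line = rows[bad])
  }
  df <- data.frame(id = as.integer(num[, 1]),
                   type_code = as.integer(num[, 2]),
                   x = num[, 3], y = num[, 4], z = num[, 5],
                   radius = num[, 6],
                   parent = as.integer(num[, 7]))
  soma_rows <- df$type_code == 1L
  if (!any(soma_rows))
    nm_structure_error("SWC input has no soma sample (type 1)")
  soma <- soma_sphere(center = colMeans(df[soma_rows, c("x", "y", "z")]),
                      radius = mean(df$radius[soma_rows]))
  soma_ids <- df$id[soma_rows]
  rest <- df[!soma_rows, , drop = FALSE]
  type <- unname(swc_type_names[as.character(rest$type_code)])
  type[is.na(type)] <- "other"
  points <- data.frame(id = rest$id, type = type,
                       x = rest$x, y = rest$y, z = rest$z,
                       radius = rest$radius, parent = rest$parent)
  # re-root points hanging off soma samples
  dangling <- !(points$parent %in% c(-1L, points$id, soma_ids))
  if (any(dangling))
    nm_structure_error(sprintf("dangling parent id(s): %s",
      paste(unique(points$parent[dangling]), collapse = ", ")))
  stems <- points$id[points$parent %in% c(soma_ids, -1L)]
  points$parent[points$parent %in% soma_ids] <- -1L
  neuron_morphology(soma, points, stems)
}

#' Serialize a morphology to SWC text
#'
#' The soma sphere becomes a single type-1 sample with id 1; skeleton points
#' are renumbered consecutively after it, stems parented to the soma sample.
#'
#' @param m a [neuron_morphology()].
#' @param path optional file path; when omitted the lines are returned.
#' @return character vector of SWC lines (invisibly when written to `path`).
#' @export
write_swc <- function(m, path = NULL) {
  soma <- if (m$soma$variant == "sphere") m$soma else contour_to_sphere(m$soma)
  p <- m$points
  newid <- seq_len(nrow(p)) + 1L
  remap <- stats::setNames(newid, p$id)
  parent <- ifelse(p$parent == -1L, 1L, remap[as.character(p$parent)])
  codes <- swc_type_code(p$type)
  lines <- c(
    "# SWC written by neuromesh",
    sprintf("1 1 %.9g %.9g %.9g %.9g -1",
            soma$center[1], soma$center[2], soma$center[3], soma$radius),
    sprintf("%d %d %.9g %.9g %.9g %.9g %d",
            newid, codes, p$x, p$y, p$z, p$radius, as.integer(parent)))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Convert a traced soma contour to a bounding sphere
#'
#' Center = centroid of the contour vertices; radius = area-equivalent radius
#' `sqrt(A / pi)` of the polygon projected onto its best-fit plane, so
#' elongated contours do not inflate the sphere.
#'
#' @param soma a contour-variant soma descriptor.
#' @return a sphere-variant soma descriptor.
#' @export
contour_to_sphere <- function(soma) {
  if (is.null(soma$variant) || soma$variant != "contour")
    nm_arg_error("contour_to_sphere expects a contour-variant soma")
  pts <- soma$contour
  if (nrow(pts) < 3L) nm_geometry_error("degenerate contour (< 3 points)")
  ctr <- colMeans(pts)
  cen <- sweep(pts, 2, ctr, "-")
  sv <- svd(cen)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1e-12))
    nm_geometry_error("degenerate (collinear) contour")
  uv <- cen %*% sv$v[, 1:2]  # projection onto best-fit plane
  n <- nrow(uv)
  nxt <- c(2:n, 1L)
  area <- abs(sum(uv[, 1] * uv[nxt, 2] - uv[nxt, 1] * uv[, 2]) / 2)
  if (area < 1e-12) nm_geometry_error("degenerate contour: zero area")
  soma_sphere(center = ctr, radius = sqrt(area / pi))
}

#' Initial segments of the first-order neurites
#'
#' One record per stem: start position and radius of the stem's first traced
#' point, and the unit direction from the soma center to it. This is all the
#' soma deformation stage needs.
#'
#' @param m a [neuron_morphology()].
#' @return data.frame with columns `id`, `type`, `x`, `y`, `z`, `radius`,
#'   `dx`, `dy`, `dz` (one row per stem; zero rows for a soma-only neuron).
#' @export
first_order_stems <- function(m) {
  soma <- if (m$soma$variant == "sphere") m$soma else contour_to_sphere(m$soma)
  if (length(m$stems) == 0L) {
    return(data.frame(id = integer(0), type = character(0),
                      x = numeric(0), y = numeric(0), z = numeric(0),
                      radius = numeric(0),
                      dx = numeric(0), dy = numeric(0), dz = numeric(0)))
  }
  rows <- m$points[match(m$stems, m$points$id), , drop = FALSE]
  dirs <- t(apply(rows[, c("x", "y", "z")], 1, function(p) {
    d <- as.numeric(p) - soma$center
    if (vnorm(d) < 1e-9)
      nm_geometry_error("stem start coincides with the soma center")
    vunit(d)
  }))
  data.frame(id = rows$id, type = rows$type,
             x = rows$x, y = rows$y, z = rows$z, radius = rows$radius,
             dx = dirs[, 1], dy = dirs[, 2], dz = dirs[, 3])
}
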