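#' Parse a simplified Neurolucida ASC file
#'
#' Supported dialect (geometry tokens only):
#' * a CellBody block `("CellBody" (x y z d) (x y z d) ...)` giving the
#'   ordered 2D soma contour (stored in 3D; a non-coplanar contour is
#'   accepted with a logged warning);
#' * one parenthesized tree per neurite: nested lists of `(x y z d)` points,
#'   with `|` separating sibling branches at a bifurcation, optionally tagged
#'   `"Axon"`, `"Dendrite"` or `"Apical"`.
#'
#' Neurolucida thickness values are diameters, so `d` is halved into a
#' radius. Markers, spines-in-file, colors and the binary DAT format are out
#' of scope.
#'
#' @param input path to an ASC file.
#' @param text optional character vector of lines (overrides `input`).
#' @return a [neuron_morphology()] with a contour-variant soma.
#' @export
parse_asc <- function(input = NULL, text = NULL) {
  lines <- if (!is.null(text)) text else readLines(input, warn = FALSE)
  src <- paste(lines, collapse = "\n")
  src <- gsub(";[^\n]*", "", src)  # comments
  toks <- asc_tokenize(src)
  forest <- asc_parse_sexprs(toks)
  cellbody <- NULL
  trees <- list()
  for (node in forest) {
    tag <- asc_block_tag(node)
    if (identical(tag, "CellBody")) cellbody <- node
    else trees[[length(trees) + 1L]] <- node
  }
  if (is.null(cellbody))
    nm_structure_error("ASC input has no CellBody block")
  contour <- do.call(rbind, lapply(Filter(is.list, cellbody),
                                   asc_point_coords))
  if (is.null(contour) || nrow(contour) < 3L)
    nm_structure_error("CellBody contour needs at least 3 points")
  check_contour_planarity(contour[, 1:3, drop = FALSE])
  soma <- soma_contour(contour[, 1:3, drop = FALSE])

  pts <- new.env(parent = emptyenv())
  pts$rows <- list()
  pts$next_id <- 1L
  stems <- integer(0)
  for (tree in trees) {
    type <- switch(tolower(asc_block_tag(tree) %||% "dendrite"),
                   axon = "axon", apical = "apical_dendrite",
                   dendrite = "basal_dendrite", "basal_dendrite")
    first_id <- asc_emit_branch(tree, parent = -1L, type = type, pts = pts)
    if (!is.na(first_id)) stems <- c(stems, first_id)
  }
  points <- if (length(pts$rows)) do.call(rbind, pts$rows) else
    data.frame(id = integer(0), type = character(0), x = numeric(0),
               y = numeric(0), z = numeric(0), radius = numeric(0),
               parent = integer(0))
  neuron_morphology(soma, points, stems)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_contour_planarity <- function(pts, tol = 1e-6) {
  cen <- sweep(pts, 2, colMeans(pts), "-")
  sv <- svd(cen)
  if (sv$d[3] > tol * max(sv$d[1], 1e-12))
    nm_warn("soma contour points are not coplanar within tolerance; using them as stored",
            class = "nm_nonplanar_contour")
  invisible(NULL)
}

asc_tokenize <- function(src) {
  pat <- "\\(|\\)|\\||\"[^\"]*\"|[-+0-9.eE]+|[A-Za-z_]+"
  m <- gregexpr(pat, src)[[1]]
  if (m[1] == -1L) nm_parse_error("ASC input has no tokens")
  regmatches(src, gregexpr(pat, src))[[1]]
}

# recursive-descent parse into nested lists; atoms are strings/numbers
asc_parse_sexprs <- function(toks) {
  pos <- 1L
  n <- length(toks)
  parse_one <- function() {
    tk <- toks[pos]
    if (tk == "(") {
      pos <<- pos + 1L
      items <- list()
      repeat {
        if (pos > n) nm_parse_error("unbalanced parentheses in ASC input")
        if (toks[pos] == ")") {
          pos <<- pos + 1L
          return(items)
        }
        items[[length(items) + 1L]] <- parse_one()
      }
    } else if (tk == ")") {
      nm_parse_error("unbalanced parentheses in ASC input")
    } else {
      pos <<- pos + 1L
      num <- suppressWarnings(as.numeric(tk))
      if (!is.na(num)) return(num)
      gsub("\"", "", tk)
    }
  }
  out <- list()
  while (pos <= n) out[[length(out) + 1L]] <- parse_one()
  out
}

asc_block_tag <- function(node) {
  if (is.list(node) && length(node) > 0L && is.character(node[[1]]))
    node[[1]] else NULL
}

asc_is_point <- function(node) {
  is.list(node) && length(node) >= 4L &&
    all(vapply(node[1:4], is.numeric, logical(1)))
}

asc_point_coords <- function(node) {
  if (!asc_is_point(node)) return(NULL)
  matrix(unlist(node[1:4]), 1L, 4L)
}

# emit one branch: leading run of points, then either nothing (terminal) or
# one nested list containing sibling branches separated by "|"
asc_emit_branch <- function(node, parent, type, pts) {
  first_id <- NA_integer_
  i <- 1L
  items <- Filter(function(x) !is.character(x), node)
  while (i <= length(items) && asc_is_point(items[[i]])) {
    p <- asc_point_coords(items[[i]])
    id <- pts$next_id
    pts$next_id <- id + 1L
    pts$rows[[length(pts$rows) + 1L]] <- data.frame(
      id = id, type = type, x = p[1], y = p[2], z = p[3],
      radius = p[4] / 2, parent = parent)
    if (is.na(first_id)) first_id <- id
    parent <- id
    i <- i + 1L
  }
  if (i <= length(items)) {
    sub <- items[[i]]
    if (!is.list(sub))
      nm_parse_error("unexpected token inside branch")
    # split children on "|"
    kids <- list(list())
    for (el in sub) {
      if (is.character(el) && el == "|") kids[[length(kids) + 1L]] <- list()
      else kids[[length(kids)]][[length(kids[[length(kids)]]) + 1L]] <- el
    }
    for (kid in kids) asc_emit_branch(kid, parent, type, pts)
  }
  first_id
}
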