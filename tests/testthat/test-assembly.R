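test_that("linking collinear tubes adds exactly a 2p band", {
  p <- 8L
  a <- build_truncated_cone(c(0, 0, 0), c(0, 0, 5), 1, 1,
                            resolution_params(2, p))
  b <- build_truncated_cone(c(0, 0, 5.6), c(0, 0, 11), 1, 1,
                            resolution_params(2, p))
  linked <- link_consecutive(a, b)
  expect_equal(nrow(linked$faces), nrow(a$faces) + nrow(b$faces) + 2L * p)
  r <- validate_mesh(linked)
  expect_equal(r$nonmanifold_edges, 0L)
  expect_equal(r$boundary_edges, 2L * p)  # the two remaining open ends
  # straight case: no shortening, ring positions untouched
  expect_equal(linked$vertices[1:(nrow(a$vertices)), ], a$vertices,
               ignore_attr = TRUE)
})

test_that("a sharp bend triggers shortening and stays intersection-free", {
  p <- 8L
  joint <- c(0, 0, 3)
  dir2 <- c(sin(pi / 3), 0, cos(pi / 3))
  a <- build_truncated_cone(c(0, 0, 0), joint, 1, 1, resolution_params(1, p))
  b <- build_truncated_cone(joint + 0.4 * dir2, joint + 3.4 * dir2, 1, 1,
                            resolution_params(1, p))
  linked <- link_consecutive(a, b)
  # shortening moved the end ring of a back along its axis
  endring <- linked$vertices[a$ports$end$loop, , drop = FALSE]
  expect_lt(max(endring[, 3]), 3)
  expect_equal(count_local_intersections(linked, joint, 2.5), 0L)
  expect_equal(validate_mesh(linked)$nonmanifold_edges, 0L)
})

test_that("mismatched ring sizes are rejected", {
  a <- build_truncated_cone(c(0, 0, 0), c(0, 0, 5), 1, 1,
                            resolution_params(1, 8))
  b <- build_truncated_cone(c(0, 0, 6), c(0, 0, 10), 1, 1,
                            resolution_params(1, 6))
  expect_error(link_consecutive(a, b), class = "nm_argument_error")
})

test_that("bifurcation hole-and-sew obeys Euler bookkeeping", {
  p <- 6L
  trunk <- build_truncated_cone(c(0, 0, 0), c(0, 0, 10), 1, 1,
                                resolution_params(6, p))
  dir2 <- c(1, 0, 0.4) / sqrt(1.16)
  start <- c(1.4, 0, 5)
  child2 <- build_truncated_cone(start, start + 5 * dir2, 0.5, 0.4,
                                 resolution_params(2, p))
  # anchor = nearest trunk vertex; record its valence first
  d2 <- rowSums(sweep(trunk$vertices, 2,
                      trunk$ports$start$center + c(0, 0, 0), "-")^2)
  d2 <- rowSums(sweep(trunk$vertices, 2, start, "-")^2)
  anchor <- which.min(d2)
  d <- sum(rowSums(matrix(trunk$faces == anchor, ncol = 3)) > 0)
  sewn <- connect_bifurcation(trunk, child2)
  # V loses the anchor, F loses d faces and gains d + p band triangles
  expect_equal(nrow(sewn$vertices),
               nrow(trunk$vertices) + nrow(child2$vertices) - 1L)
  expect_equal(nrow(sewn$faces),
               nrow(trunk$faces) + nrow(child2$faces) + p)
  r <- validate_mesh(sewn)
  expect_equal(r$nonmanifold_edges, 0L)
  # open boundaries left: trunk start + trunk end + child2 end
  expect_equal(r$boundary_edges, 3L * p)
})

test_that("bifurcation anchor ties break to the lowest vertex index", {
  p <- 6L
  trunk <- build_truncated_cone(c(0, 0, 0), c(0, 0, 10), 1, 1,
                                resolution_params(6, p))
  # force an exact tie: mirror vertex 16 across the y = 0 plane of vertex 15
  # and probe from that plane, so both squared distances are bit-identical
  v15 <- trunk$vertices[15, ]
  trunk$vertices[16, ] <- c(v15[1], -v15[2], v15[3])
  probe <- c(v15[1] * 2, 0, v15[3])
  d2 <- rowSums(sweep(trunk$vertices, 2, probe, "-")^2)
  expect_identical(d2[15], d2[16])
  anchor <- which.min(d2)
  expect_equal(anchor, 15L)  # lowest index wins the tie
  outward <- c(sign(v15[1]) * 4, 0, 0)
  child2 <- build_truncated_cone(probe, probe + outward, 0.4, 0.4,
                                 resolution_params(0, p))
  sewn <- connect_bifurcation(trunk, child2, probe)
  # vertex 15 (not 16) was consumed as the anchor
  match15 <- apply(sewn$vertices, 1, function(v) all(v == v15))
  expect_false(any(match15))
})

test_that("attaching a tube to a soma port consumes both boundary loops", {
  m <- star_morphology()
  soma <- build_soma(m)
  port <- soma$ports$stem1
  res <- resolution_params(2, 6)
  strips <- neuromesh:::build_chain_strips(m, m$stems[1], res)
  tube <- strips[[1]]$mesh
  d <- length(port$loop)
  pp <- length(tube$ports$start$loop)
  joined <- attach_to_soma(soma, tube, "stem1")
  # fan erased (d faces), band adds d + p
  expect_equal(nrow(joined$faces),
               nrow(soma$faces) - d + nrow(tube$faces) + d + pp)
  r <- validate_mesh(joined)
  expect_equal(r$nonmanifold_edges, 0L)
  expect_equal(r$boundary_edges, 0L)  # terminal strip is capped: fully closed
  expect_equal(r$euler_characteristic, 2L)
  # deliberately mismatched diameters are refused
  fat <- tube
  fat$ports$start$radius <- tube$ports$start$radius * 3
  expect_error(attach_to_soma(soma, fat, "stem2"),
               class = "nm_geometry_error")
})

test_that("assembled neurons are watertight with exact band accounting", {
  for (sd in c(3L, 12L)) {
    m <- generate_morphology(fixture_spec(seed = sd))
    mesh <- assemble_neuron(m, res = resolution_params(3, 6))
    r <- validate_mesh(mesh)
    expect_true(r$closed)
    expect_equal(r$euler_characteristic, 2L)
    expect_equal(r$components, 1L)
    expect_gt(r$volume, 0)
  }
})

test_that("joint neighbourhoods are intersection-free at default resolution", {
  for (sd in c(5L, 18L)) {
    m <- generate_morphology(fixture_spec(seed = sd))
    mesh <- assemble_neuron(m, res = resolution_params(4, 6))
    pts <- m$points
    forks <- pts$id[pts$id %in% pts$parent[duplicated(pts$parent)]]
    for (fid in forks) {
      at <- as.numeric(pts[match(fid, pts$id), c("x", "y", "z")])
      r_local <- pts$radius[match(fid, pts$id)]
      expect_equal(count_local_intersections(mesh, at, 2 * r_local), 0L)
    }
  }
})

test_that("assembly smoothing protects junction rings and keeps topology", {
  m <- generate_morphology(fixture_spec(seed = 8L))
  raw <- assemble_neuron(m, res = resolution_params(2, 6))
  sm <- assemble_neuron(m, res = resolution_params(2, 6),
                        smooth_iterations = 2L)
  expect_identical(dim(sm$faces), dim(raw$faces))
  expect_identical(sm$faces, raw$faces)
  jv <- attr(raw, "junction_vertices")
  expect_equal(sm$vertices[jv, ], raw$vertices[jv, ])
  expect_true(validate_mesh(sm)$closed)
})
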