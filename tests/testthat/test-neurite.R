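test_that("radius interpolation is linear with exact endpoints", {
  expect_equal(interpolate_radius(0, 1.2, 3.4), 1.2)
  expect_equal(interpolate_radius(1, 1.2, 3.4), 3.4)
  expect_equal(interpolate_radius(0.5, 1, 3), 2)
  grid <- seq(0, 1, by = 0.05)
  vals <- interpolate_radius(grid, 0.4, 2.2)
  expect_true(all(diff(vals) >= 0))
  expect_error(interpolate_radius(1.2, 1, 2), class = "nm_argument_error")
})

test_that("truncated cone counts follow the ring formulas", {
  # the reference illustration: 6 intermediate sections, 8 points per ring
  tc <- build_truncated_cone(c(0, 0, 0), c(0, 0, 10), 1, 2,
                             resolution_params(6, 8))
  expect_equal(nrow(tc$vertices), 64L)        # (6 + 2) rings x 8
  expect_equal(nrow(tc$faces), 112L)          # 2 * 8 * (8 - 1)
  # minimal legal tube
  tmin <- build_truncated_cone(c(0, 0, 0), c(1, 1, 1), 0.5, 0.5,
                               resolution_params(0, 3))
  expect_equal(nrow(tmin$vertices), 6L)
  expect_equal(nrow(tmin$faces), 6L)
  for (res in list(c(0, 3), c(2, 3), c(4, 6), c(8, 12))) {
    tc <- build_truncated_cone(c(0, 0, 0), c(3, -2, 7), 0.7, 1.1,
                               resolution_params(res[1], res[2]))
    R <- res[1] + 2L
    expect_equal(nrow(tc$vertices), R * res[2])
    expect_equal(nrow(tc$faces), 2L * res[2] * (R - 1L))
  }
  expect_error(build_truncated_cone(c(0, 0, 0), c(0, 0, 0), 1, 1),
               class = "nm_geometry_error")
  expect_error(build_truncated_cone(c(0, 0, 0), c(0, 0, 1), 0, 1),
               class = "nm_argument_error")
})

test_that("equal base radii give a true cylinder", {
  tc <- build_truncated_cone(c(0, 0, 0), c(0, 0, 8), 1.5, 1.5,
                             resolution_params(4, 10))
  rad <- sqrt(tc$vertices[, 1]^2 + tc$vertices[, 2]^2)
  expect_equal(rad, rep(1.5, nrow(tc$vertices)), tolerance = 1e-12)
})

test_that("cross-section placement respects end gaps and logs short segments", {
  path <- data.frame(x = c(0, 10, 20), y = 0, z = 0, radius = 1)
  pl <- place_cross_sections(path, resolution_params(3, 6))
  # straight path: all ring normals parallel
  expect_true(all(abs(pl$nx - 1) < 1e-12))
  # intermediates keep max(radius, 0.1 L) away from segment ends
  inter <- pl[!pl$at_point, ]
  expect_true(all(abs(inter$x - round(inter$x / 10) * 10) >= 1 - 1e-9))
  short <- data.frame(x = c(0, 0.1), y = 0, z = 0, radius = 1)
  expect_message(
    pl2 <- place_cross_sections(short, resolution_params(4, 6)),
    class = "nm_fallback")
  expect_equal(nrow(pl2), 2L)  # bases only
})

test_that("rings at a right-angle joint tilt to the bisector and do not cross", {
  path <- data.frame(x = c(0, 6, 6), y = c(0, 0, 6), z = 0, radius = 1)
  pl <- place_cross_sections(path, resolution_params(2, 8))
  joint <- pl[pl$at_point & pl$x == 6 & pl$y == 0, ]
  expect_equal(as.numeric(joint[1, c("nx", "ny", "nz")]),
               c(1, 1, 0) / sqrt(2), tolerance = 1e-9)
  mesh <- neuromesh:::sweep_ring_stack(pl, 8L)
  expect_equal(count_local_intersections(mesh, c(6, 0, 0), 3), 0L)
})

test_that("branch meshes keep stored radii exactly at morphological points", {
  for (sd in c(2L, 6L)) {
    m <- generate_morphology(fixture_spec(seed = sd))
    res <- resolution_params(3, 7)
    for (s in seq_along(m$stems)) {
      strips <- neuromesh:::build_chain_strips(m, m$stems[s], res)
      for (st in strips) {
        pl <- st$placements
        at <- which(pl$at_point)
        for (i in at) {
          ctr <- as.numeric(pl[i, c("x", "y", "z")])
          ring <- st$mesh$vertices[(i - 1L) * 7L + 1:7, , drop = FALSE]
          circum <- sqrt(rowSums(sweep(ring, 2, ctr, "-")^2))
          expect_true(all(abs(circum - pl$radius[i]) < 1e-9))
          pr <- pl$point_row[i]
          row <- m$points[st$chain$rows[pr], ]
          expect_equal(pl$radius[i], row$radius, tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("parallel transport keeps ring twist below one sector", {
  m <- generate_morphology(fixture_spec(seed = 4L))
  res <- resolution_params(4, 8)
  p <- res$points_per_section
  strips <- neuromesh:::build_chain_strips(m, m$stems[1], res)
  for (st in strips) {
    pl <- st$placements
    for (i in seq_len(nrow(pl) - 1L)) {
      n1 <- as.numeric(pl[i, c("nx", "ny", "nz")])
      r1 <- as.numeric(pl[i, c("rx", "ry", "rz")])
      n2 <- as.numeric(pl[i + 1L, c("nx", "ny", "nz")])
      r2 <- as.numeric(pl[i + 1L, c("rx", "ry", "rz")])
      # transport r1 into ring i+1's plane and compare angles
      tr <- neuromesh:::rotate_between(r1, n1, n2)
      ang <- acos(max(-1, min(1, sum(tr * r2))))
      expect_lt(ang, 2 * pi / p)
    }
  }
})

test_that("branch structure: a Y stem yields three strips, tips get caps", {
  pts <- data.frame(
    id = 1:4, type = "basal_dendrite",
    x = c(6, 12, 18, 18), y = c(0, 0, 5, -5), z = 0,
    radius = c(1, 0.9, 0.7, 0.7), parent = c(-1L, 1L, 2L, 2L))
  m <- neuron_morphology(soma_sphere(c(0, 0, 0), 4), pts, stems = 1L)
  strips <- neuromesh:::build_chain_strips(m, 1L, resolution_params(1, 6))
  expect_length(strips, 3L)
  expect_false(strips[[1]]$terminal)
  expect_true(strips[[2]]$terminal && strips[[3]]$terminal)
  # terminal strips are capped: only one boundary loop (the start ring)
  loops <- neuromesh:::boundary_loops(strips[[2]]$mesh)
  expect_length(loops, 1L)
})

test_that("zero radii are clamped with a logged fallback", {
  pts <- data.frame(id = 1:3, type = "basal_dendrite",
                    x = c(6, 12, 18), y = 0, z = 0,
                    radius = c(0.5, 0, 0.4), parent = c(-1L, 1L, 2L))
  m <- neuron_morphology(soma_sphere(c(0, 0, 0), 4), pts, stems = 1L)
  expect_message(
    strips <- neuromesh:::build_chain_strips(m, 1L, resolution_params(0, 6)),
    class = "nm_fallback")
  expect_gte(min(strips[[1]]$placements$radius), 0.05)
})

test_that("total triangles increase strictly across the resolution ladder", {
  m <- generate_morphology(fixture_spec(seed = 11L))
  counts <- sapply(list(c(2, 3), c(4, 6), c(8, 12)), function(rs) {
    nrow(assemble_neuron(m, res = resolution_params(rs[1], rs[2]))$faces)
  })
  expect_true(all(diff(counts) > 0))
})
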