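reduced_test_sphere <- function(radius = 5, subdiv = 3L, fraction = 0.5) {
  reduce_sphere(make_icosphere(c(0, 0, 0), radius, subdiv), fraction)
}

test_that("deform_soma with no stems is an exact fixed point", {
  sphere <- reduced_test_sphere()
  out <- deform_soma(sphere, first_order_stems(
    generate_morphology(fixture_spec(seed = 1, n_stems = 0L))))
  expect_lt(max(abs(out$mesh$vertices - sphere$vertices)), 1e-6)
  expect_identical(out$mesh$faces, sphere$faces)
})

test_that("deformation pins land on targets and the soma does not collapse", {
  m <- star_morphology()
  sphere <- reduced_test_sphere()
  vol0 <- measure_volume(sphere)
  out <- deform_soma(sphere, first_order_stems(m))
  soma_r <- 5
  for (roi in out$regions) {
    err <- sqrt(rowSums((out$mesh$vertices[roi$members, , drop = FALSE] -
                           roi$targets)^2))
    expect_lt(max(err) / soma_r, 0.01)
  }
  expect_identical(out$mesh$faces, sphere$faces)  # topology preserved
  expect_gte(measure_volume(out$mesh), 0.95 * vol0)
})

test_that("larger pull distances displace the surface further", {
  m <- star_morphology()
  sphere <- reduced_test_sphere()
  ctr <- colMeans(sphere$vertices)
  disp <- sapply(c(1.5, 2.5) / 5.75, function(scale) {
    # scale chosen so the pulled disc sits 1.5 vs 2.5 um from the center
    out <- deform_soma(sphere, first_order_stems(m),
                       deform_params(pull_distance_scale = scale))
    max(sqrt(rowSums(sweep(out$mesh$vertices, 2, ctr, "-")^2)))
  })
  expect_gt(disp[2], disp[1])
})

test_that("overlapping regions of two close stems raise a region conflict", {
  pts <- data.frame(id = 1:2, type = "basal_dendrite",
                    x = c(5.75, 5.7), y = c(0, 0.45), z = 0,
                    radius = 0.8, parent = -1L)
  m <- neuron_morphology(soma_sphere(c(0, 0, 0), 5), pts, stems = 1:2)
  expect_error(
    deform_soma(reduced_test_sphere(), first_order_stems(m)),
    class = "nm_region_conflict_error")
})

test_that("rearrange_region_contour scales the contour to the target diameter", {
  m <- star_morphology()
  sphere <- reduced_test_sphere()
  out <- deform_soma(sphere, first_order_stems(m))
  roi <- out$regions[[1]]
  target <- 2 * roi$radius
  mesh2 <- rearrange_region_contour(out$mesh, roi, target)
  # circumscribed diameter about the stem axis equals the target
  rel <- sweep(mesh2$vertices[roi$boundary, , drop = FALSE], 2, roi$center, "-")
  along <- as.numeric(rel %*% roi$axis)
  radial <- sqrt(rowSums((rel - outer(along, roi$axis))^2))
  expect_equal(2 * max(radial), target, tolerance = 0.005)
  # radial distances scale uniformly: halving the target halves every radius
  mesh3 <- rearrange_region_contour(out$mesh, roi, target / 2)
  rel3 <- sweep(mesh3$vertices[roi$boundary, , drop = FALSE], 2, roi$center, "-")
  radial3 <- sqrt(rowSums((rel3 - outer(as.numeric(rel3 %*% roi$axis),
                                        roi$axis))^2))
  expect_equal(radial3, radial / 2, tolerance = 1e-9)
  # already at target: no movement
  mesh4 <- rearrange_region_contour(mesh2, roi, target)
  expect_equal(mesh4$vertices, mesh2$vertices, tolerance = 1e-9)
  bad <- roi
  bad$boundary <- roi$boundary[1:2]
  expect_error(rearrange_region_contour(out$mesh, bad, target),
               class = "nm_geometry_error")
})

test_that("fan tessellation keeps the soma closed with chi = 2", {
  m <- star_morphology()
  soma <- build_soma(m)
  r <- validate_mesh(soma)
  expect_true(r$closed)
  expect_equal(r$euler_characteristic, 2L)
  expect_equal(r$components, 1L)
  expect_length(soma$ports, 4L)
  # each port is a genuine fan: center vertex valence equals contour length
  for (p in soma$ports) {
    star <- sum(rowSums(matrix(soma$faces == p$center_vertex, ncol = 3)) > 0)
    expect_equal(star, length(p$loop))
  }
})

test_that("a seed-only region fans into exactly |boundary| triangles", {
  sphere <- reduced_test_sphere(subdiv = 2L)
  roi <- compute_region_of_influence(sphere, c(4, 0, 0), 0)
  roi$center <- sphere$vertices[roi$seed, ]
  roi$axis <- c(1, 0, 0)
  roi$radius <- 0.5
  nf0 <- nrow(sphere$faces)
  valence <- sum(rowSums(matrix(sphere$faces == roi$seed, ncol = 3)) > 0)
  out <- fan_tessellate_region(sphere, roi)
  p <- out$ports$port
  expect_equal(length(p$loop), valence)
  expect_equal(nrow(out$faces), nf0)  # d faces removed, d fan faces added
  expect_true(validate_mesh(out)$closed)
})

test_that("a region spanning more than half the sphere is rejected", {
  sphere <- reduced_test_sphere(subdiv = 1L)
  roi <- compute_region_of_influence(sphere, c(4, 0, 0), 0)
  roi$members <- seq_len(nrow(sphere$vertices) %/% 2 + 2L)
  expect_error(fan_tessellate_region(sphere, roi),
               class = "nm_geometry_error")
})
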