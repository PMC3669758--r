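test_that("parse_swc maps a toy file onto the data model", {
  txt <- c("# toy",
           "1 1 0 0 0 5 -1",
           "2 3 7 0 0 1 1",
           "3 3 14 0 0 0.8 2")
  m <- parse_swc(text = txt)
  expect_s3_class(m, "neuron_morphology")
  expect_equal(length(m$stems), 1L)
  expect_equal(m$soma$variant, "sphere")
  expect_equal(m$soma$radius, 5)
  expect_equal(nrow(m$points), 2L)
  expect_equal(m$points$type, c("basal_dendrite", "basal_dendrite"))
})

test_that("parse_swc collapses multiple soma samples to mean center/radius", {
  txt <- c("1 1 0 0 0 5 -1",
           "2 1 2 0 0 5 1",
           "3 1 4 0 0 5 2",
           "4 3 8 0 0 1 1")
  m <- parse_swc(text = txt)
  expect_equal(m$soma$center, c(2, 0, 0))
  expect_equal(m$soma$radius, 5)
})

test_that("parse_swc rejects malformed and inconsistent input", {
  expect_error(parse_swc(text = c("1 1 0 0 0 5 -1", "2 3 1 2 3 1")),
               class = "nm_parse_error")
  expect_error(parse_swc(text = c("1 1 0 0 0 5 -1", "2 3 a 0 0 1 1")),
               class = "nm_parse_error")
  err <- expect_error(
    parse_swc(text = c("1 1 0 0 0 5 -1", "5 3 0 0 0 1.0 99")),
    class = "nm_structure_error")
  expect_match(conditionMessage(err), "99")
  # cyclic parent chain
  expect_error(
    neuron_morphology(soma_sphere(c(0, 0, 0), 5),
                      data.frame(id = 1:2, type = "basal_dendrite",
                                 x = 0, y = 0, z = 0, radius = 1,
                                 parent = c(2L, 1L)), stems = integer(0)),
    class = "nm_structure_error")
  # unknown type codes map to "other"
  m <- parse_swc(text = c("1 1 0 0 0 5 -1", "2 7 8 0 0 1 1"))
  expect_equal(m$points$type, "other")
})

test_that("SWC round-trips identically through write_swc/parse_swc", {
  for (sd in c(1L, 5L, 9L)) {
    m0 <- generate_morphology(fixture_spec(seed = sd))
    txt <- write_swc(m0)
    m1 <- parse_swc(text = txt)
    m2 <- parse_swc(text = write_swc(m1))
    expect_identical(m1$points, m2$points)
    expect_identical(m1$stems, m2$stems)
    expect_identical(m1$soma, m2$soma)
    expect_identical(write_swc(m1), write_swc(m2))
  }
})

test_that("stem count equals parent links into the soma", {
  for (sd in 1:5) {
    m <- generate_morphology(fixture_spec(seed = sd, n_stems = sd %% 4 + 1L))
    expect_equal(length(m$stems), sum(m$points$parent == -1L))
  }
})

test_that("parse_asc reads contour plus branch trees", {
  txt <- c("(\"CellBody\"",
           " (0 0 0 1) (4 0 0 1) (4 4 0 1) (0 4 0 1)",
           ")",
           "( (6 2 0 1.6) (10 2 0 1.4) (14 2 0 1.2) )")
  m <- parse_asc(text = txt)
  expect_equal(m$soma$variant, "contour")
  expect_equal(nrow(m$soma$contour), 4L)
  expect_equal(length(m$stems), 1L)
  expect_equal(nrow(m$points), 3L)
  # Neurolucida thickness is a diameter: stored radius is half
  expect_equal(m$points$radius, c(0.8, 0.7, 0.6))
})

test_that("parse_asc handles a bifurcation with | siblings", {
  txt <- c("(\"CellBody\" (0 0 0 1) (4 0 0 1) (2 4 0 1))",
           "( (6 0 0 1) (10 0 0 1)",
           "  ( (12 2 0 0.8) (14 4 0 0.8)",
           "  | (12 -2 0 0.8) (14 -4 0 0.8) )",
           ")")
  m <- parse_asc(text = txt)
  expect_equal(nrow(m$points), 6L)
  fork_id <- m$points$id[2]
  expect_equal(sum(m$points$parent == fork_id), 2L)
})

test_that("parse_asc error and warning policies", {
  expect_error(parse_asc(text = "( (1 2 3 4)"), class = "nm_parse_error")
  expect_error(parse_asc(text = "( (6 0 0 1) (10 0 0 1) )"),
               class = "nm_structure_error")
  nonplanar <- c("(\"CellBody\" (0 0 0 1) (4 0 0.01 1) (4 4 -0.02 1) (0 4 0.03 1))",
                 "( (6 0 0 1) (10 0 0 1) )")
  expect_warning(parse_asc(text = nonplanar), class = "nm_nonplanar_contour")
})

test_that("contour_to_sphere uses the area-equivalent radius", {
  th <- 2 * pi * (0:63) / 64
  circ <- cbind(3 + 7 * cos(th), -2 + 7 * sin(th), 1)
  s <- contour_to_sphere(soma_contour(circ))
  expect_equal(s$center, c(3, -2, 1), tolerance = 1e-8)
  expect_equal(s$radius, 7, tolerance = 0.005)
  sq <- contour_to_sphere(soma_contour(rbind(c(0, 0, 0), c(1, 0, 0),
                                             c(1, 1, 0), c(0, 1, 0))))
  expect_equal(sq$radius, sqrt(1 / pi), tolerance = 1e-9)
  expect_error(soma_contour(rbind(c(0, 0, 0), c(1, 0, 0))),
               class = "nm_argument_error")
  expect_error(
    contour_to_sphere(soma_contour(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)))),
    class = "nm_geometry_error")
})

test_that("first_order_stems reports exact star directions and empty cases", {
  st <- first_order_stems(star_morphology())
  expect_equal(nrow(st), 4L)
  expect_equal(as.matrix(st[, c("dx", "dy", "dz")]),
               rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0)),
               ignore_attr = TRUE)
  one <- neuron_morphology(
    soma_sphere(c(0, 0, 0), 5),
    data.frame(id = 1L, type = "basal_dendrite", x = 10, y = 0, z = 0,
               radius = 1, parent = -1L), stems = 1L)
  expect_equal(as.numeric(first_order_stems(one)[1, c("dx", "dy", "dz")]),
               c(1, 0, 0))
  none <- generate_morphology(fixture_spec(seed = 1L, n_stems = 0L))
  expect_equal(nrow(first_order_stems(none)), 0L)
  # stem at the soma center has no direction
  bad <- neuron_morphology(
    soma_sphere(c(0, 0, 0), 5),
    data.frame(id = 1L, type = "basal_dendrite", x = 0, y = 0, z = 0,
               radius = 1, parent = -1L), stems = 1L)
  expect_error(first_order_stems(bad), class = "nm_geometry_error")
})
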