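make_oscillator <- function(dt = 0.01) {
  # unit-mass node on a k = 1 spring anchored at the origin, x0 = (1,0,0)
  neuromesh:::new_mass_spring_system(
    positions = matrix(c(1, 0, 0), 1),
    springs = data.frame(i = 1L, j = 0L, L0 = 0, k = 1),
    center = c(0, 0, 0), mass = 1, damping = 0, dt = dt)
}

test_that("build_spring_system creates surface plus internal springs at rest", {
  ico <- make_icosphere(c(0, 0, 0), 2, 0L)
  sys <- build_spring_system(ico)
  expect_equal(sum(sys$springs$j > 0L), 30L)   # icosahedron edges
  expect_equal(sum(sys$springs$j == 0L), 12L)  # one center spring per vertex
  f <- compute_forces(sys)
  expect_lt(max(abs(f)), 1e-10)                # all springs at rest length
  dup <- ico
  dup$vertices[2, ] <- dup$vertices[1, ]
  expect_error(build_spring_system(dup), class = "nm_geometry_error")
})

test_that("Hooke forces are equal, opposite and damped", {
  sys <- neuromesh:::new_mass_spring_system(
    positions = rbind(c(0, 0, 0), c(1.5, 0, 0)),
    springs = data.frame(i = 1L, j = 2L, L0 = 1, k = 2),
    mass = 1, damping = 0, dt = 0.01)
  f <- compute_forces(sys)
  expect_equal(f[1, ], c(1, 0, 0))    # magnitude k (L - L0) = 2 * 0.5
  expect_equal(f[2, ], c(-1, 0, 0))   # Newton's third law
  # symmetric star of identical stretched springs: zero net force at center
  ns <- 6L
  th <- 2 * pi * (0:(ns - 1)) / ns
  sys2 <- neuromesh:::new_mass_spring_system(
    positions = rbind(c(0, 0, 0), cbind(2 * cos(th), 2 * sin(th), 0)),
    springs = data.frame(i = 1L, j = 2:(ns + 1L), L0 = 1, k = 3),
    mass = 1, damping = 0, dt = 0.01)
  expect_lt(max(abs(compute_forces(sys2)[1, ])), 1e-12)
  # with damping, moving nodes feel -c v; pinned nodes report zero force
  sys$vel[1, ] <- c(0, 2, 0)
  sys$damping <- 0.5
  f2 <- compute_forces(sys)
  expect_equal(f2[1, ], c(1, -1, 0))
  sys3 <- pin_nodes(sys, 1L, sys$pos[1, , drop = FALSE])
  expect_equal(compute_forces(sys3)[1, ], c(0, 0, 0))
})

test_that("spring forces over all free nodes cancel pairwise", {
  ico <- make_icosphere(c(0, 0, 0), 2, 1L)
  sys <- build_spring_system(ico, damping = 0)
  sys$springs <- sys$springs[sys$springs$j > 0L, ]  # surface springs only
  sys$pos <- sys$pos * 1.3                          # stretch uniformly
  f <- compute_forces(sys)
  expect_lt(max(abs(colSums(f))), 1e-9)
})

test_that("Verlet holds the oscillator amplitude while Euler injects energy", {
  dt <- 0.01
  steps <- round(2 * pi / dt)
  run <- function(method) {
    sys <- make_oscillator(dt)
    traj <- numeric(steps)
    for (s in seq_len(steps)) {
      sys <- integrate_step(sys, method)
      traj[s] <- sys$pos[1, 1]
    }
    list(final = sys$pos[1, ], amp = max(abs(traj)), traj = traj)
  }
  v <- run("verlet")
  # x(t) = cos t returns to (1, 0, 0) after one period
  expect_equal(v$final, c(1, 0, 0), tolerance = 0.01)
  verlet_drift <- abs(v$amp - 1)
  expect_lt(verlet_drift, 0.01)
  e <- run("euler")
  euler_drift <- abs(e$amp - 1)
  expect_gt(euler_drift, verlet_drift)
  # Euler's envelope grows monotonically: successive |extrema| increase
  ex <- abs(e$traj[c(round(steps / 2), steps)])
  expect_gt(ex[2], ex[1])
  r <- run("rk2")
  expect_equal(r$final, c(1, 0, 0), tolerance = 0.05)
})

test_that("equilibrium states are fixed points of every integrator", {
  ico <- make_icosphere(c(0, 0, 0), 2, 1L)
  for (method in c("euler", "rk2", "verlet")) {
    sys <- build_spring_system(ico)
    sys <- integrate_step(sys, method)
    expect_equal(sys$pos, ico$vertices, tolerance = 1e-12)
  }
})

test_that("divergence raises an informative error", {
  sys <- make_oscillator(dt = 1e6)
  expect_error({
    for (s in 1:50) sys <- integrate_step(sys, "euler")
  }, class = "nm_divergence_error")
})

test_that("the compiled relaxation loop matches R integration", {
  ico <- make_icosphere(c(0, 0, 0), 2, 1L)
  sys <- build_spring_system(ico, damping = 0.5)
  # same perturbed start, no pins: run n Verlet steps both ways
  sys$pos[1, ] <- sys$pos[1, ] * 1.2
  n <- 40L
  res <- neuromesh:::.relax_verlet(
    positions = sys$pos,
    spring_i = sys$springs$i, spring_j = sys$springs$j,
    L0 = sys$springs$L0, K = sys$springs$k, center = sys$center,
    mass = sys$mass, damping = sys$damping, dt = sys$dt,
    pinned = integer(0), pin_from = matrix(0, 0, 3),
    pin_to = matrix(0, 0, 3), schedule_steps = 0L, max_steps = n,
    ke_tol_per_node = 0)
  rsys <- sys
  for (s in seq_len(n)) rsys <- integrate_step(rsys, "verlet")
  # the two startup formulas differ by a O(dt^3) damping term on step one
  expect_equal(unname(res$positions), unname(rsys$pos), tolerance = 1e-5)
})
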