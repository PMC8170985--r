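unit_cube <- function() box_mesh(c(1e-3, 1e-3, 1e-3), c(1L, 1L, 1L))

test_that("element deformation: identity, affine stretch, rigid rotation", {
  mesh <- unit_cube()
  u0 <- matrix(0, 8, 3)
  for (st in element_deformation(mesh, u0, 1)) {
    expect_equal(st$F, diag(3))
    expect_equal(st$J, 1)
  }

  u <- cbind(0.2 * mesh$nodes[, 1], 0, 0)   # x -> 1.2 x
  for (st in element_deformation(mesh, u, 1)) {
    expect_equal(sort(st$lambda), sort(c(1.2, 1, 1)), tolerance = 1e-12)
    expect_equal(st$J, 1.2, tolerance = 1e-12)
  }

  set.seed(7)
  Q <- random_rotation()
  uq <- mesh$nodes %*% t(Q) - mesh$nodes
  for (st in element_deformation(mesh, uq, 1)) {
    expect_equal(st$lambda, c(1, 1, 1), tolerance = 1e-10)
    expect_equal(st$J, 1, tolerance = 1e-10)
  }
  expect_error(element_deformation(mesh, u0, 99),
               class = "foamfem_invalid_argument")
})

test_that("patch test: affine displacement reproduces the homogeneous stress", {
  mesh <- unit_cube()
  mat <- test_material()
  set.seed(17)
  A <- matrix(stats::runif(9, -0.1, 0.1), 3, 3)
  u <- mesh$nodes %*% t(A)
  Fh <- diag(3) + A
  S_exact <- cauchy_stress(Fh, mat)
  for (st in element_deformation(mesh, u, 1)) {
    expect_equal(st$F, Fh, tolerance = 1e-12)
    expect_equal(cauchy_stress(st, mat), S_exact, tolerance = 1e-6)
  }
})

test_that("internal forces: zero at rest, self-equilibrated, face equilibrium", {
  mesh <- unit_cube()
  mat <- test_material()
  expect_equal(internal_forces(mesh, matrix(0, 8, 3), mat), matrix(0, 8, 3))

  set.seed(27)
  for (i in 1:5) {
    A <- matrix(stats::runif(9, -0.2, 0.2), 3, 3)
    f <- internal_forces(mesh, mesh$nodes %*% t(A), mat)
    expect_lt(max(abs(colSums(f))), 1e-8 * max(abs(f), 1e-30))
  }

  # uniform uniaxial stress state: +x face forces sum to sigma * current area
  nu <- mat$nu; lam <- 1.3
  u <- cbind((lam - 1) * mesh$nodes[, 1],
             (lam^-nu - 1) * mesh$nodes[, 2],
             (lam^-nu - 1) * mesh$nodes[, 3])
  f <- internal_forces(mesh, u, mat)
  S <- cauchy_stress(diag(c(lam, lam^-nu, lam^-nu)), mat)
  face <- which(mesh$nodes[, 1] > 0.5e-3)
  area_cur <- (1e-3 * lam^-nu)^2
  expect_equal(sum(f[face, 1]), S[1, 1] * area_cur, tolerance = 1e-6)
  # lateral faces are stress free
  expect_equal(S[2, 2], 0, tolerance = 1e-9 * abs(S[1, 1]))
})

test_that("translation invariance: rigid translation produces zero force", {
  mesh <- box_mesh(c(2e-3, 1e-3, 1e-3), c(2L, 1L, 1L))
  mat <- test_material()
  u <- matrix(rep(c(3e-3, -2e-3, 1e-3), each = nrow(mesh$nodes)), ncol = 3)
  expect_equal(internal_forces(mesh, u, mat), matrix(0, nrow(mesh$nodes), 3))
})

test_that("lumped mass: V/8 split, exact total, refinement invariance", {
  mesh <- unit_cube()
  mat <- material_constants(1000, 1e6, 1e4, 0.3, C = 1e3, b = 2)
  M <- lumped_mass(mesh, mat)
  expect_equal(M, rep(1000 * 1e-9 / 8, 8))
  expect_equal(sum(M), 1000 * 1e-9)

  fine <- box_mesh(c(1e-3, 1e-3, 1e-3), c(3L, 2L, 2L))
  expect_equal(sum(lumped_mass(fine, mat)), 1000 * 1e-9)

  two <- box_mesh(c(2e-3, 1e-3, 1e-3), c(2L, 1L, 1L))
  M2 <- lumped_mass(two, mat)
  shared <- which(abs(two$nodes[, 1] - 1e-3) < 1e-12)
  expect_equal(M2[shared], rep(2 * 1000 * 1e-9 / 8, 4))
})

test_that("critical time step follows L/c and scales with element size", {
  mat <- material_constants(1000, K = 1e9 - 4 / 3 * 1e4, G = 1e4, nu = 0.3,
                            C = 1e3, b = 2)   # c = 1000 m/s
  mesh <- box_mesh(c(1, 1, 1), c(1L, 1L, 1L))  # L = 1 m
  ti <- critical_timestep(mesh, mat, safety = 1)
  expect_equal(ti$dt, 1e-3, tolerance = 1e-12)

  # L = 1 mm, c = 1500 m/s
  m2 <- material_constants(1000, K = 1500^2 * 1000 - 4 / 3 * 1e4, G = 1e4,
                           nu = 0.3, C = 1e3, b = 2)
  mm <- box_mesh(c(1e-3, 1e-3, 1e-3), c(1L, 1L, 1L))
  expect_equal(critical_timestep(mm, m2, safety = 1)$dt, 1e-3 / 1500,
               tolerance = 1e-9)

  half <- box_mesh(c(0.5e-3, 0.5e-3, 0.5e-3), c(1L, 1L, 1L))
  expect_equal(critical_timestep(half, m2, safety = 1)$dt,
               0.5 * critical_timestep(mm, m2, safety = 1)$dt)
})

test_that("selective mass scaling only grows sub-target elements and reports added mass", {
  mesh <- box_mesh(c(1e-3, 1e-3, 1e-3), c(1L, 1L, 1L))
  mat <- test_material()
  ti <- critical_timestep(mesh, mat, safety = 1)

  res0 <- apply_mass_scaling(mesh, mat, dt_target = ti$dt / 2)
  expect_identical(res0$densities, mat$density)
  expect_identical(res0$info$added_mass, 0)

  # dt_crit = 0.0005 ms, target 0.001 ms -> density x4
  res4 <- apply_mass_scaling(mesh, mat, dt_target = 2 * ti$dt)
  expect_equal(res4$densities, 4 * mat$density, tolerance = 1e-12)
  expect_gte(min(res4$info$dt_crit), 2 * ti$dt * (1 - 1e-12))
  total <- mat$density * sum(mesh$volumes)
  expect_equal(res4$info$added_mass, 3 * total, tolerance = 1e-12)
  expect_equal(res4$info$added_mass_pct, 300, tolerance = 1e-12)
})

test_that("central difference: inertial kinematics and momentum conservation", {
  # zero net force: velocity constant, displacement linear
  st <- nodal_state(u = matrix(0, 1, 3), v = matrix(c(1, 0, 0), 1, 3), M = 2)
  z <- matrix(0, 1, 3)
  for (i in 1:10) st <- central_difference_step(st, z, z, dt = 0.1)
  expect_equal(st$v, matrix(c(1, 0, 0), 1, 3))
  expect_equal(st$u, matrix(c(1, 0, 0), 1, 3), tolerance = 1e-12)

  # constant force F on mass m: u(T) = F T^2 / (2 m) to O(dt^2)
  st <- nodal_state(u = matrix(0, 1, 3), v = matrix(0, 1, 3), M = 2)
  Fc <- matrix(c(3, 0, 0), 1, 3)
  dt <- 1e-3
  for (i in 1:1000) st <- central_difference_step(st, z, Fc, dt = dt)
  expect_equal(st$u[1, 1], 0.5 * (3 / 2) * 1^2, tolerance = 1e-4)

  expect_error(central_difference_step(st, z * NA, Fc, dt),
               class = "foamfem_instability")

  # free body in flight: momentum exactly conserved, f_int stays ~0
  model <- make_cuboid8(termination = 5e-3)
  model$config$initial_velocity <- c(1, 0.5, -0.2)
  run <- run_simulation(model)
  M <- lumped_mass(model$mesh, model$materials[[1]])
  p0 <- colSums(M * run$node$v[1, , ])
  pT <- colSums(M * run$node$v[length(run$time), , ])
  expect_equal(pT, p0, tolerance = 1e-10)
})

test_that("rigid plane penalty contact forces follow penetration depth", {
  pl <- rigid_plane(c(0, 0, 0), c(0, 0, 1), penalty = 100)
  x <- matrix(c(0, 0, 0.5,
                1, 0, -0.02,
                0, 1, 0.1), 3, 3, byrow = TRUE)
  ct <- rigid_plane_contact(x, pl)
  expect_equal(ct$forces[1, ], c(0, 0, 0))
  expect_equal(ct$forces[2, ], c(0, 0, 100 * 0.02))
  expect_equal(ct$resultant, c(0, 0, 2))
  expect_equal(rigid_plane_contact(x + 1, pl)$resultant, c(0, 0, 0))
  expect_error(rigid_plane(c(0, 0, 0), c(0, 0, 2), 1),
               class = "foamfem_invalid_argument")
})

test_that("negative volume terminates with a named element and partial output", {
  model <- make_drop_block(sfo = 1, impact_speed = 30, penalty_scale = 5,
                           termination = 5e-3)
  run <- run_simulation(model)
  expect_true(run$manifest$termination_status %in% c("negative_volume", "unstable"))
  expect_gt(length(run$time), 0)
  if (run$manifest$termination_status == "negative_volume") {
    expect_match(run$manifest$status_message, "element \\d+")
  }
})

test_that("deterministic replay: identical model gives bitwise identical output", {
  m1 <- make_drop_block(sfo = 1, termination = 3e-3)
  m2 <- make_drop_block(sfo = 1, termination = 3e-3)
  r1 <- run_simulation(m1)
  r2 <- run_simulation(m2)
  expect_identical(r1$element$stress, r2$element$stress)
  expect_identical(r1$node$u, r2$node$u)
  expect_identical(r1$contact, r2$contact)
})
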