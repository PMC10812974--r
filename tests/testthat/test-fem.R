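test_that("element kinematics reproduce affine fields exactly", {
  tet <- make_unit_fixture("single_tet")
  X <- tet$nodes
  expect_equal(element_kinematics(X, matrix(0, 4, 3)), diag(3))
  # rigid translation
  expect_equal(element_kinematics(X, matrix(1, 4, 3) %*% diag(c(1, 2, 3))),
               diag(3))
  # affine displacement u = A X reproduced exactly
  A <- matrix(c(0.1, 0.02, -0.03, 0.01, -0.05, 0.04, 0, 0.03, 0.06), 3, 3)
  U <- X %*% t(A)
  expect_equal(element_kinematics(X, U), diag(3) + A, tolerance = 1e-14)
})

test_that("strain-displacement matrix linearizes the Green-Lagrange strain", {
  set.seed(11)
  tet <- make_unit_fixture("single_tet")
  X <- tet$nodes
  E_of <- function(U) {
    F <- element_kinematics(X, U)
    (crossprod(F) - diag(3)) / 2
  }
  to_voigt <- function(E) c(E[1, 1], E[2, 2], E[3, 3],
                            2 * E[1, 2], 2 * E[2, 3], 2 * E[1, 3])
  for (case in 1:3) {
    U <- matrix(runif(12, -0.05, 0.05), 4, 3)
    B <- strain_displacement_matrix(X, U)
    # small-strain operator at the reference configuration
    if (case == 1) {
      B0 <- strain_displacement_matrix(X, matrix(0, 4, 3))
      expect_equal(B0, strain_displacement_matrix(X, matrix(0, 4, 3)))
    }
    dU <- matrix(runif(12, -1, 1), 4, 3)
    eps <- 1e-7
    dE_fd <- (E_of(U + eps * dU) - E_of(U - eps * dU)) / (2 * eps)
    dE_B <- B %*% as.vector(t(dU))
    expect_lt(max(abs(to_voigt(dE_fd) - dE_B)), 1e-6)
  }
})

test_that("the assembled rest state is exactly stress-free", {
  mesh <- make_synthetic_forearm(forearm_params(edge_length = 22))
  model <- fem_model(mesh)
  st <- system_state(model)
  expect_equal(st$lam, rep(-1, model$n_lam))
  asm <- assemble_system(model, st)
  expect_lt(sqrt(sum(asm$residual^2)), 1e-10)
})

test_that("internal forces balance the applied load at convergence", {
  cube <- make_unit_fixture("unit_cube", 1)
  model <- fem_model(cube, fibers = axial_fibers(6))
  lc <- load_case(dirichlet = list(
    list(set = "x0", comps = c("x", "y", "z"), value = 0)),
    loads = list(list(set = "x1", force = c(0.05, 0, 0))),
    schedule = "constant")
  st <- newton_solve(model, system_state(model), lc,
                     settings = solver_settings(dt = 1, tol = 1e-10))
  fint <- attr(st, "newton")$fint
  # reaction at the fixed face equals the applied load (Newton's third law)
  fixed_dofs <- 3 * (cube$sets$x0 - 1) + 1
  expect_equal(sum(fint[fixed_dofs]), -0.05, tolerance = 1e-8)
})

test_that("a single-element solve reproduces the material-point stress", {
  tet <- make_unit_fixture("single_tet")
  model <- fem_model(tet, fibers = axial_fibers(1))
  lam <- 1.15
  st <- solve_uniaxial(model, tet, lam, alpha = 0)
  # FE nominal stress against the independent 1D oracle
  p_fe <- axial_nominal_stress(st, tet, single_tet = TRUE)
  expect_equal(p_fe, uniaxial_oracle(lam, 0), tolerance = 1e-8)
  # transverse stretch lambda^(-1/2) from the incompressibility constraint
  uy <- st$u[3 * (which(tet$nodes[, 2] == 1) - 1) + 2]
  expect_equal(1 + uy, lam^-0.5, tolerance = 1e-6)
})

test_that("zero load and zero activation stay at rest in one iteration", {
  cube <- make_unit_fixture("unit_cube", 1)
  model <- fem_model(cube, fibers = axial_fibers(6))
  lc <- load_case(dirichlet = list(
    list(set = "x0", comps = c("x", "y", "z"), value = 0)))
  st <- newton_solve(model, system_state(model), lc)
  expect_equal(attr(st, "newton")$iterations, 1)
  expect_equal(max(abs(st$u)), 0)
})

test_that("Newton converges superlinearly near the root", {
  tet <- make_unit_fixture("single_tet")
  model <- fem_model(tet, fibers = axial_fibers(1))
  st <- solve_uniaxial(model, tet, 1.2, alpha = 0.5, n_increments = 2)
  res <- attr(st, "newton")$residuals
  res <- res[res > 1e-14]
  # ratios of successive residuals shrink as the root is approached
  ratios <- res[-1] / res[-length(res)]
  n <- length(ratios)
  expect_gte(n, 2)
  expect_lt(ratios[n], ratios[max(1, n - 1)])
  expect_lt(ratios[n], 1e-2)
})

test_that("mesh refinement leaves the homogeneous end force unchanged", {
  lam <- 1.1
  forces <- vapply(c(1, 2), function(s) {
    cube <- make_unit_fixture("unit_cube", s)
    model <- fem_model(cube, fibers = axial_fibers(nrow(cube$elems)))
    st <- solve_uniaxial(model, cube, lam, alpha = 0)
    axial_nominal_stress(st, cube)
  }, 1)
  expect_lt(abs(forces[2] - forces[1]) / abs(forces[1]), 0.02)
})

test_that("isometric activation ramps track the material-point stress", {
  cube <- make_unit_fixture("unit_cube", 1)
  model <- fem_model(cube, fibers = axial_fibers(6))
  lc <- load_case(dirichlet = list(
    list(set = "x0", comps = "x", value = 0),
    list(set = "x1", comps = "x", value = 0),
    list(set = "y0", comps = "y", value = 0),
    list(set = "z0", comps = "z", value = 0)))
  prof <- activation_profile("linear_ramp", t_peak = 0.5, alpha_max = 0.91)
  hist <- time_march(model, lc, prof, t_end = 0.5,
                     settings = solver_settings(dt = 0.05),
                     record_stress = TRUE)
  expected <- muscle_params()$T0M * ramp_value(hist$times, prof)
  expect_lt(max(abs(rowMeans(hist$fiber_stress) - expected)), 1e-8)
  expect_lt(max(hist$max_J_dev), 1e-5)
  # at rest with no load or activation nothing moves
  hist0 <- time_march(model, lc,
                      activation_profile("ode", u = 0), t_end = 0.1,
                      settings = solver_settings(dt = 0.05))
  expect_equal(max(vapply(hist0$u, function(u) max(abs(u)), 1)), 0)
})

test_that("halving the time step barely changes a slow activation ramp", {
  cube <- make_unit_fixture("unit_cube", 1)
  model <- fem_model(cube, fibers = axial_fibers(6))
  # free-end contraction: one face fixed, activation shortens the cube
  lc <- load_case(dirichlet = list(
    list(set = "x0", comps = "x", value = 0),
    list(set = "y0", comps = "y", value = 0),
    list(set = "z0", comps = "z", value = 0)))
  prof <- activation_profile("linear_ramp", t_peak = 1.0, alpha_max = 0.5)
  ux <- vapply(c(0.05, 0.025), function(dt) {
    hist <- time_march(model, lc, prof, t_end = 1.0,
                       settings = solver_settings(dt = dt))
    u_end <- hist$u[[length(hist$u)]]
    mean(u_end[3 * (cube$sets$x1 - 1) + 1])
  }, 1)
  expect_gt(abs(ux[1]), 1e-3)          # the cube actually shortens
  expect_lt(abs(ux[2] - ux[1]) / abs(ux[1]), 0.01)
})

test_that("solutions are invariant under element reordering", {
  cube <- make_unit_fixture("unit_cube", 1)
  perm <- c(4L, 2L, 6L, 1L, 5L, 3L)
  cube2 <- fem_mesh(cube$nodes, cube$elems[perm, ], cube$region[perm],
                    cube$sets, elem_patch = cube$elem_patch[perm])
  lam <- 1.12
  f1 <- axial_nominal_stress(
    solve_uniaxial(fem_model(cube, fibers = axial_fibers(6)), cube,
                   lam, 0.3), cube)
  f2 <- axial_nominal_stress(
    solve_uniaxial(fem_model(cube2, fibers = axial_fibers(6)), cube2,
                   lam, 0.3), cube2)
  expect_equal(f1, f2, tolerance = 1e-9)
})

test_that("load on a constrained component is rejected", {
  cube <- make_unit_fixture("unit_cube", 1)
  model <- fem_model(cube, fibers = axial_fibers(6))
  lc <- load_case(dirichlet = list(
    list(set = "x1", comps = "x", value = 0)),
    loads = list(list(set = "x1", force = c(1, 0, 0))))
  expect_error(newton_solve(model, system_state(model), lc),
               "must not also be loaded")
})
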