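test_that("the Laplace solution on a straight cylinder is exactly linear", {
  cyl <- make_cylinder_fixture(length = 50, radius = 5, n_axial = 8)
  phi <- solve_laplace(cyl, "z0", "z1")
  expect_lt(max(abs(phi - cyl$nodes[, 3] / 50), na.rm = TRUE), 1e-8)
  # maximum principle: extrema on the Dirichlet boundary
  expect_true(all(phi >= -1e-12 & phi <= 1 + 1e-12, na.rm = TRUE))
  dirs <- fiber_directions(cyl, phi)
  expect_equal(nrow(dirs), nrow(cyl$elems))
  expect_lt(max(abs(rowSums(dirs^2) - 1)), 1e-9)
  # directions within 1e-6 radians of the axis, oriented source -> sink
  ang <- acos(pmin(1, dirs[, 3]))
  expect_lt(max(ang), 1e-6)
})

test_that("a single tetrahedron solves to the stiffness-weighted average", {
  tet <- make_unit_fixture("single_tet")
  tet$sets <- list(fixed = c(1L, 2L, 3L), free = 4L,
                   src = c(1L, 2L), snk = 3L)
  # hand-computed element Laplacian: K = V * G G' with G the constant
  # shape gradients of this tetrahedron
  X <- tet$nodes
  D <- cbind(1, X)
  G <- t(solve(D)[2:4, ])
  K <- (det(D) / 6) * G %*% t(G)
  vals <- c(0, 0, 1)                     # src nodes 0, snk node 1
  expected <- -sum(K[4, 1:3] * vals) / K[4, 4]
  phi <- solve_laplace(tet, "src", "snk")
  expect_equal(unname(phi[4]), expected, tolerance = 1e-12)
})

test_that("Laplace problem rejects bad Dirichlet sets", {
  cyl <- make_cylinder_fixture(n_axial = 4)
  cyl$sets$overlap <- c(cyl$sets$z0[1], cyl$sets$z1[1])
  expect_error(solve_laplace(cyl, "z0", "overlap"), "overlap")
  expect_error(solve_laplace(cyl, "z0", "nope"), "no node set")
})

test_that("fiber directions rotate with the mesh", {
  cyl <- make_cylinder_fixture(length = 30, radius = 4, n_axial = 6)
  phi <- solve_laplace(cyl, "z0", "z1")
  d0 <- fiber_directions(cyl, phi)
  th <- 0.7
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  rot <- cyl
  rot$nodes <- cyl$nodes %*% t(R)
  phi_r <- solve_laplace(rot, "z0", "z1")
  expect_lt(max(abs(phi - phi_r), na.rm = TRUE), 1e-9)
  d1 <- fiber_directions(rot, phi_r)
  expect_lt(max(abs(d1 - d0 %*% t(R))), 1e-8)
})

test_that("fusiform muscle fibers follow the centerline", {
  mesh <- make_synthetic_forearm(forearm_params(edge_length = 18))
  phi <- solve_laplace(mesh, "muscle_proximal", "muscle_distal")
  expect_true(all(phi[!is.na(phi)] >= -1e-10 & phi[!is.na(phi)] <= 1 + 1e-10))
  dirs <- fiber_directions(mesh, phi)
  axis <- attr(mesh, "forearm")$muscle_axis
  dev <- acos(pmin(1, abs(dirs %*% axis))) * 180 / pi
  expect_lt(mean(dev), 10)
})
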