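test_that("unit fixtures are watertight with named face sets", {
  tet <- make_unit_fixture("single_tet")
  expect_equal(nrow(tet$nodes), 4)
  expect_equal(nrow(tet$elems), 1)
  expect_equal(sum(tet_volumes(tet)), 1 / 6, tolerance = 1e-12)

  cube <- make_unit_fixture("unit_cube", 1)
  expect_equal(nrow(cube$elems), 6)
  expect_equal(sum(tet_volumes(cube)), 1, tolerance = 1e-12)
  expect_true(all(tet_volumes(cube) > 0))
  expect_setequal(names(cube$sets), c("x0", "x1", "y0", "y1", "z0", "z1"))
  expect_true(all(vapply(cube$sets, length, 1L) == 4))

  cube2 <- make_unit_fixture("unit_cube", 3)
  expect_equal(nrow(cube2$elems), 6 * 27)
  expect_equal(sum(tet_volumes(cube2)), 1, tolerance = 1e-12)
})

test_that("synthetic forearm honours its construction contract", {
  p <- forearm_params(edge_length = 18)
  mesh <- make_synthetic_forearm(p)
  expect_gte(nrow(mesh$elems), 200)
  expect_true(all(tet_volumes(mesh) > 0))
  expect_setequal(unique(mesh$region), c("muscle", "bone", "tendon"))
  needed <- c("tendon_proximal_fixed", "radius_proximal_pin",
              "radius_y_restrained", "radius_load",
              "muscle_proximal", "muscle_distal", "insertion")
  expect_true(all(needed %in% names(mesh$sets)))
  expect_true(all(vapply(mesh$sets[needed], length, 1L) >= 1))
  expect_length(mesh$sets$radius_proximal_pin, 1)

  # region adjacency: bone and muscle never touch; bone meets tendon only
  # at the insertion patch; muscle meets tendon at its attachment faces
  node_regions <- function(r)
    sort(unique(as.vector(mesh$elems[mesh$region == r, ])))
  bone_n <- node_regions("bone")
  mus_n <- node_regions("muscle")
  ten_n <- node_regions("tendon")
  expect_length(intersect(bone_n, mus_n), 0)
  expect_setequal(intersect(bone_n, ten_n), mesh$sets$insertion)
  expect_true(all(mesh$sets$muscle_proximal %in% intersect(mus_n, ten_n)))
  expect_true(all(mesh$sets$muscle_distal %in% intersect(mus_n, ten_n)))

  # mesh quality floor (documented): the insertion bridge contains flat
  # transition elements; the floor is 0.2 degrees
  expect_gt(min_dihedral_angle(mesh), 0.2)
})

test_that("region volumes match the generative solids", {
  mesh <- make_synthetic_forearm(forearm_params(edge_length = 18))
  v <- tapply(tet_volumes(mesh), mesh$region, sum)
  va <- attr(mesh, "forearm")$analytic_volumes
  expect_lt(abs(v[["bone"]] - va[["bone"]]) / va[["bone"]], 0.05)
  expect_lt(abs(v[["muscle"]] - va[["muscle"]]) / va[["muscle"]], 0.05)
})

test_that("generation is deterministic and scales geometrically", {
  p <- forearm_params(edge_length = 20, jitter = 0.05, seed = 3)
  m1 <- make_synthetic_forearm(p)
  m2 <- make_synthetic_forearm(p)
  expect_identical(m1$nodes, m2$nodes)
  expect_identical(m1$elems, m2$elems)

  base <- forearm_params(edge_length = 20)
  dbl <- forearm_params(radius_length = 500, radius_radius = 16,
                        muscle_length = 400, muscle_max_radius = 64,
                        tendon_length = 30, tendon_radius = 16,
                        edge_length = 40, bridge_height = 24)
  v1 <- sum(tet_volumes(make_synthetic_forearm(base)))
  v2 <- sum(tet_volumes(make_synthetic_forearm(dbl)))
  expect_equal(v2 / v1, 8, tolerance = 0.02)
})

test_that("generator rejects invalid parameters and keeps >= 200 elements", {
  expect_error(forearm_params(edge_length = -1))
  expect_error(forearm_params(q = 3), "even")
  expect_error(forearm_params(muscle_length = 300), "allowance")
  # the minimal layer counts keep even very coarse requests above the
  # 200-element floor
  coarse <- make_synthetic_forearm(forearm_params(edge_length = 100))
  expect_gte(nrow(coarse$elems), 200)
})
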