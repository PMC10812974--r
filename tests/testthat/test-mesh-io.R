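round_trip_identical <- function(mesh, format, ext) {
  path <- withr::local_tempfile(fileext = ext)
  write_mesh(mesh, path, format = format)
  m2 <- read_mesh(path)
  expect_lt(max(abs(m2$nodes - mesh$nodes)), 1e-12)
  expect_identical(unname(m2$elems), unname(mesh$elems))
  expect_identical(m2$region, mesh$region)
  expect_identical(m2$sets[names(mesh$sets)], mesh$sets)
}

test_that("all formats round-trip the forearm mesh exactly", {
  mesh <- make_synthetic_forearm(forearm_params(edge_length = 22))
  round_trip_identical(mesh, "msh22", ".msh")
  round_trip_identical(mesh, "msh41", ".msh")
  round_trip_identical(mesh, "vtk", ".vtk")
  round_trip_identical(mesh, "vtu", ".vtu")
})

test_that("MSH node tags are 1-based on disk and survive renumbering", {
  cube <- make_unit_fixture("unit_cube", 1)
  path <- withr::local_tempfile(fileext = ".msh")
  write_mesh(cube, path, format = "msh22")
  lines <- readLines(path)
  i0 <- which(lines == "$Nodes")
  first_node <- strsplit(lines[i0 + 2], "\\s+")[[1]][1]
  expect_identical(first_node, "1")
  round_trip_identical(cube, "msh22", ".msh")
})

test_that("readers fail fast on defective files", {
  expect_error(read_mesh("does-not-exist.msh"), "does not exist")
  bogus <- withr::local_tempfile(fileext = ".xyz")
  writeLines("not a mesh", bogus)
  expect_error(read_mesh(bogus, format = "xyz"), "unknown mesh format")

  # a VTK file without region labels is rejected, never defaulted
  cube <- make_unit_fixture("unit_cube", 1)
  path <- withr::local_tempfile(fileext = ".vtk")
  write_mesh(cube, path, format = "vtk")
  lines <- readLines(path)
  drop <- grep("^CELL_DATA|^SCALARS region|^LOOKUP_TABLE", lines)[1:3]
  n_rg <- nrow(cube$elems)
  rg_line <- grep("^SCALARS region", lines) + 2
  writeLines(lines[-(c(drop, rg_line))], path)
  expect_error(read_mesh(path), "region")
})

test_that("the state writer exports displacement and element fields", {
  cube <- make_unit_fixture("unit_cube", 1)
  model <- fem_model(cube, fibers = axial_fibers(6))
  st <- system_state(model)
  st$u <- rep(c(0.01, 0, 0), nrow(cube$nodes))
  path <- withr::local_tempfile(fileext = ".vtk")
  write_vtk_state(model, st, path)
  lines <- readLines(path)
  expect_true(any(grepl("VECTORS displacement", lines)))
  expect_true(any(grepl("SCALARS jacobian", lines)))
  expect_true(any(grepl("SCALARS fiber_stretch", lines)))
  expect_true(any(grepl("SCALARS multiplier", lines)))
})
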