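test_that("flexion angle recovers rigid rotations exactly", {
  ref <- rbind(c(0, 0, 0), c(250, 0, 0))
  expect_equal(elbow_flexion_angle(ref, ref), 0)
  # rotation about the mediolateral axis lifting the distal end (+z)
  lift_y <- function(deg) {
    th <- deg * pi / 180
    rbind(c(cos(th), 0, -sin(th)), c(0, 1, 0), c(sin(th), 0, cos(th)))
  }
  cur <- ref %*% t(lift_y(30))
  expect_gt(cur[2, 3], 0)              # the distal marker moved upward
  expect_equal(elbow_flexion_angle(ref, cur), 30, tolerance = 1e-12)
  expect_equal(elbow_flexion_angle(ref, ref %*% t(lift_y(-12))), -12,
               tolerance = 1e-12)
  # small mediolateral perturbation barely affects the sagittal angle
  cur2 <- cur
  cur2[2, 2] <- cur2[2, 2] + 2.5       # 1% of the segment length
  expect_lt(abs(elbow_flexion_angle(ref, cur2) - 30), 0.2)
  expect_error(elbow_flexion_angle(ref, rbind(c(0, 0, 0), c(0, 0, 0))),
               "non-coincident")
})

test_that("uniaxial validation passes against the 1D oracle", {
  rep <- run_uniaxial_validation(lambdas = c(1.1, 1.2, 1.3),
                                 alphas = c(0.5, 0.91))
  expect_s3_class(rep, "uniaxial_validation")
  expect_true(attr(rep, "pass"))
  expect_lt(attr(rep, "max_rel_error"), 0.01)
  # the isometric case at alpha = 0.91 carries the maximal nominal stress
  iso <- rep[rep$mode == "isometric_activation" & rep$value == 0.91, ]
  expect_equal(iso$fe_stress, rep(0.535 * 0.91, nrow(iso)),
               tolerance = 1e-4)
})

test_that("scenario configs and material files round-trip through YAML", {
  mat_path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("muscle: {type: muscle, T0M: 0.4, u: 0.3}",
               "bone: {type: bone}",
               "tendon: {type: tendon, lame_lambda: 9000, lame_mu: 60}"),
             mat_path)
  mats <- read_material_file(mat_path)
  expect_equal(mats$muscle$T0M, 0.4)
  expect_equal(mats$muscle$u, 0.3)
  expect_equal(mats$tendon$lame_mu, 60)
  expect_s3_class(mats$bone, "elastic_params")

  cfg_path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("study: strength",
               "geometry: {edge_length: 20}",
               "dt: 0.02", "t_end: 0.4", "max_load: 50",
               sprintf("materials: %s", mat_path)),
             cfg_path)
  sc <- read_scenario_config(cfg_path)
  expect_equal(sc$study, "strength")
  expect_equal(sc$config$dt, 0.02)
  expect_equal(sc$config$max_load, 50)
  expect_equal(sc$config$materials$muscle$T0M, 0.4)
  expect_equal(sc$config$geometry$edge_length, 20)
})

test_that("study runners are deterministic and export bitwise-equal CSVs", {
  mesh <- make_synthetic_forearm(forearm_params(edge_length = 22))
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  short <- function(out) {
    cfg <- study_config(mesh = mesh, dt = 0.05, t_end = 0.2,
                        output_dir = out)
    mus <- muscle_params()
    tr <- musclefem:::run_sarcopenia_case(cfg, mesh, mus)
    musclefem:::export_study(
      musclefem:::finish_study("mini", "case", 1, list(tr),
                               list(output_dir = NULL)), out)
    tr
  }
  t1 <- short(out1)
  t2 <- short(out2)
  expect_identical(t1$angle, t2$angle)
  f1 <- file.path(out1, "mini_case01.csv")
  f2 <- file.path(out2, "mini_case01.csv")
  expect_true(file.exists(f1))
  expect_identical(readLines(f1), readLines(f2))
})

test_that("the command-line interface honours its exit-code contract", {
  expect_equal(suppressMessages(cli_main("definitely-not-a-command")), 2L)
  expect_equal(cli_main(character()), 2L)
  expect_equal(suppressMessages(cli_main(c("run", "/no/such/config.yaml"))),
               1L)
  mesh_path <- withr::local_tempfile(fileext = ".vtu")
  expect_equal(suppressMessages(
    cli_main(c("mesh", mesh_path, "--kind", "unit_cube"))), 0L)
  expect_true(file.exists(mesh_path))
})
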