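test_that("kinematics reproduce reference, isochoric and dilated states", {
  k <- kinematics_from_F(diag(3), c(1, 0, 0), lambda_f_prev = 1, dt = 0.01)
  expect_equal(k$J, 1)
  expect_equal(k$lambda_f, 1)
  expect_equal(k$lambda_f_dot, 0)

  lam <- 1.2
  k2 <- kinematics_from_F(diag(c(lam, lam^-0.5, lam^-0.5)), c(1, 0, 0))
  expect_equal(k2$J, 1, tolerance = 1e-12)
  expect_equal(k2$lambda_f, 1.2, tolerance = 1e-12)

  # pure dilation leaves the isochoric measures at their reference values
  k3 <- kinematics_from_F(2 * diag(3), c(0, 1, 0))
  expect_equal(k3$J, 8, tolerance = 1e-12)
  expect_equal(k3$I_tilde_C, 3, tolerance = 1e-12)
  expect_equal(k3$lambda_f, 1, tolerance = 1e-12)

  expect_error(kinematics_from_F(-diag(3), c(1, 0, 0)), "singular")
  expect_error(kinematics_from_F(diag(3), c(1, 1, 0)), "unit")
})

test_that("Hill branch functions match their closed forms and stay continuous", {
  p <- muscle_params()
  expect_equal(f_PE(1.0, p), 0)
  expect_equal(f_PE(0.9, p), 0)
  expect_equal(f_PE(1.1, p),
               2 * p$a * p$A * exp(p$a * 0.01) * 0.1, tolerance = 1e-12)
  # positive and increasing above slack length
  lf <- seq(1.01, 1.4, by = 0.01)
  expect_true(all(diff(f_PE(lf, p)) > 0))

  expect_equal(f_LCE(1.0), 1)
  expect_equal(f_LCE(1.5), 0)
  expect_equal(f_LCE(0.5), 0)
  expect_equal(f_LCE(1.25), 0.75)
  expect_true(all(f_LCE(seq(0, 2, by = 0.01)) >= 0))

  expect_equal(f_VCE(-12), 0)
  expect_equal(f_VCE(0), 1)
  expect_equal(f_VCE(2), pi / (4 * atan(5)) + 1, tolerance = 1e-12)
  # continuity at every branch point
  eps <- 1e-9
  expect_lt(abs(f_VCE(2 - eps) - f_VCE(2 + eps)), 1e-8)
  expect_lt(abs(f_VCE(-10 - eps) - f_VCE(-10 + eps)), 1e-8)
  expect_lt(abs(f_PE(1 - eps, p) - f_PE(1 + eps, p)), 1e-8)
  expect_lt(abs(f_LCE(0.5 - eps) - f_LCE(0.5 + eps)), 1e-8)
  expect_lt(abs(f_LCE(1.5 - eps) - f_LCE(1.5 + eps)), 1e-8)
  # monotone and bounded force-velocity relation
  rates <- seq(-15, 5, by = 0.05)
  fv <- f_VCE(rates)
  expect_true(all(diff(fv) >= 0))
  expect_true(all(fv >= 0 & fv <= pi / (4 * atan(5)) + 1))
})

test_that("fiber mixture stress reduces to the single-population form", {
  p <- muscle_params(mu_SO = 0.42, mu_FG = 0.58)
  kin <- kinematics_from_F(diag(3), c(1, 0, 0))
  expect_equal(fiber_nominal_stress(kin, activation_pair(0), p), 0)

  # isometric single-type activation: T = T0M * alpha
  p1 <- muscle_params(mu_SO = 0, mu_FG = 1)
  expect_equal(fiber_nominal_stress(kin, activation_pair(0, 0.91), p1),
               0.535 * 0.91, tolerance = 1e-12)

  # equal activations: mixture identical to a single population
  for (rep in 1:5) {
    kin <- random_kin_state()
    al <- runif(1)
    mix <- fiber_nominal_stress(kin, activation_pair(al, al), p)
    single <- p$T0M * (f_PE(kin$lambda_f, p) +
                         f_LCE(kin$lambda_f) * f_VCE(kin$lambda_f_dot) * al)
    expect_equal(mix, single, tolerance = 1e-14)
  }
})

test_that("strain energy vanishes at reference and matches closed forms", {
  p <- muscle_params()
  kin <- kinematics_from_F(diag(3), c(1, 0, 0))
  expect_equal(muscle_strain_energy(kin, activation_pair(0), p), 0)

  # isotropic-matrix term at I~_C = 3.1 (isochoric biaxial-like state)
  # solve lam with lam^2 + 2/lam = 3.1 along the fiber-neutral axis
  g <- function(l) l^2 + 2 / l - 3.1
  lam <- uniroot(g, c(1, 1.5), tol = 1e-14)$root
  kin2 <- kinematics_from_F(diag(c(lam^-0.5, lam, lam^-0.5)), c(1, 0, 0))
  u_i <- p$c * (exp(p$b * 0.1) - 1)
  # fiber term also active (lambda_f = lam^-0.5 < 1 contributes nothing)
  expect_equal(muscle_strain_energy(kin2, activation_pair(0), p), u_i,
               tolerance = 1e-6)

  # passive fiber energy in closed form
  kin3 <- kinematics_from_F(diag(c(1.1, 1.1^-0.5, 1.1^-0.5)), c(1, 0, 0))
  u_pe <- p$T0M * p$A * (exp(p$a * 0.01) - 1)
  u_i3 <- p$c * (exp(p$b * (1.1^2 + 2 / 1.1 - 3)) - 1)
  expect_equal(muscle_strain_energy(kin3, activation_pair(0), p),
               u_pe + u_i3, tolerance = 1e-10)
  expect_equal(u_pe, 6.066e-5, tolerance = 1e-3)
})

test_that("second Piola-Kirchhoff stress is the energy gradient", {
  p <- muscle_params()
  # stress-free rest state at the rest multiplier
  kin <- kinematics_from_F(diag(3), c(1, 0, 0))
  S0 <- muscle_second_pk(kin, activation_pair(0), p, multiplier = -1)
  expect_equal(S0, matrix(0, 3, 3))

  set.seed(42)
  for (rep in 1:20) {
    kin <- random_kin_state()
    act <- activation_pair(runif(1), runif(1))
    mult <- runif(1, -2, 1)
    S <- muscle_second_pk(kin, act, p, mult)
    expect_equal(S, t(S))
    Sfd <- fd_stress_oracle(kin$E, act, p, mult, kin$N_m, kin$lambda_f_dot)
    expect_lt(max(abs(S - Sfd)) / max(abs(S)), 1e-5)
  }
})

test_that("stress is objective: superposed rotations leave S unchanged", {
  set.seed(7)
  p <- muscle_params()
  for (rep in 1:10) {
    kin <- random_kin_state()
    act <- activation_pair(runif(1))
    S <- muscle_second_pk(kin, act, p, -1)
    # random rotation via QR of a random matrix
    qr_ <- qr(matrix(rnorm(9), 3))
    R <- qr.Q(qr_)
    if (det(R) < 0) R[, 1] <- -R[, 1]
    kin_rot <- kinematics_from_F(R %*% kin$F, kin$N_m)
    kin_rot$lambda_f_dot <- kin$lambda_f_dot
    S_rot <- muscle_second_pk(kin_rot, act, p, -1)
    expect_lt(max(abs(S - S_rot)), 1e-11)
  }
})

test_that("St. Venant-Kirchhoff stress is linear with the printed moduli", {
  bone <- bone_params()
  expect_equal(stvk_second_pk(matrix(0, 3, 3), bone), matrix(0, 3, 3))
  S <- stvk_second_pk(diag(c(0.01, 0, 0)), bone)
  expect_equal(diag(S), c(215.39, 92.31, 92.31), tolerance = 1e-10)
  E1 <- matrix(rnorm(9), 3); E1 <- (E1 + t(E1)) / 2
  E2 <- matrix(rnorm(9), 3); E2 <- (E2 + t(E2)) / 2
  expect_equal(stvk_second_pk(E1 + E2, bone),
               stvk_second_pk(E1, bone) + stvk_second_pk(E2, bone),
               tolerance = 1e-9)
})

test_that("material tangent matches closed forms and is symmetric", {
  bone <- bone_params()
  D <- material_tangent(list(E = matrix(0, 3, 3)), bone)
  lam <- bone$lame_lambda; mu <- bone$lame_mu
  D_exact <- lam * outer(c(1, 1, 1, 0, 0, 0), c(1, 1, 1, 0, 0, 0)) +
    2 * mu * diag(c(1, 1, 1, 0.5, 0.5, 0.5))
  expect_equal(D, D_exact, tolerance = 1e-6)

  kin <- kinematics_from_F(diag(3), c(1, 0, 0))
  Dm <- material_tangent(kin, muscle_params(), activation_pair(0),
                         multiplier = -1)
  expect_lt(max(abs(Dm - t(Dm))) / max(abs(Dm)), 1e-6)
})
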