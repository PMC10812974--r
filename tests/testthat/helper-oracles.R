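# Shared oracles and fixtures. The finite-difference energy oracle and the
# one-dimensional uniaxial oracle are independent of the implementation
# paths they check.

# Central finite difference of the total energy (strain energy plus
# multiplier * constraint) with respect to the Green-Lagrange strain, in
# tensor components; the fiber stretch rate is frozen at `rate`.
fd_stress_oracle <- function(E0, act, params, multiplier, N_m, rate,
                             h = 1e-6) {
  voigt <- cbind(i = c(1, 2, 3, 1, 2, 1), j = c(1, 2, 3, 2, 3, 3))
  energy <- function(E) {
    C <- 2 * E + diag(3)
    F <- chol(C)
    kin <- kinematics_from_F(F, N_m)
    kin$lambda_f_dot <- rate
    muscle_strain_energy(kin, act, params) + multiplier * (kin$J^2 - 1)
  }
  S <- matrix(0, 3, 3)
  for (k in 1:6) {
    i <- voigt[k, 1]; j <- voigt[k, 2]
    dE <- matrix(0, 3, 3)
    if (i == j) dE[i, j] <- h else { dE[i, j] <- h / 2; dE[j, i] <- h / 2 }
    d <- (energy(E0 + dE) - energy(E0 - dE)) / (2 * h)
    S[i, j] <- d; S[j, i] <- d
  }
  S
}

# Random kinematic state with controlled Jacobian, away from the model's
# branch points.
random_kin_state <- function(jmin = 0.95, jmax = 1.05) {
  F <- diag(3) + matrix(runif(9, -0.08, 0.08), 3, 3)
  F <- F * (runif(1, jmin, jmax) / det(F))^(1 / 3)
  N <- runif(3) - 0.5
  N <- N / sqrt(sum(N^2))
  kinematics_from_F(F, N, lambda_f_prev = 1, dt = 0.01)
}

# Closed-form 1D nominal stress of the incompressible uniaxial path
# diag(lambda, lambda^-1/2, lambda^-1/2) with fibers along the load axis.
uniaxial_oracle <- function(lambda, alpha, rate = 0,
                            params = muscle_params()) {
  It <- lambda^2 + 2 / lambda
  params$c * params$b * exp(params$b * (It - 3)) *
    (2 * lambda - 2 / lambda^2) +
    params$T0M * (f_PE(lambda, params) +
                    f_LCE(lambda) * f_VCE(rate) * alpha)
}

# Axis-aligned single-population fiber field for the unit fixtures.
axial_fibers <- function(n) {
  structure(matrix(rep(c(1, 0, 0), n), ncol = 3, byrow = TRUE),
            class = "fiber_field", elements = seq_len(n))
}

# Uniaxial stretch of a unit fixture: prescribe the axial displacement and
# symmetry planes, let the solver find the transverse contraction, return
# the converged state (with the `newton` attribute).
solve_uniaxial <- function(model, mesh, lambda, alpha,
                           n_increments = 5) {
  settings <- solver_settings(dt = 1, tol = 1e-9)
  st <- system_state(model)
  for (f in seq_len(n_increments) / n_increments) {
    lc <- load_case(dirichlet = list(
      list(set = "x0", comps = "x", value = 0),
      list(set = "x1", comps = "x", value = f * (lambda - 1)),
      list(set = "y0", comps = "y", value = 0),
      list(set = "z0", comps = "z", value = 0)))
    st <- newton_solve(model, st, lc, alpha = c(SO = alpha, FG = alpha),
                       settings = settings)
  }
  st
}

# Axial nominal stress of a converged uniaxial state: reaction force per
# unit reference area (the single tet integrates P_xx dN/dx over V = 1/6).
axial_nominal_stress <- function(state, mesh, single_tet = FALSE) {
  f <- sum(attr(state, "newton")$fint[3 * (mesh$sets$x1 - 1) + 1])
  if (single_tet) 6 * f else f
}

# The scenario studies are expensive; run them once per test session at
# the test-scale conditions and share across test files.
study_cache <- new.env(parent = emptyenv())

test_study_config <- function() {
  if (is.null(study_cache$config)) {
    mesh <- make_synthetic_forearm(forearm_params(edge_length = 18))
    study_cache$config <- study_config(mesh = mesh, dt = 0.015, t_end = 1.2)
  }
  study_cache$config
}

cached_study <- function(name) {
  if (is.null(study_cache[[name]])) {
    runner <- switch(name,
                     velocity = run_velocity_study,
                     composition = run_composition_study,
                     strength = run_strength_study,
                     excitation = run_excitation_study)
    study_cache[[name]] <- runner(test_study_config())
  }
  study_cache[[name]]
}
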