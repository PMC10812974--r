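#' Solver settings for the quasi-static Newton solution
#'
#' @param dt Time increment (s), `> 0`.
#' @param tol Relative Newton tolerance on the force residual norm, in
#'   `(0, 1e-2]`.
#' @param tol_J Convergence requirement on the incompressibility constraint:
#'   maximum `|J - 1|` over constrained elements.
#' @param max_iter Maximum Newton iterations per increment (`>= 5`).
#' @param fd_step Displacement perturbation (mm) of the numerical consistent
#'   tangent.
#' @param max_bisect Maximum within-step bisections of the load/activation
#'   increment before a step is declared failed.
#' @param max_step Trust-region cap (mm) on the largest nodal displacement
#'   component of a Newton step; steps are scaled down to this length.
#'   Prevents wild excursions when the tangent of the slack (soft) muscle
#'   underestimates the stiffening response.
#' @param rate_cap Cap (1/s) on the estimated per-iteration change of any
#'   muscle element's fiber stretch rate, active while the muscle is
#'   activated. The force-velocity relation acts as a narrow viscous well
#'   around the current stretch rate (its slope decays away from zero
#'   rate), so Newton iterates that jump far outside it lose the damping
#'   stiffness and diverge; the cap keeps iterates inside the well without
#'   restricting converged increments, whose physical stretch change per
#'   step is far smaller.
#' @param aug_penalty Augmented-Lagrangian penalty coefficient (MPa): the
#'   constraint stress of each muscle element is evaluated with multiplier
#'   `lambda_e + aug_penalty (J^2 - 1)`. The penalty keeps the volumetric
#'   deviation small along the Newton path (so the element-constant
#'   multiplier update stays well behaved) while the multiplier still
#'   enforces the constraint exactly at convergence.
#' @param tangent_reg Step regularization of the multiplier block applied
#'   to the tangent only (per unit constrained volume). It bounds the
#'   checkerboard-mode content of the Newton step without perturbing the
#'   converged solution (the residual is untouched); the Newton rate loss
#'   is of order `tangent_reg x volume / Schur-complement scale`.
#' @param stabilization Perturbed-Lagrangian stabilization coefficient of
#'   the element-constant multiplier space. The P0 multiplier field on
#'   structured tetrahedral meshes carries checkerboard null modes
#'   (linearly dependent constraint gradients); the constraint residual is
#'   regularized to `V_e (J^2 - 1) - stabilization V_e (lambda_e -
#'   lambda_rest)`, which leaves the reference state exact and perturbs
#'   `|J - 1|` only at order `stabilization x pressure`.
#' @return An object of class `solver_settings`.
#' @export
solver_settings <- function(dt = 0.01, tol = 1e-6, tol_J = 1e-5,
                            max_iter = 60, fd_step = 1e-6,
                            max_bisect = 12, max_step = 25,
                            rate_cap = 4, stabilization = 1e-7,
                            tangent_reg = 0, aug_penalty = 50) {
  stopifnot(dt > 0, tol > 0, tol <= 1e-2, max_iter >= 5, fd_step > 0,
            tol_J > 0, max_bisect >= 0, max_step > 0, rate_cap > 0,
            stabilization >= 0, tangent_reg >= 0, aug_penalty >= 0)
  structure(list(dt = dt, tol = tol, tol_J = tol_J, max_iter = max_iter,
                 fd_step = fd_step, max_bisect = max_bisect,
                 max_step = max_step, rate_cap = rate_cap,
                 stabilization = stabilization, tangent_reg = tangent_reg,
                 aug_penalty = aug_penalty),
            class = "solver_settings")
}

#' Boundary conditions and loading of a quasi-static run
#'
#' @param dirichlet List of constraints, each a list with fields `set` (node
#'   set name), `comps` (subset of `"x","y","z"`), and `value` (prescribed
#'   displacement, mm; scalar or one per component).
#' @param loads List of nodal loads, each a list with fields `set` and
#'   `force` (total force vector in N, divided equally over the set).
#' @param schedule `"ramp_with_activation"` (load factor follows
#'   `alpha(t)/alpha_max` of the driving profile) or `"constant"` (full
#'   load held for the whole run, brought in over the short `ramp_in`
#'   window).
#' @param ramp_in Ramp-in time (s) of the `"constant"` schedule. A
#'   quasi-static state cannot jump at `t = 0`, so the constant load is
#'   applied over this window; by its end the activation dynamics have
#'   produced enough muscle tone that the loaded equilibria are
#'   well-behaved.
#' @return An object of class `load_case`.
#' @export
load_case <- function(dirichlet = list(), loads = list(),
                      schedule = c("ramp_with_activation", "constant"),
                      ramp_in = 0.05) {
  schedule <- match.arg(schedule)
  stopifnot(ramp_in >= 0)
  for (d in dirichlet) {
    stopifnot(!is.null(d$set), all(d$comps %in% c("x", "y", "z")))
  }
  structure(list(dirichlet = dirichlet, loads = loads,
                 schedule = schedule, ramp_in = ramp_in),
            class = "load_case")
}

# Resolve a load case against a mesh: fixed dof indices + values, and the
# (full-magnitude) external force vector.
resolve_load_case <- function(mesh, lc) {
  n <- nrow(mesh$nodes)
  comp_id <- c(x = 1L, y = 2L, z = 3L)
  fixed <- integer(0)
  values <- numeric(0)
  for (d in lc$dirichlet) {
    nodes <- mesh_set_nodes(mesh, d$set)
    val <- d$value %||% 0
    if (length(val) == 1) val <- rep(val, length(d$comps))
    for (ci in seq_along(d$comps)) {
      dofs <- 3 * (nodes - 1) + comp_id[[d$comps[ci]]]
      fixed <- c(fixed, dofs)
      values <- c(values, rep(val[ci], length(dofs)))
    }
  }
  if (anyDuplicated(fixed)) {
    keep <- !duplicated(fixed)
    fixed <- fixed[keep]; values <- values[keep]
  }
  fext <- numeric(3 * n)
  for (ld in lc$loads) {
    nodes <- mesh_set_nodes(mesh, ld$set)
    for (k in 1:3) {
      # loaded components must not also be constrained
      if (ld$force[k] != 0 && any((3 * (nodes - 1) + k) %in% fixed))
        stop("constrained components must not also be loaded")
    }
    per <- ld$force / length(nodes)
    for (k in 1:3) fext[3 * (nodes - 1) + k] <-
        fext[3 * (nodes - 1) + k] + per[k]
  }
  list(fixed = fixed, values = values, fext = fext)
}

#' Finite-element model: mesh + materials + fibers + constraint layout
#'
#' Precomputes everything the assembly needs: shape-function gradients and
#' volumes of the linear tetrahedra, the per-element material table, fiber
#' directions on the muscle region, and the incompressibility-multiplier
#' layout (one multiplier per muscle element by default, or one per element
#' patch when `constraint = "patch"`, the mean-dilatation locking
#' mitigation).
#'
#' @param mesh A [fem_mesh()].
#' @param materials Named list with entries `muscle` ([muscle_params()]),
#'   `bone` and `tendon` ([elastic_params()]); only regions present in the
#'   mesh are required.
#' @param fibers A [fiber_directions()] field, or `NULL` to solve the
#'   Laplace problem between node sets `muscle_proximal` / `muscle_distal`
#'   when muscle elements are present.
#' @param constraint `"element"` (per-muscle-element multiplier) or
#'   `"patch"` (one multiplier per generator patch of muscle elements).
#' @return An object of class `fem_model`.
#' @export
fem_model <- function(mesh,
                      materials = list(muscle = muscle_params(),
                                       bone = bone_params(),
                                       tendon = tendon_params()),
                      fibers = NULL,
                      constraint = c("element", "patch")) {
  constraint <- match.arg(constraint)
  sg <- shape_gradients(mesh)
  m <- nrow(mesh$elems)
  kind <- ifelse(mesh$region == "muscle", 0L, 1L)
  stvk <- matrix(0, m, 2)
  for (r in c("bone", "tendon")) {
    idx <- mesh$region == r
    if (any(idx)) {
      if (is.null(materials[[r]]))
        stop(sprintf("mesh contains %s elements but no %s material given", r, r))
      stvk[idx, 1] <- materials[[r]]$lame_lambda
      stvk[idx, 2] <- materials[[r]]$lame_mu
    }
  }
  mus <- which(mesh$region == "muscle")
  Nm <- matrix(0, m, 3)
  if (length(mus)) {
    if (is.null(materials$muscle))
      stop("mesh contains muscle elements but no muscle material given")
    if (is.null(fibers)) {
      phi <- solve_laplace(mesh, "muscle_proximal", "muscle_distal")
      fibers <- fiber_directions(mesh, phi)
    }
    if (!identical(attr(fibers, "elements"), mus))
      stop("fiber field does not match the mesh's muscle elements")
    Nm[mus, ] <- unclass(fibers)[, , drop = FALSE]
  }
  lam_id <- rep(-1L, m)
  if (length(mus)) {
    if (constraint == "patch") {
      if (is.null(mesh$elem_patch))
        stop("constraint = 'patch' requires a mesh with elem_patch ids")
      pid <- mesh$elem_patch[mus]
      lam_id[mus] <- as.integer(factor(pid)) - 1L
    } else {
      lam_id[mus] <- seq_along(mus) - 1L
    }
  }
  n_lam <- max(lam_id) + 1L
  V_lam <- numeric(n_lam)
  if (n_lam > 0) {
    con <- lam_id >= 0
    V_lam <- as.numeric(tapply(sg$V[con],
                               factor(lam_id[con], levels = 0:(n_lam - 1)),
                               sum))
  }
  structure(list(mesh = mesh, materials = materials, fibers = fibers,
                 constraint = constraint, G = sg$G, V = sg$V,
                 conn0 = mesh$elems - 1L, kind = kind, stvk = stvk,
                 Nm = Nm, lam_id = lam_id, n_lam = n_lam, V_lam = V_lam,
                 muscle_elems = mus, h_elem = sg$V^(1 / 3)),
            class = "fem_model")
}

#' @export
print.fem_model <- function(x, ...) {
  cat(sprintf("FE model: %d elements (%d muscle), %d displacement dofs, %d incompressibility multipliers (%s)\n",
              nrow(x$mesh$elems), length(x$muscle_elems),
              3 * nrow(x$mesh$nodes), x$n_lam, x$constraint))
  invisible(x)
}

#' System state of a quasi-static increment
#'
#' Nodal displacements, per-constraint Lagrange multipliers (initialized at
#' the rest value `-kappa_vol/2`, which makes the reference state exactly
#' stress-free), the per-element fiber stretch of the previous step, the
#' current time and the activation levels of both fiber populations.
#'
#' @param model A [fem_model()].
#' @return An object of class `fem_state`.
#' @export
system_state <- function(model) {
  kappa <- if (!is.null(model$materials$muscle))
    model$materials$muscle$kappa_vol else 2
  structure(list(u = numeric(3 * nrow(model$mesh$nodes)),
                 lam = rep(-kappa / 2, model$n_lam),
                 lamf_prev = rep(1, nrow(model$mesh$elems)),
                 t = 0, alpha = c(SO = 0, FG = 0)),
            class = "fem_state")
}

muscle_par_vec <- function(model) {
  p <- model$materials$muscle
  if (is.null(p)) p <- muscle_params()
  c(p$c, p$b, p$T0M, p$A, p$a, p$mu_SO, p$mu_FG, p$kappa_vol)
}

#' Assemble the residual and consistent tangent
#'
#' Internal force minus external load on the displacement rows, plus one
#' volume-scaled constraint row `V_e (J_e^2 - 1)` per incompressibility
#' multiplier; the tangent is the numerical consistent tangent (central
#' difference of each element residual) with analytic
#' displacement-multiplier coupling blocks.
#'
#' @param model A [fem_model()].
#' @param state A [system_state()].
#' @param fext External force vector (length 3 x nodes); defaults to zero.
#' @param dt Time increment used for the fiber stretch-rate backward
#'   difference.
#' @param want_tangent Assemble the sparse tangent as well?
#' @param fd_step Tangent perturbation (mm).
#' @param stabilization Multiplier-space stabilization coefficient (see
#'   [solver_settings()]).
#' @param aug_penalty Augmented-Lagrangian penalty on the volumetric
#'   constraint (MPa; see [solver_settings()]).
#' @return List with `residual` (length dofs + multipliers), `tangent`
#'   (sparse, or `NULL`), `J`, `lamf`, `fiber_T` (per element), `fint`.
#' @export
assemble_system <- function(model, state, fext = NULL, dt = 1,
                            want_tangent = TRUE, fd_step = 1e-6,
                            stabilization = 0, tangent_reg = 0,
                            aug_penalty = 0) {
  ndof <- 3 * nrow(model$mesh$nodes)
  if (is.null(fext)) fext <- numeric(ndof)
  res <- fem_assemble_cpp(model$G, model$V, model$conn0, model$kind,
                          model$stvk, model$Nm, state$lamf_prev, dt,
                          state$alpha[["SO"]], state$alpha[["FG"]],
                          c(muscle_par_vec(model), aug_penalty),
                          model$lam_id, state$lam,
                          state$u, fd_step, want_tangent)
  if (res$bad_elem > 0)
    stop(sprintf("inverted element during assembly: element %d has J = %g",
                 res$bad_elem, res$bad_J))
  wres <- res$wres
  if (stabilization > 0 && model$n_lam > 0) {
    kappa <- if (!is.null(model$materials$muscle))
      model$materials$muscle$kappa_vol else 2
    wres <- wres - stabilization * model$V_lam * (state$lam + kappa / 2)
  }
  K <- NULL
  if (want_tangent) {
    ti <- res$ti + 1L; tj <- res$tj + 1L; tx <- res$tx
    if (stabilization + tangent_reg > 0 && model$n_lam > 0) {
      di <- ndof + seq_len(model$n_lam)
      ti <- c(ti, di); tj <- c(tj, di)
      tx <- c(tx, -(stabilization + tangent_reg) * model$V_lam)
    }
    K <- Matrix::sparseMatrix(i = ti, j = tj, x = tx,
                              dims = rep(ndof + model$n_lam, 2))
  }
  list(residual = c(res$fint - fext, wres), tangent = K,
       J = res$J, lamf = res$lamf, fiber_T = res$T, fint = res$fint)
}

# One quasi-static increment at fixed targets. `target` carries alpha
# (c(SO, FG)), fext (full vector) and dirichlet values for the resolved
# `bc`.
#
# Full coupled Newton on (u, lambda) with the augmented-Lagrangian penalty
# regularizing the constraint along the path. Full steps are accepted
# whenever the candidate state assembles (no element inversion): quadratic
# overshoot through the stiff bone rotations is part of the normal Newton
# path here and a monotone line search would stall on it. Steps are halved
# only to avoid inversion and capped by the trust region; lack of progress
# and divergence are caught by the stall counters, upon which the caller
# bisects the load/activation increment.
newton_increment <- function(model, state, target, bc, settings, dt) {
  ndof <- 3 * nrow(model$mesh$nodes)
  state$alpha <- target$alpha
  state$u[bc$fixed] <- target$dir_values
  free_disp <- setdiff(seq_len(ndof), bc$fixed)
  free_all <- c(free_disp, ndof + seq_len(model$n_lam))
  fscale <- max(sqrt(sum(target$fext^2)), 1)
  trace <- numeric(0)
  assemble <- function(st, tangent) tryCatch(
    assemble_system(model, st, target$fext, dt, want_tangent = tangent,
                    fd_step = settings$fd_step,
                    stabilization = settings$stabilization,
                    tangent_reg = settings$tangent_reg,
                    aug_penalty = settings$aug_penalty),
    error = function(e) NULL)
  # constraint deviation: per-element |J - 1| for element-level
  # multipliers (the physical measure; the multiplier residual itself has
  # unobservable checkerboard components), per-multiplier volume-average
  # for patch-level ones
  jdev_of <- function(asm) {
    if (model$n_lam == 0) return(0)
    if (model$constraint == "element")
      max(abs(asm$J[model$muscle_elems] - 1))
    else
      max(abs(asm$residual[ndof + seq_len(model$n_lam)]) / model$V_lam) / 2
  }

  asm <- assemble(state, TRUE)
  if (is.null(asm))
    return(list(converged = FALSE, state = state, trace = trace,
                asm = NULL))
  conv <- FALSE
  # watchdog globalization: run undamped Newton speculatively (quadratic
  # overshoot through the stiff bone rotations recovers in a few
  # iterations), but checkpoint every new best residual; if no progress
  # within a few iterations, restore the checkpoint and switch to a strict
  # monotone backtracking line search (needed for the stiff implicit
  # stretch-rate coupling at small time steps)
  best <- list(state = state, asm = asm, rn = Inf)
  since_best <- 0
  strict <- FALSE
  for (it in seq_len(settings$max_iter)) {
    rn <- sqrt(sum(asm$residual[free_disp]^2))
    jdev <- jdev_of(asm)
    trace <- c(trace, rn)
    if (rn <= settings$tol * fscale && jdev <= settings$tol_J) {
      conv <- TRUE
      break
    }
    if (rn < 0.99 * best$rn) {
      best <- list(state = state, asm = asm, rn = rn)
      since_best <- 0
    } else {
      since_best <- since_best + 1
      if (!strict && (since_best > 6 || rn > 1e5 * (best$rn + fscale))) {
        state <- best$state
        asm <- best$asm
        strict <- TRUE
        since_best <- 0
        next
      }
      if (strict && since_best > 25) break
    }
    r <- asm$residual[free_all]
    K <- asm$tangent[free_all, free_all, drop = FALSE]
    du <- tryCatch(as.numeric(Matrix::solve(K, -r)),
                   error = function(e) NULL)
    if (is.null(du) || any(!is.finite(du))) break
    full <- numeric(ndof + model$n_lam)
    full[free_all] <- du
    biggest <- max(abs(full[seq_len(ndof)]))
    if (biggest > settings$max_step)
      full <- full * (settings$max_step / biggest)
    rn_all <- sqrt(sum(r^2))
    # cap on the per-iterate fiber-stretch excursion: the force-velocity
    # relation is a narrow viscous well around the current stretch rate,
    # and iterates that jump far outside it lose the damping stiffness and
    # diverge; rigid motions of the muscle (which dominate the passive
    # droop phase) change lambda_f little and pass at full step
    lf_cap <- if (length(model$muscle_elems) && max(target$alpha) > 1e-3)
      max(settings$rate_cap * dt, 5e-3) else Inf
    mus <- model$muscle_elems
    step <- 1
    accepted <- NULL
    asm2 <- NULL
    for (ls in 1:12) {
      cand <- state
      cand$u <- state$u + step * full[seq_len(ndof)]
      cand$lam <- state$lam + step * full[ndof + seq_len(model$n_lam)]
      asm2 <- assemble(cand, TRUE)
      if (!is.null(asm2)) {
        ok_rate <- !is.finite(lf_cap) ||
          max(abs(asm2$lamf[mus] - asm$lamf[mus])) <= lf_cap
        if (ok_rate) {
          if (!strict) { accepted <- cand; break }
          rn2 <- sqrt(sum(asm2$residual[free_all]^2))
          if (rn2 <= rn_all * (1 - 1e-4 * step)) { accepted <- cand; break }
        }
      }
      step <- step / 2
    }
    if (is.null(accepted)) break   # inverted everywhere / no descent
    state <- accepted
    asm <- asm2
  }
  list(converged = conv, state = state, trace = trace, asm = asm)
}

#' Quasi-static Newton solve at fixed activation and load
#'
#' Solves the discrete equilibrium (internal force = external load, plus the
#' per-element incompressibility constraints) by a damped Newton method with
#' Dirichlet row/column elimination. On success the multiplier field is
#' updated and the fiber-stretch history is rolled forward.
#'
#' @param model A [fem_model()].
#' @param state Starting [system_state()].
#' @param lc A [load_case()].
#' @param alpha Activation levels `c(SO = , FG = )`.
#' @param load_factor Scale applied to the load case's nodal forces.
#' @param settings A [solver_settings()].
#' @param roll_history Update `lamf_prev` and advance `t` by `dt` on
#'   success (the per-step bookkeeping of [time_march()]).
#' @return The converged state, with attribute `newton` (iteration trace).
#'   Non-convergence raises a condition of class `musclefem_newton_failure`
#'   carrying the trace, which enables load-step bisection by the caller.
#' @export
newton_solve <- function(model, state, lc, alpha = c(SO = 0, FG = 0),
                         load_factor = 1, settings = solver_settings(),
                         roll_history = TRUE) {
  bc <- resolve_load_case(model$mesh, lc)
  target <- list(alpha = alpha, fext = bc$fext * load_factor,
                 dir_values = bc$values)
  out <- newton_increment(model, state, target, bc, settings, settings$dt)
  if (!out$converged) {
    cond <- structure(class = c("musclefem_newton_failure", "error",
                                "condition"),
                      list(message = sprintf(
                        "Newton failed to converge in %d iterations (residuals: %s)",
                        settings$max_iter,
                        paste(signif(out$trace, 3), collapse = " -> ")),
                        call = sys.call(), trace = out$trace))
    stop(cond)
  }
  st <- out$state
  if (roll_history) {
    st$lamf_prev <- out$asm$lamf
    st$t <- state$t + settings$dt
  }
  attr(st, "newton") <- list(iterations = length(out$trace),
                             residuals = out$trace,
                             J = out$asm$J, lamf = out$asm$lamf,
                             fiber_T = out$asm$fiber_T,
                             fint = out$asm$fint)
  st
}

#' March a load/activation schedule through time
#'
#' Sequential quasi-static solves at `t_n = n dt`. The activation of each
#' fiber population follows its profile; the external load follows the load
#' case schedule (`ramp_with_activation` scales the load with
#' `alpha(t)/alpha_ss` of the driving profile, `constant` applies the full
#' load from the first increment). The fiber stretch rate is the backward
#' difference over the time step. If an increment does not converge, the
#' load/activation increment is bisected (continuation between the last
#' converged targets and the step targets, up to `max_bisect` splits) before
#' the step is declared failed.
#'
#' @param model A [fem_model()].
#' @param lc A [load_case()].
#' @param profiles Either one [activation_profile()] applied to both fiber
#'   populations, or a list `list(SO = , FG = )`.
#' @param t_end End time (s).
#' @param settings A [solver_settings()] (supplies `dt`).
#' @param state Optional starting state.
#' @param t_start Time of the starting state (s); steps run at
#'   `t_start + n dt`. Used to continue a previous march.
#' @param record_stress Record per-element fiber stress at every step?
#' @return An object of class `fem_history`: times, activation levels, load
#'   factors, displacement snapshots, per-step incompressibility deviation
#'   `max|J-1|`, fiber stretch summaries, and Newton iteration counts.
#' @export
time_march <- function(model, lc, profiles, t_end,
                       settings = solver_settings(), state = NULL,
                       t_start = 0, record_stress = FALSE) {
  if (inherits(profiles, "activation_profile"))
    profiles <- list(SO = profiles, FG = profiles)
  stopifnot(all(c("SO", "FG") %in% names(profiles)))
  if (is.null(state)) state <- system_state(model)
  bc <- resolve_load_case(model$mesh, lc)
  dt <- settings$dt
  nstep <- max(1L, as.integer(round((t_end - t_start) / dt)))
  alpha_ref <- max(activation_steady_state(profiles$SO),
                   activation_steady_state(profiles$FG))
  load_factor_at <- function(t) switch(
    lc$schedule,
    ramp_with_activation = min(max(activation_value(t, profiles$SO),
                                   activation_value(t, profiles$FG)) /
                                 max(alpha_ref, 1e-12), 1),
    constant = if (lc$ramp_in > 0) min(t / lc$ramp_in, 1) else 1)

  times <- numeric(nstep)
  aSO <- aFG <- lfac <- jdev <- iters <- numeric(nstep)
  lamf_mean <- numeric(nstep)
  u_steps <- vector("list", nstep)
  stress <- if (record_stress)
    matrix(0, nstep, length(model$muscle_elems)) else NULL

  prev_target <- if (t_start > 0) list(
    alpha = c(SO = activation_value(t_start, profiles$SO),
              FG = activation_value(t_start, profiles$FG)),
    fext = bc$fext * load_factor_at(t_start),
    dir_values = bc$values)
  else list(alpha = state$alpha, fext = numeric(length(bc$fext)),
            dir_values = bc$values * 0)
  mus <- model$muscle_elems

  for (n in seq_len(nstep)) {
    t_n <- t_start + n * dt
    a_SO <- activation_value(t_n, profiles$SO)
    a_FG <- activation_value(t_n, profiles$FG)
    lf <- load_factor_at(t_n)
    target <- list(alpha = c(SO = a_SO, FG = a_FG),
                   fext = bc$fext * lf, dir_values = bc$values)

    # continuation: advance from the last converged targets to the step
    # targets, adaptively bisecting the increment on Newton failure and
    # re-doubling after success
    mix <- function(a, b, s) a + s * (b - a)
    s_lo <- 0
    level <- 0           # current halving depth: span = 2^-level
    st <- state
    substeps <- 0
    repeat {
      s_hi <- min(1, s_lo + 2^(-level))
      tgt <- list(alpha = c(SO = mix(prev_target$alpha[["SO"]],
                                     target$alpha[["SO"]], s_hi),
                            FG = mix(prev_target$alpha[["FG"]],
                                     target$alpha[["FG"]], s_hi)),
                  fext = mix(prev_target$fext, target$fext, s_hi),
                  dir_values = mix(prev_target$dir_values,
                                   target$dir_values, s_hi))
      out <- tryCatch(newton_increment(model, st, tgt, bc, settings, dt),
                      error = function(e) list(converged = FALSE,
                                               trace = numeric(0)))
      substeps <- substeps + 1
      if (out$converged) {
        st <- out$state
        s_lo <- s_hi
        if (s_lo >= 1) break
        level <- max(0, level - 1)
      } else {
        level <- level + 1
        if (level > settings$max_bisect || substeps > 4 * 2^settings$max_bisect)
          stop(sprintf("time step %d (t = %.4g s) failed to converge after bisecting the increment %d times",
                       n, t_n, settings$max_bisect))
      }
    }
    state <- st
    state$t <- t_n
    state$lamf_prev <- out$asm$lamf
    prev_target <- target

    times[n] <- t_n
    aSO[n] <- a_SO; aFG[n] <- a_FG; lfac[n] <- lf
    iters[n] <- length(out$trace)
    jdev[n] <- if (length(mus)) max(abs(out$asm$J[mus] - 1)) else 0
    lamf_mean[n] <- if (length(mus)) mean(out$asm$lamf[mus]) else 1
    u_steps[[n]] <- state$u
    if (record_stress) stress[n, ] <- out$asm$fiber_T[mus]
  }
  structure(list(times = times, alpha_SO = aSO, alpha_FG = aFG,
                 load_factor = lfac, u = u_steps, max_J_dev = jdev,
                 lamf_mean = lamf_mean, newton_iters = iters,
                 fiber_stress = stress, model = model,
                 final_state = state),
            class = "fem_history")
}

#' @export
print.fem_history <- function(x, ...) {
  cat(sprintf("quasi-static history: %d steps to t = %g s; max |J-1| = %.2e; mean Newton iterations %.1f\n",
              length(x$times), max(x$times), max(x$max_J_dev),
              mean(x$newton_iters)))
  invisible(x)
}
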