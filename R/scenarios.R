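#' Elbow flexion angle from two markers on the radius axis
#'
#' The flexion angle is the signed angle between the current and reference
#' orientation of the radius axis (pin marker to load-end marker), projected
#' onto the sagittal x-z plane; positive when the load end moves upward
#' (+z). Exact on rigid rotations about the mediolateral (y) axis.
#'
#' @param ref 2 x 3 matrix of reference marker coordinates (rows: pin node,
#'   load-end marker).
#' @param cur 2 x 3 matrix of current marker coordinates.
#' @return Angle in degrees.
#' @export
elbow_flexion_angle <- function(ref, cur) {
  vr <- ref[2, ] - ref[1, ]
  vc <- cur[2, ] - cur[1, ]
  if (sqrt(sum(vr^2)) < 1e-12 || sqrt(sum(vc^2)) < 1e-12)
    stop("markers must be non-coincident")
  # sagittal projection: components (x, z)
  a <- c(vr[1], vr[3]); b <- c(vc[1], vc[3])
  atan2(a[1] * b[2] - a[2] * b[1], a[1] * b[1] + a[2] * b[2]) * 180 / pi
}

#' Scenario configuration
#'
#' Collects everything a study runner needs: the mesh (or the generator
#' parameters to build it), material overrides, the solver time step and
#' window, the load magnitude, and the incompressibility constraint layout.
#'
#' @param mesh A [fem_mesh()] from [make_synthetic_forearm()], or `NULL` to
#'   generate one from `geometry`.
#' @param geometry A [forearm_params()] used when `mesh` is `NULL`.
#' @param materials Material list as in [fem_model()].
#' @param dt Time step (s).
#' @param t_end End time (s) of the constant-load (sarcopenia) studies.
#' @param max_load Peak vertical load at the distal radius (N).
#' @param constraint Incompressibility layout, `"patch"` (default for the
#'   forearm studies: one multiplier per generator hex patch, the
#'   mean-dilatation mitigation of the degenerate per-element P0 space) or
#'   `"element"`.
#' @param aug_penalty Augmented-Lagrangian penalty (MPa) of the early
#'   transient (robust setting).
#' @param aug_penalty_late Penalty after `penalty_switch_t`, tightening the
#'   per-element volumetric deviation through the stressed part of the
#'   trajectory.
#' @param penalty_switch_t Time (s) at which the penalty is raised.
#' @param ramp_in Load ramp-in window (s) of the constant-load studies
#'   (see [load_case()]); long enough that activation tone has developed
#'   by the time the full load is carried, including at the lowest
#'   excitation levels swept.
#' @param output_dir Optional directory for per-case CSV exports.
#' @return An object of class `study_config`.
#' @export
study_config <- function(mesh = NULL, geometry = forearm_params(),
                         materials = list(muscle = muscle_params(),
                                          bone = bone_params(),
                                          tendon = tendon_params()),
                         dt = 0.01, t_end = 1.5, max_load = 100,
                         constraint = "patch", aug_penalty = 2000,
                         aug_penalty_late = 8000,
                         penalty_switch_t = 0.15,
                         ramp_in = 0.2, output_dir = NULL) {
  stopifnot(dt > 0, t_end > dt, max_load >= 0, ramp_in >= 0,
            aug_penalty >= 0, aug_penalty_late >= 0, penalty_switch_t >= 0)
  structure(list(mesh = mesh, geometry = geometry, materials = materials,
                 dt = dt, t_end = t_end, max_load = max_load,
                 constraint = constraint, aug_penalty = aug_penalty,
                 aug_penalty_late = aug_penalty_late,
                 penalty_switch_t = penalty_switch_t,
                 ramp_in = ramp_in, output_dir = output_dir),
            class = "study_config")
}

config_mesh <- function(config) {
  if (is.null(config$mesh)) make_synthetic_forearm(config$geometry)
  else config$mesh
}

forearm_boundary_conditions <- function(schedule) {
  load_case(
    dirichlet = list(
      list(set = "tendon_proximal_fixed", comps = c("x", "y", "z"), value = 0),
      list(set = "radius_proximal_pin", comps = c("x", "y", "z"), value = 0),
      list(set = "radius_y_restrained", comps = "y", value = 0)),
    loads = list(list(set = "radius_load", force = c(0, 0, -1))),
    schedule = schedule)
}

scale_loads <- function(lc, max_load) {
  lc$loads[[1]]$force <- c(0, 0, -max_load)
  lc
}

# Trajectory of the elbow flexion angle from a time-march history.
flexion_trajectory_from_history <- function(hist, mesh) {
  fa <- attr(mesh, "forearm")
  pin <- fa$pin_node
  loadn <- fa$load_nodes
  ref <- rbind(mesh$nodes[pin, ],
               colMeans(mesh$nodes[loadn, , drop = FALSE]))
  ang <- vapply(hist$u, function(u) {
    U <- matrix(u, ncol = 3, byrow = TRUE)
    cur <- rbind(mesh$nodes[pin, ] + U[pin, ],
                 colMeans(mesh$nodes[loadn, , drop = FALSE] +
                            U[loadn, , drop = FALSE]))
    elbow_flexion_angle(ref, cur)
  }, 1)
  df <- data.frame(t = c(0, hist$times),
                   alpha_SO = c(0, hist$alpha_SO),
                   alpha_FG = c(0, hist$alpha_FG),
                   load_factor = c(0, hist$load_factor),
                   angle = c(0, ang))
  onset <- df$t[which(df$angle > 1)[1]]
  structure(df, class = c("flexion_trajectory", "data.frame"),
            peak = max(df$angle), onset = if (is.na(onset)) Inf else onset,
            max_J_dev = max(hist$max_J_dev))
}

#' @export
print.flexion_trajectory <- function(x, ...) {
  cat(sprintf("flexion trajectory: %d steps to t = %g s; peak angle %.2f deg; onset %.3g s; max |J-1| = %.1e\n",
              nrow(x) - 1, max(x$t), attr(x, "peak"), attr(x, "onset"),
              attr(x, "max_J_dev")))
  invisible(x)
}

#' @export
plot.flexion_trajectory <- function(x, ...) {
  plot(x$t, x$angle, type = "l", xlab = "time [s]",
       ylab = "elbow flexion angle [deg]", ...)
  invisible(x)
}

# March a flexion case with a staged augmented-Lagrangian penalty: the
# early transient (load ramp-in, weak muscle tone) runs at the robust
# `aug_penalty`; once past `penalty_switch_t` the run continues at
# `aug_penalty_late`, which tightens the per-element volumetric deviation
# through the stressed part of the trajectory. The converged mixed
# solution does not depend on the penalty; only the constraint accuracy
# along the path does.
run_flexion_case <- function(model, mesh, lc, profiles, t_end, dt,
                             state = NULL, aug_penalty = 2000,
                             aug_penalty_late = aug_penalty,
                             penalty_switch_t = 0.15) {
  t_switch <- round(penalty_switch_t / dt) * dt
  if (aug_penalty_late <= aug_penalty || t_end <= t_switch + dt / 2) {
    hist <- time_march(model, lc, profiles, t_end,
                       settings = solver_settings(
                         dt = dt, aug_penalty = aug_penalty),
                       state = state)
    return(flexion_trajectory_from_history(hist, mesh))
  }
  h1 <- time_march(model, lc, profiles, t_switch,
                   settings = solver_settings(dt = dt,
                                              aug_penalty = aug_penalty),
                   state = state)
  h2 <- time_march(model, lc, profiles, t_end,
                   settings = solver_settings(
                     dt = dt, aug_penalty = aug_penalty_late),
                   state = h1$final_state, t_start = t_switch)
  flexion_trajectory_from_history(merge_histories(h1, h2), mesh)
}

merge_histories <- function(h1, h2) {
  structure(list(times = c(h1$times, h2$times),
                 alpha_SO = c(h1$alpha_SO, h2$alpha_SO),
                 alpha_FG = c(h1$alpha_FG, h2$alpha_FG),
                 load_factor = c(h1$load_factor, h2$load_factor),
                 u = c(h1$u, h2$u),
                 max_J_dev = c(h1$max_J_dev, h2$max_J_dev),
                 lamf_mean = c(h1$lamf_mean, h2$lamf_mean),
                 newton_iters = c(h1$newton_iters, h2$newton_iters),
                 fiber_stress = NULL, model = h1$model,
                 final_state = h2$final_state),
            class = "fem_history")
}

# Equilibrium under the full constant load with zero activation (the
# passive droop). Solved once per study and reused as the warm start of
# every case's first increment: the first-step solution is identical, only
# the Newton path to it is shortened.
passive_droop <- function(model, lc, dt, aug_penalty = 2000) {
  h <- time_march(model, lc, activation_profile("ode", u = 0),
                  t_end = dt,
                  settings = solver_settings(dt = dt,
                                             aug_penalty = aug_penalty))
  st <- h$final_state
  st$t <- 0
  st
}

finish_study <- function(id, param_name, values, trajectories, config,
                         per10 = 10) {
  peaks <- vapply(trajectories, attr, 1, "peak")
  onsets <- vapply(trajectories, attr, 1, "onset")
  fit <- if (length(values) >= 3) stats::lm(peaks ~ values) else NULL
  res <- structure(list(id = id, param_name = param_name, values = values,
                        trajectories = trajectories, peaks = peaks,
                        onsets = onsets,
                        slope_per_10 = if (!is.null(fit))
                          unname(coef(fit)[2]) * per10 else NA_real_,
                        r_squared = if (!is.null(fit))
                          summary(fit)$r.squared else NA_real_,
                        max_J_dev = max(vapply(trajectories, attr, 1,
                                               "max_J_dev"))),
                   class = "flexion_study")
  if (!is.null(config$output_dir)) export_study(res, config$output_dir)
  res
}

#' @export
print.flexion_study <- function(x, ...) {
  cat(sprintf("study '%s': swept %s over {%s}\n", x$id, x$param_name,
              paste(signif(x$values, 4), collapse = ", ")))
  cat(sprintf("  peak angles [deg]: %s\n",
              paste(sprintf("%.2f", x$peaks), collapse = ", ")))
  if (is.finite(x$slope_per_10))
    cat(sprintf("  OLS slope per 10%%: %.3f deg (R^2 = %.4f)\n",
                x$slope_per_10, x$r_squared))
  cat(sprintf("  max |J-1| across runs: %.2e\n", x$max_J_dev))
  invisible(x)
}

#' @export
summary.flexion_study <- function(object, ...) {
  data.frame(study = object$id, parameter = object$param_name,
             value = object$values, peak_angle = object$peaks,
             onset = object$onsets)
}

#' @export
plot.flexion_study <- function(x, ...) {
  plot(x$values, x$peaks, xlab = x$param_name,
       ylab = "peak flexion angle [deg]", pch = 19, ...)
  if (is.finite(x$slope_per_10))
    abline(stats::lm(x$peaks ~ x$values), lty = 2)
  invisible(x)
}

export_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(study$trajectories)) {
    utils::write.csv(as.data.frame(study$trajectories[[i]]),
                     file.path(dir, sprintf("%s_case%02d.csv", study$id, i)),
                     row.names = FALSE)
  }
  utils::write.csv(summary(study),
                   file.path(dir, sprintf("%s_summary.csv", study$id)),
                   row.names = FALSE)
  invisible(study)
}

#' Contraction-velocity study
#'
#' Reproduces the contraction-velocity experiment on the synthetic forearm:
#' linearly ramped activation to `alpha_max = 0.91` with ramp durations 0.05
#' (fast), 0.20 (medium) and 1.00 s (slow); the distal load ramps with the
#' activation to `max_load` and each case runs to its own activation peak
#' (the angle at the end of the ramp is the case's peak flexion). Slower
#' ramps flex further because rapid shortening suppresses the fiber force
#' through the force-velocity relation.
#'
#' @param config A [study_config()].
#' @return A `flexion_study` with one trajectory per ramp duration.
#' @export
run_velocity_study <- function(config = study_config()) {
  mesh <- config_mesh(config)
  model <- fem_model(mesh, config$materials, constraint = config$constraint)
  t_peaks <- c(fast = 0.05, medium = 0.20, slow = 1.00)
  lc <- scale_loads(forearm_boundary_conditions("ramp_with_activation"),
                    config$max_load)
  # the activation-proportional load schedule provides muscle tone from
  # the first increment on, so these runs start at a stiffer penalty; all
  # three cases share one level, falling back together if any case fails
  ladder <- sort(unique(pmax(c(8000, 5000, config$aug_penalty),
                             config$aug_penalty)), decreasing = TRUE)
  traj <- NULL
  for (rho in ladder) {
    traj <- tryCatch(lapply(t_peaks, function(tp) {
      prof <- activation_profile("linear_ramp", t_peak = tp,
                                 alpha_max = 0.91)
      run_flexion_case(model, mesh, lc, prof, t_end = tp, dt = tp / 50,
                       aug_penalty = rho,
                       aug_penalty_late = config$aug_penalty_late %||%
                         config$aug_penalty,
                       penalty_switch_t = config$penalty_switch_t %||%
                         0.15)
    }), error = function(e) NULL)
    if (!is.null(traj)) break
  }
  if (is.null(traj))
    stop("velocity study failed to converge at every penalty level")
  finish_study("velocity", "t_peak", unname(t_peaks), traj, config)
}

fiber_profiles <- function(params) {
  list(SO = activation_profile("ode", u = params$u,
                               tau_rise = params$tau_rise_SO,
                               tau_fall = params$tau_fall_SO,
                               alpha_min = params$alpha_min),
       FG = activation_profile("ode", u = params$u,
                               tau_rise = params$tau_rise_FG,
                               tau_fall = params$tau_fall_FG,
                               alpha_min = params$alpha_min))
}

# Run a full sweep of sarcopenia cases at one shared late-penalty level,
# falling back to softer levels if any case fails: all cases of a sweep
# must share their numerics, or penalty-dependent offsets distort the
# cross-case comparison.
run_sweep_cases <- function(config, mesh, muscles) {
  ladder <- sort(unique(pmax(c(config$aug_penalty_late %||% 0, 8000, 5000,
                               config$aug_penalty),
                             config$aug_penalty)), decreasing = TRUE)
  for (rho in ladder) {
    cfg2 <- config
    cfg2$aug_penalty_late <- rho
    res <- tryCatch(lapply(muscles, function(m)
      run_sarcopenia_case(cfg2, mesh, m)), error = function(e) NULL)
    if (!is.null(res)) return(res)
  }
  stop("sweep failed to converge at every penalty level")
}

# The sarcopenia sweeps share their baseline (young) condition; runs are
# memoized per session on the full case signature so shared cases are
# solved once. Results are deterministic, so the cache is transparent.
.case_cache <- new.env(parent = emptyenv())

run_sarcopenia_case <- function(config, mesh, muscle, warm = NULL) {
  key <- paste(
    digest_signature(list(muscle, config$dt, config$t_end, config$max_load,
                          config$constraint, config$aug_penalty,
                          config$aug_penalty_late %||% 0,
                          config$penalty_switch_t %||% 0,
                          config$ramp_in %||% 0.05,
                          dim(mesh$nodes), dim(mesh$elems),
                          sum(mesh$nodes), sum(mesh$elems))),
    collapse = "|")
  hit <- .case_cache[[key]]
  if (!is.null(hit)) return(hit)
  materials <- config$materials
  materials$muscle <- muscle
  model <- fem_model(mesh, materials, constraint = config$constraint)
  lc <- scale_loads(forearm_boundary_conditions("constant"),
                    config$max_load)
  lc$ramp_in <- config$ramp_in %||% 0.05
  res <- run_flexion_case(model, mesh, lc, fiber_profiles(muscle),
                          t_end = config$t_end, dt = config$dt,
                          state = warm,
                          aug_penalty = config$aug_penalty,
                          aug_penalty_late = config$aug_penalty_late %||%
                            config$aug_penalty,
                          penalty_switch_t = config$penalty_switch_t %||%
                            0.15)
  .case_cache[[key]] <- res
  res
}

digest_signature <- function(x) {
  # stable plain-text signature of a nested list of numerics
  paste(vapply(rapply(x, function(v) paste(format(v, digits = 15),
                                           collapse = ","),
                      how = "unlist"), identity, ""), collapse = ";")
}

# Shared passive warm start for a sweep of sarcopenia cases on one mesh.
sarcopenia_warm_start <- function(config, mesh, muscle) {
  materials <- config$materials
  materials$muscle <- muscle
  model <- fem_model(mesh, materials, constraint = config$constraint)
  lc <- scale_loads(forearm_boundary_conditions("constant"),
                    config$max_load)
  passive_droop(model, lc, config$dt, config$aug_penalty)
}

#' Fiber-composition (aging) study
#'
#' Sweeps the fast-twitch cross-sectional fraction over the young (58%),
#' elderly I (51%) and elderly II (44%) compositions under a constant
#' distal load, with excitation-driven activation dynamics per fiber type.
#' Reports the OLS slope of peak angle per 10 percentage points of
#' fast-twitch fraction and the fit R^2.
#'
#' @param config A [study_config()].
#' @return A `flexion_study`.
#' @export
run_composition_study <- function(config = study_config()) {
  mesh <- config_mesh(config)
  fast_pct <- c(young = 58, elderly_I = 51, elderly_II = 44)
  base <- config$materials$muscle %||% muscle_params()
  muscles <- lapply(fast_pct, function(pct)
    muscle_params(c = base$c, b = base$b, T0M = base$T0M,
                  A = base$A, a = base$a, alpha_min = base$alpha_min,
                  mu_SO = 1 - pct / 100, mu_FG = pct / 100,
                  tau_rise_SO = base$tau_rise_SO,
                  tau_fall_SO = base$tau_fall_SO,
                  tau_rise_FG = base$tau_rise_FG,
                  tau_fall_FG = base$tau_fall_FG,
                  u = base$u, kappa_vol = base$kappa_vol))
  traj <- run_sweep_cases(config, mesh, muscles)
  finish_study("composition", "fast_twitch_pct", unname(fast_pct), traj,
               config)
}

#' Maximum-muscle-stress (strength decline) study
#'
#' Scales the maximum nominal fiber stress from 100% down to 70% in 10%
#' steps (young composition otherwise) under constant load. The peak angle
#' decreases nearly linearly with the scale.
#'
#' @param config A [study_config()].
#' @return A `flexion_study`.
#' @export
run_strength_study <- function(config = study_config()) {
  mesh <- config_mesh(config)
  scales <- c(1.0, 0.9, 0.8, 0.7)
  base <- config$materials$muscle %||% muscle_params()
  muscles <- lapply(scales, function(s) {
    mus <- base
    mus$T0M <- base$T0M * s
    mus
  })
  traj <- run_sweep_cases(config, mesh, muscles)
  finish_study("strength", "T0M_scale_pct", 100 * scales, traj, config)
}

#' Neural-excitation (neurological dysfunction) study
#'
#' Sweeps the neural excitation u over 0.5 ... 0.1 in steps of 0.1 under
#' constant load. The steady-state activation saturates in u, so peak angle
#' falls slowly per 0.1 of u above u = 0.2 and sharply below it; the study
#' reports both slopes and their ratio (the excitation threshold effect).
#'
#' @param config A [study_config()].
#' @return A `flexion_study` with extra fields `slope_below`, `slope_above`
#'   (degrees per 0.1 of u below/above the 0.2 threshold).
#' @export
run_excitation_study <- function(config = study_config()) {
  mesh <- config_mesh(config)
  us <- c(0.5, 0.4, 0.3, 0.2, 0.1)
  base <- config$materials$muscle %||% muscle_params()
  muscles <- lapply(us, function(uu) {
    mus <- base
    mus$u <- uu
    mus
  })
  traj <- run_sweep_cases(config, mesh, muscles)
  res <- finish_study("excitation", "u", us, traj, config, per10 = 1)
  peaks <- res$peaks
  above <- us >= 0.2
  res$slope_above <- unname(coef(stats::lm(peaks[above] ~ us[above]))[2]) * 0.1
  res$slope_below <- (peaks[us == 0.2] - peaks[us == 0.1]) / 0.1 * 0.1
  res
}

#' Uniaxial validation against the one-dimensional oracle
#'
#' Validates the finite-element implementation on homogeneous states:
#' passive uniaxial stretch (lambda in `[1, 1.3]`) and isometric activation
#' (alpha up to 0.91) of a single tetrahedron and a six-tetrahedron unit
#' cube, with the transverse contraction resolved by the solver under the
#' incompressibility constraint. The FE nominal stress (axial reaction per
#' reference area) is compared with the closed-form 1D stress on the
#' incompressible path `diag(lambda, lambda^-1/2, lambda^-1/2)`:
#' `P = c b exp(b(I~C - 3)) (2 lambda - 2/lambda^2)
#'    + T0M (f_PE + f_LCE f_VCE alpha)`.
#' The run fails (attribute `pass` is `FALSE`) if any relative error
#' exceeds 1%.
#'
#' @param lambdas Passive stretch grid.
#' @param alphas Isometric activation grid.
#' @return Data frame (class `uniaxial_validation`) with one row per case
#'   and columns `fixture`, `mode`, `value`, `fe_stress`, `oracle`,
#'   `rel_error`; attributes `pass` and `max_rel_error`.
#' @export
run_uniaxial_validation <- function(lambdas = seq(1.05, 1.3, by = 0.05),
                                    alphas = c(0.25, 0.5, 0.75, 0.91)) {
  oracle <- function(lam, alpha) {
    p <- muscle_params()
    It <- lam^2 + 2 / lam
    p$c * p$b * exp(p$b * (It - 3)) * (2 * lam - 2 / lam^2) +
      p$T0M * (f_PE(lam, p) + f_LCE(lam) * f_VCE(0) * alpha)
  }
  fixtures <- list(
    single_tet = make_unit_fixture("single_tet"),
    unit_cube = make_unit_fixture("unit_cube", 1))
  rows <- list()
  for (fx in names(fixtures)) {
    mesh <- fixtures[[fx]]
    nmus <- sum(mesh$region == "muscle")
    fib <- structure(matrix(rep(c(1, 0, 0), nmus), ncol = 3, byrow = TRUE),
                     class = "fiber_field", elements = seq_len(nmus))
    model <- fem_model(mesh, fibers = fib)
    settings <- solver_settings(dt = 1, tol = 1e-9)
    x1 <- mesh$sets$x1
    axial_stress <- function(state) {
      # nominal stress = axial reaction over the reference cross-section;
      # for the unit cube the x1 face has unit area, for the single tet the
      # reaction at the apex node integrates P_xx * dN/dx over V = 1/6
      f <- sum(attr(state, "newton")$fint[3 * (x1 - 1) + 1])
      if (fx == "single_tet") 6 * f else f
    }
    stretch_case <- function(lam, alpha) {
      lc <- load_case(dirichlet = list(
        list(set = "x0", comps = "x", value = 0),
        list(set = "x1", comps = "x", value = lam - 1),
        list(set = "y0", comps = "y", value = 0),
        list(set = "z0", comps = "z", value = 0)))
      st <- system_state(model)
      for (f in seq(0.2, 1, by = 0.2)) {
        lcf <- lc
        lcf$dirichlet[[2]]$value <- f * (lam - 1)
        st <- newton_solve(model, st, lcf, alpha = c(SO = alpha, FG = alpha),
                           settings = settings)
      }
      axial_stress(st)
    }
    for (lam in lambdas)
      rows[[length(rows) + 1]] <- data.frame(
        fixture = fx, mode = "passive_stretch", value = lam,
        fe_stress = stretch_case(lam, 0), oracle = oracle(lam, 0))
    for (al in alphas)
      rows[[length(rows) + 1]] <- data.frame(
        fixture = fx, mode = "isometric_activation", value = al,
        fe_stress = stretch_case(1, al), oracle = oracle(1, al))
  }
  rep <- do.call(rbind, rows)
  rep$rel_error <- abs(rep$fe_stress - rep$oracle) / pmax(abs(rep$oracle),
                                                          1e-12)
  maxerr <- max(rep$rel_error)
  structure(rep, class = c("uniaxial_validation", "data.frame"),
            pass = maxerr <= 0.01, max_rel_error = maxerr)
}

#' @export
print.uniaxial_validation <- function(x, ...) {
  cat(sprintf("uniaxial validation: %d cases, max relative error %.3g -> %s\n",
              nrow(x), attr(x, "max_rel_error"),
              if (attr(x, "pass")) "PASS" else "FAIL"))
  invisible(x)
}
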