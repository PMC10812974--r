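#' Per-point kinematics from a deformation gradient
#'
#' Computes the kinematic quantities the constitutive model consumes at one
#' material point: the right Cauchy-Green tensor `C = F'F`, Green-Lagrange
#' strain `E = (C - I)/2`, Jacobian `J = det F`, the reduced (isochoric)
#' first invariant `I_tilde_C = J^(-2/3) tr C`, the isochoric fiber stretch
#' `lambda_f = sqrt(J^(-2/3) N'CN)` along the reference fiber direction, and
#' its rate by first-order backward difference over the time increment.
#'
#' @param F 3x3 deformation gradient with `det(F) > 0`.
#' @param N_m Unit reference fiber direction (length-3 vector).
#' @param lambda_f_prev Fiber stretch at the previous time step (for the
#'   backward-difference rate). Defaults to the reference value 1.
#' @param dt Time increment (s), `> 0`.
#' @param element Optional element identifier used in error messages.
#' @return An object of class `kin_point` with fields `F`, `J`, `C`, `E`,
#'   `I_tilde_C`, `lambda_f`, `lambda_f_dot`, `N_m`.
#' @examples
#' k <- kinematics_from_F(diag(3), c(1, 0, 0))
#' k$J; k$lambda_f
#' @export
kinematics_from_F <- function(F, N_m, lambda_f_prev = 1, dt = 1,
                              element = NULL) {
  F <- matrix(as.numeric(F), 3, 3)
  N_m <- as.numeric(N_m)
  stopifnot(length(N_m) == 3, dt > 0)
  if (abs(sqrt(sum(N_m^2)) - 1) > 1e-12)
    stop("fiber direction N_m must be a unit vector")
  J <- det(F)
  if (!is.finite(J) || J <= 0) {
    where <- if (is.null(element)) "" else sprintf(" in element %s", element)
    stop(sprintf("singular deformation%s: det(F) = %g is not positive",
                 where, J))
  }
  C <- crossprod(F)                      # F'F
  E <- (C - diag(3)) / 2
  Jm23 <- J^(-2 / 3)
  I_tilde_C <- Jm23 * sum(diag(C))
  lambda_f <- sqrt(Jm23 * drop(crossprod(N_m, C %*% N_m)))
  structure(list(F = F, J = J, C = C, E = E, I_tilde_C = I_tilde_C,
                 lambda_f = lambda_f,
                 lambda_f_dot = (lambda_f - lambda_f_prev) / dt,
                 N_m = N_m),
            class = "kin_point")
}

#' @export
print.kin_point <- function(x, ...) {
  cat(sprintf(
    "material-point kinematics: J = %.6g, I~_C = %.6g, lambda_f = %.6g, d(lambda_f)/dt = %.4g 1/s\n",
    x$J, x$I_tilde_C, x$lambda_f, x$lambda_f_dot))
  invisible(x)
}

#' Passive fiber stress function
#'
#' Dimensionless passive branch of the Hill model,
#' `f_PE = 2 a A exp(a (lambda_f - 1)^2) (lambda_f - 1)` for stretches above
#' 1 and zero otherwise (slack fibers carry no passive load). The nominal
#' passive stress is `T0M * f_PE`.
#'
#' @param lambda_f Fiber stretch ratio(s), `> 0`. Vectorized.
#' @param params A [muscle_params()] object (supplies `a`, `A`).
#' @return Numeric vector of the same length as `lambda_f`.
#' @export
f_PE <- function(lambda_f, params = muscle_params()) {
  d <- lambda_f - 1
  ifelse(d > 0, 2 * params$a * params$A * exp(params$a * d^2) * d, 0)
}

#' Active force-length function
#'
#' Dimensionless parabola `-4 (lambda_f - 1)^2 + 1` on the working range
#' `[0.5, 1.5]` of fiber stretch, zero outside; maximal (1) at optimal
#' length `lambda_f = 1`.
#'
#' @param lambda_f Fiber stretch ratio(s). Vectorized.
#' @return Values in `[0, 1]`.
#' @export
f_LCE <- function(lambda_f) {
  v <- -4 * (lambda_f - 1)^2 + 1
  ifelse(lambda_f >= 0.5 & lambda_f <= 1.5, pmax(v, 0), 0)
}

#' Active force-velocity function
#'
#' Dimensionless force-velocity relation of the contractile element as a
#' function of the fiber stretch rate (negative during shortening): zero at
#' and below -10 1/s (force collapses at maximal shortening velocity),
#' `-(1/atan 5) atan(-0.5 rate) + 1` between -10 and 2 1/s, and the
#' eccentric plateau `pi/(4 atan 5) + 1` above 2 1/s. Continuous and
#' non-decreasing.
#'
#' @param lambda_f_dot Fiber stretch rate(s), 1/s. Vectorized.
#' @return Values in `[0, pi/(4 atan 5) + 1]`.
#' @export
f_VCE <- function(lambda_f_dot) {
  mid <- -(1 / atan(5)) * atan(-0.5 * lambda_f_dot) + 1
  ifelse(lambda_f_dot <= -10, 0,
         ifelse(lambda_f_dot > 2, pi / (4 * atan(5)) + 1, mid))
}

#' Nominal fiber stress of the fiber mixture
#'
#' Total nominal (first Piola-Kirchhoff, 1D) stress along the fiber
#' direction, mixing slow- and fast-twitch populations by cross-sectional
#' area fraction:
#' `T = T0M * [ mu_SO (f_PE + f_LCE f_VCE alpha_SO)
#'            + mu_FG (f_PE + f_LCE f_VCE alpha_FG) ]` (MPa).
#' With equal activations this reduces to the single-population form
#' `T0M (f_PE + f_LCE f_VCE alpha)`.
#'
#' @param kin A [kinematics_from_F()] point (uses `lambda_f`,
#'   `lambda_f_dot`).
#' @param act An [activation_pair()].
#' @param params A [muscle_params()] object.
#' @return Nominal stress in MPa.
#' @export
fiber_nominal_stress <- function(kin, act, params = muscle_params()) {
  fp <- f_PE(kin$lambda_f, params)
  fl <- f_LCE(kin$lambda_f)
  fv <- f_VCE(kin$lambda_f_dot)
  params$T0M * (params$mu_SO * (fp + fl * fv * act$alpha_SO) +
                params$mu_FG * (fp + fl * fv * act$alpha_FG))
}

# Closed-form passive fiber energy T0M * A * (exp(a (lf-1)^2) - 1), lf > 1.
u_pe_closed <- function(lambda_f, params) {
  d <- pmax(lambda_f - 1, 0)
  params$T0M * params$A * (exp(params$a * d^2) - 1)
}

# Contractile-element energy: alpha T0M f_VCE * integral of f_LCE from 1 to
# lambda_f, f_VCE frozen at the current rate. Adaptive quadrature; signed
# (negative for shortening below the optimal length).
u_ce_quadrature <- function(lambda_f, lambda_f_dot, alpha_eff, params) {
  if (alpha_eff == 0 || lambda_f == 1) return(0)
  fv <- f_VCE(lambda_f_dot)
  if (fv == 0) return(0)
  q <- stats::integrate(f_LCE, lower = 1, upper = lambda_f,
                        rel.tol = 1e-10, abs.tol = 1e-13)
  alpha_eff * params$T0M * fv * q$value
}

#' Strain energy density of muscle
#'
#' Strain energy per unit reference volume (MPa):
#' `U = kappa_vol (J - 1) + c (exp(b (I_tilde_C - 3)) - 1) + U_PE + U_CE`,
#' where `U_PE` is the closed-form integral of the passive fiber stress and
#' `U_CE` integrates the force-length curve over fiber stretch with the
#' force-velocity factor frozen at the current stretch rate (the rate enters
#' parametrically, not variationally). Zero in the reference state.
#'
#' @inheritParams fiber_nominal_stress
#' @return Energy density in MPa.
#' @export
muscle_strain_energy <- function(kin, act, params = muscle_params()) {
  alpha_eff <- params$mu_SO * act$alpha_SO + params$mu_FG * act$alpha_FG
  params$kappa_vol * (kin$J - 1) +
    params$c * (exp(params$b * (kin$I_tilde_C - 3)) - 1) +
    u_pe_closed(kin$lambda_f, params) +
    u_ce_quadrature(kin$lambda_f, kin$lambda_f_dot, alpha_eff, params)
}

#' Second Piola-Kirchhoff stress of muscle
#'
#' Evaluates the stress tensor of the incompressible, transversely isotropic
#' hyperelastic muscle model (MPa):
#' \deqn{S = \kappa J C^{-1}
#'   + 2bc\,e^{b(\tilde I_C - 3)}\left(J^{-2/3} I
#'       - \tfrac{1}{3}\tilde I_C C^{-1}\right)
#'   + T \left(J^{-2/3}\lambda_f^{-1} N \otimes N
#'       - \tfrac{1}{3}\lambda_f C^{-1}\right)
#'   + \lambda\, 2 J^2 C^{-1}}
#' where `T` is the nominal fiber stress ([fiber_nominal_stress()]), kappa is
#' the volumetric coefficient (default 2), and the last term is the
#' contribution of the incompressibility constraint `W = J^2 - 1` with
#' Lagrange multiplier `lambda` (`multiplier`). The stress is the exact
#' derivative of [muscle_strain_energy()] `+ multiplier * W` with respect to
#' the Green-Lagrange strain, with the force-velocity factor frozen.
#'
#' At the reference state the volumetric term `kappa I` is balanced by the
#' constraint term when `multiplier = -kappa_vol/2` (the rest-state
#' multiplier), giving `S = 0`.
#'
#' @inheritParams fiber_nominal_stress
#' @param multiplier Lagrange multiplier of the incompressibility constraint.
#' @return Symmetric 3x3 stress tensor (MPa).
#' @export
muscle_second_pk <- function(kin, act, params = muscle_params(),
                             multiplier = -params$kappa_vol / 2) {
  C <- kin$C
  rc <- rcond(C)
  if (!is.finite(rc) || rc < 1e-14)
    stop("degenerate element: right Cauchy-Green tensor is singular")
  Cinv <- solve(C)
  Cinv <- (Cinv + t(Cinv)) / 2
  J <- kin$J
  Jm23 <- J^(-2 / 3)
  I3 <- diag(3)
  S_vol <- params$kappa_vol * J * Cinv
  S_iso <- 2 * params$b * params$c * exp(params$b * (kin$I_tilde_C - 3)) *
    (Jm23 * I3 - kin$I_tilde_C / 3 * Cinv)
  Tn <- fiber_nominal_stress(kin, act, params)
  NN <- tcrossprod(kin$N_m)
  S_fib <- Tn * (Jm23 / kin$lambda_f * NN - kin$lambda_f / 3 * Cinv)
  S_con <- multiplier * 2 * J^2 * Cinv
  S <- S_vol + S_iso + S_fib + S_con
  (S + t(S)) / 2
}

#' Second Piola-Kirchhoff stress of an isotropic elastic solid
#'
#' St. Venant-Kirchhoff law `S = lambda tr(E) I + 2 mu E`, used for bone and
#' tendon. Linear in the Green-Lagrange strain, hence objective under large
#' rotations.
#'
#' @param E Symmetric 3x3 Green-Lagrange strain tensor.
#' @param params An [elastic_params()] object.
#' @return Symmetric 3x3 stress tensor (MPa).
#' @export
stvk_second_pk <- function(E, params) {
  E <- (E + t(E)) / 2
  params$lame_lambda * sum(diag(E)) * diag(3) + 2 * params$lame_mu * E
}

# Voigt ordering used throughout: (11, 22, 33, 12, 23, 13), engineering
# shear strains (gamma = 2 E_ij), single stress components.
voigt_index <- cbind(i = c(1, 2, 3, 1, 2, 1), j = c(1, 2, 3, 2, 3, 3))

tensor_to_voigt_stress <- function(S) S[cbind(voigt_index[, 1], voigt_index[, 2])]

# Evaluate the stress (Voigt, 6-vector) at a perturbed Green-Lagrange
# strain, rebuilding kinematics from C' = 2E' + I via Cholesky and freezing
# the fiber stretch rate at `rate`.
stress_at_E <- function(E, material, act, multiplier, N_m, rate) {
  C <- 2 * E + diag(3)
  if (inherits(material, "elastic_params"))
    return(tensor_to_voigt_stress(stvk_second_pk(E, material)))
  F <- chol(C)                        # any F with F'F = C works: S = S(C)
  kin <- kinematics_from_F(F, N_m)
  kin$lambda_f_dot <- rate
  tensor_to_voigt_stress(muscle_second_pk(kin, act, material, multiplier))
}

#' Material tangent stiffness by central differences
#'
#' Consistent tangent `dS/dE` in Voigt notation (6x6, engineering shear
#' strains), computed by central finite differences of the stress with the
#' force-velocity factor frozen within the perturbation. For the St.
#' Venant-Kirchhoff law this reproduces the closed-form tangent
#' `lambda I (x) I + 2 mu II` to difference-scheme accuracy.
#'
#' @param kin A [kinematics_from_F()] point (for muscle) or a list with
#'   field `E` (for bone/tendon).
#' @param material A [muscle_params()] or [elastic_params()] object.
#' @param act An [activation_pair()]; required for muscle.
#' @param multiplier Incompressibility multiplier (muscle only).
#' @param h Strain perturbation of the central difference scheme.
#' @return 6x6 minor-symmetric Voigt tangent (MPa).
#' @export
material_tangent <- function(kin, material, act = activation_pair(0),
                             multiplier = 0, h = 1e-7) {
  E0 <- kin$E
  N_m <- if (!is.null(kin$N_m)) kin$N_m else c(1, 0, 0)
  rate <- if (!is.null(kin$lambda_f_dot)) kin$lambda_f_dot else 0
  D <- matrix(0, 6, 6)
  for (k in 1:6) {
    i <- voigt_index[k, 1]; j <- voigt_index[k, 2]
    dE <- matrix(0, 3, 3)
    # engineering shear: unit Voigt strain = h/2 on each off-diagonal entry
    if (i == j) dE[i, j] <- h else { dE[i, j] <- h / 2; dE[j, i] <- h / 2 }
    Sp <- stress_at_E(E0 + dE, material, act, multiplier, N_m, rate)
    Sm <- stress_at_E(E0 - dE, material, act, multiplier, N_m, rate)
    D[, k] <- (Sp - Sm) / (2 * h)
  }
  D
}
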