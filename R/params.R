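#' Constitutive parameters of skeletal muscle
#'
#' Collects all constants of the incompressible, transversely isotropic
#' hyperelastic muscle model: the exponential isotropic matrix (Humphrey
#' form), the Hill-type fiber stress (passive exponential branch, active
#' force-length and force-velocity branches), the first-order activation
#' dynamics, and the fast-/slow-twitch fiber mixture.
#'
#' Units are MPa for stresses and moduli, seconds for time constants, and
#' dimensionless otherwise. The defaults are the literature values used
#' throughout the package: matrix `c = 3.795e-4` MPa, `b = 23.46`; maximum
#' nominal fiber stress `T0M = 0.535` MPa; passive fiber constants
#' `A = 8.568e-4`, `a = 12.43`; activation time constants 0.1/1.0 s
#' (fast-twitch) and 0.3/3.0 s (slow-twitch); neural excitation `u = 0.5`;
#' and a young-adult fiber mixture of 58% fast-twitch cross-sectional area.
#'
#' @param c Matrix stiffness coefficient (MPa), `> 0`.
#' @param b Matrix exponent (dimensionless), `> 0`.
#' @param T0M Maximum nominal fiber stress (MPa), `> 0`.
#' @param A Passive-fiber coefficient (dimensionless), `> 0`.
#' @param a Passive-fiber exponent (dimensionless), `> 0`.
#' @param alpha_min Minimum activation level in `[0, 1)`. The activation
#'   dynamics never decay below this floor.
#' @param mu_SO,mu_FG Cross-sectional area fractions of slow- and fast-twitch
#'   fibers; must sum to 1.
#' @param tau_rise_SO,tau_fall_SO Slow-twitch activation rise/fall time
#'   constants (s).
#' @param tau_rise_FG,tau_fall_FG Fast-twitch activation rise/fall time
#'   constants (s).
#' @param u Neural excitation, dimensionless in `[0, 0.5]`.
#' @param kappa_vol Coefficient of the volumetric energy term
#'   `kappa_vol * (J - 1)` (MPa). The multiplier of the incompressibility
#'   constraint balances its stress at the reference state (rest multiplier
#'   `-kappa_vol/2`).
#' @return An object of class `muscle_params`.
#' @seealso [elastic_params()], [fiber_nominal_stress()], [muscle_second_pk()]
#' @examples
#' p <- muscle_params()
#' p$T0M
#' @export
muscle_params <- function(c = 3.795e-4, b = 23.46, T0M = 0.535,
                          A = 8.568e-4, a = 12.43, alpha_min = 0,
                          mu_SO = 0.42, mu_FG = 0.58,
                          tau_rise_SO = 0.3, tau_fall_SO = 3.0,
                          tau_rise_FG = 0.1, tau_fall_FG = 1.0,
                          u = 0.5, kappa_vol = 2) {
  stopifnot(is.numeric(c), c > 0, is.numeric(b), b > 0,
            is.numeric(T0M), T0M > 0, is.numeric(A), A > 0,
            is.numeric(a), a > 0)
  if (alpha_min < 0 || alpha_min >= 1)
    stop("alpha_min must be in [0, 1)")
  if (mu_SO < 0 || mu_SO > 1 || mu_FG < 0 || mu_FG > 1)
    stop("fiber fractions mu_SO, mu_FG must be in [0, 1]")
  if (abs(mu_SO + mu_FG - 1) > 1e-12)
    stop("fiber fractions must satisfy mu_SO + mu_FG = 1")
  taus <- c(tau_rise_SO, tau_fall_SO, tau_rise_FG, tau_fall_FG)
  if (any(taus <= 0)) stop("all activation time constants must be positive")
  if (u < 0 || u > 0.5) stop("neural excitation u must be in [0, 0.5]")
  structure(list(c = c, b = b, T0M = T0M, A = A, a = a,
                 alpha_min = alpha_min, mu_SO = mu_SO, mu_FG = mu_FG,
                 tau_rise_SO = tau_rise_SO, tau_fall_SO = tau_fall_SO,
                 tau_rise_FG = tau_rise_FG, tau_fall_FG = tau_fall_FG,
                 u = u, kappa_vol = kappa_vol),
            class = "muscle_params")
}

#' @export
print.muscle_params <- function(x, ...) {
  cat("Hill-type muscle parameters\n")
  cat(sprintf("  matrix: c = %g MPa, b = %g\n", x$c, x$b))
  cat(sprintf("  fiber:  T0M = %g MPa, A = %g, a = %g\n", x$T0M, x$A, x$a))
  cat(sprintf("  mixture: %.0f%% slow / %.0f%% fast twitch\n",
              100 * x$mu_SO, 100 * x$mu_FG))
  cat(sprintf("  activation: u = %g, tau(SO) = %g/%g s, tau(FG) = %g/%g s\n",
              x$u, x$tau_rise_SO, x$tau_fall_SO,
              x$tau_rise_FG, x$tau_fall_FG))
  invisible(x)
}

#' Isotropic (St. Venant-Kirchhoff) elastic parameters
#'
#' Lame parameters of the geometrically nonlinear, materially linear model
#' used for bone and tendon, `S = lambda tr(E) I + 2 mu E`.
#'
#' @param lame_lambda First Lame parameter (MPa), `> 0`.
#' @param lame_mu Shear modulus (MPa), `> 0`.
#' @return An object of class `elastic_params`.
#' @seealso [bone_params()], [tendon_params()], [stvk_second_pk()]
#' @export
elastic_params <- function(lame_lambda, lame_mu) {
  stopifnot(is.numeric(lame_lambda), lame_lambda > 0,
            is.numeric(lame_mu), lame_mu > 0)
  structure(list(lame_lambda = lame_lambda, lame_mu = lame_mu),
            class = "elastic_params")
}

#' @export
print.elastic_params <- function(x, ...) {
  cat(sprintf("St. Venant-Kirchhoff: lambda = %g MPa, mu = %g MPa\n",
              x$lame_lambda, x$lame_mu))
  invisible(x)
}

#' @rdname elastic_params
#' @details `bone_params()` and `tendon_params()` return the cortical-bone
#'   and tendon defaults, (mu, lambda) = (6154, 9231) MPa and (56, 9296) MPa.
#' @export
bone_params <- function() elastic_params(lame_lambda = 9231, lame_mu = 6154)

#' @rdname elastic_params
#' @export
tendon_params <- function() elastic_params(lame_lambda = 9296, lame_mu = 56)

#' Activation levels of the two fiber populations
#'
#' @param alpha_SO,alpha_FG Activation of the slow- and fast-twitch
#'   populations, each in `[0, 1]`. A single-population model is the special
#'   case `alpha_SO == alpha_FG` (or a mixture fraction of 1).
#' @return An object of class `activation_pair`.
#' @export
activation_pair <- function(alpha_SO, alpha_FG = alpha_SO) {
  if (alpha_SO < 0 || alpha_SO > 1 || alpha_FG < 0 || alpha_FG > 1)
    stop("activation levels must be in [0, 1]")
  structure(list(alpha_SO = alpha_SO, alpha_FG = alpha_FG),
            class = "activation_pair")
}
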