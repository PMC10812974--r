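#' Activation profile
#'
#' Describes how the muscle activation level evolves in time. Two kinds are
#' supported: `"ode"`, the closed-form solution of the first-order
#' excitation-driven activation dynamics
#' \deqn{\alpha(t) = \alpha_{ss}\,(1 - e^{-kt}), \quad
#'   k = u/\tau_{rise} + (1-u)/\tau_{fall}, \quad
#'   \alpha_{ss} = \frac{u/\tau_{rise} + \alpha_{min}(1-u)/\tau_{fall}}{k}}
#' started from `alpha = 0` at `t = 0` with constant neural excitation `u`;
#' and `"linear_ramp"`, a piecewise-linear rise to `alpha_max` at `t_peak`
#' used for the contraction-velocity scenarios.
#'
#' @param kind `"ode"` or `"linear_ramp"`.
#' @param u Neural excitation in `[0, 0.5]` (ode kind).
#' @param tau_rise,tau_fall Activation/deactivation time constants (s).
#' @param alpha_min Minimum activation level (floor of the dynamics).
#' @param t_peak Ramp duration to peak (s), `> 0` (ramp kind).
#' @param alpha_max Ramp plateau level in `(0, 1]` (ramp kind).
#' @return An object of class `activation_profile`.
#' @examples
#' p <- activation_profile("ode", u = 0.5, tau_rise = 0.02, tau_fall = 0.2)
#' activation_steady_state(p)   # 0.909...
#' @export
activation_profile <- function(kind = c("ode", "linear_ramp"),
                               u = 0.5, tau_rise = 0.02, tau_fall = 0.2,
                               alpha_min = 0, t_peak = 1, alpha_max = 0.91) {
  kind <- match.arg(kind)
  if (u < 0 || u > 0.5) stop("neural excitation u must be in [0, 0.5]")
  stopifnot(tau_rise > 0, tau_fall > 0, alpha_min >= 0, alpha_min < 1)
  if (kind == "linear_ramp") {
    stopifnot(t_peak > 0)
    if (alpha_max <= 0 || alpha_max > 1)
      stop("alpha_max must be in (0, 1]")
  }
  structure(list(kind = kind, u = u, tau_rise = tau_rise,
                 tau_fall = tau_fall, alpha_min = alpha_min,
                 t_peak = t_peak, alpha_max = alpha_max),
            class = "activation_profile")
}

#' @export
print.activation_profile <- function(x, ...) {
  if (x$kind == "ode")
    cat(sprintf(
      "activation dynamics: u = %g, tau = %g/%g s, steady state %.4f\n",
      x$u, x$tau_rise, x$tau_fall, activation_steady_state(x)))
  else
    cat(sprintf("linear activation ramp: alpha_max = %g at t_peak = %g s\n",
                x$alpha_max, x$t_peak))
  invisible(x)
}

ode_rate_constant <- function(profile) {
  profile$u / profile$tau_rise + (1 - profile$u) / profile$tau_fall
}

#' Steady-state activation level
#'
#' Long-time limit of the activation dynamics,
#' `alpha_ss = (u/tau_rise + alpha_min (1-u)/tau_fall) / k`. With
#' `u = 0.5`, `tau_rise = 0.02` s, `tau_fall = 0.2` s and `alpha_min = 0`
#' this is 10/11 = 0.909..., i.e. 0.91 to two decimals.
#'
#' @param profile An [activation_profile()] of kind `"ode"` (for a ramp the
#'   plateau `alpha_max` is returned).
#' @return Steady-state activation in `[0, 1]`.
#' @export
activation_steady_state <- function(profile) {
  if (profile$kind == "linear_ramp") return(profile$alpha_max)
  k <- ode_rate_constant(profile)
  (profile$u / profile$tau_rise +
     profile$alpha_min * (1 - profile$u) / profile$tau_fall) / k
}

#' Activation level at time t
#'
#' Evaluates the profile: the closed-form exponential approach to the steady
#' state for kind `"ode"`, or the linear ramp for kind `"linear_ramp"`.
#' Monotone non-decreasing in `t` and bounded by the steady state (or ramp
#' plateau).
#'
#' @param t Time(s) in seconds, `>= 0`. Vectorized.
#' @param profile An [activation_profile()].
#' @return Activation level(s) in `[0, 1]`.
#' @export
activation_value <- function(t, profile) {
  if (any(t < 0)) stop("time must be non-negative")
  if (profile$kind == "linear_ramp") return(ramp_value(t, profile))
  ss <- activation_steady_state(profile)
  ss * (1 - exp(-ode_rate_constant(profile) * t))
}

#' Linear activation ramp
#'
#' `alpha(t) = alpha_max * min(t / t_peak, 1)`: linear rise to the plateau
#' at `t_peak`, constant afterwards.
#'
#' @inheritParams activation_value
#' @export
ramp_value <- function(t, profile) {
  if (any(t < 0)) stop("time must be non-negative")
  profile$alpha_max * pmin(t / profile$t_peak, 1)
}
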