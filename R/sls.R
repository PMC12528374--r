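#' Standard Linear Solid substrate parameters
#'
#' The substrate is modelled as a Standard Linear Solid (SLS): an equilibrium
#' spring `k2` in parallel with a Maxwell arm (spring `k1` in series with a
#' dashpot `eta`). The SLS shows instantaneous stiffness `k1 + k2` that
#' relaxes exponentially to the equilibrium stiffness `k2` with time constant
#' `tau = eta / k1`.
#'
#' Stiffnesses are expressed as spring constants in pN/nm, the natural units
#' of a point-like adhesion pulling on its local substrate neighbourhood. As
#' a rule of thumb for the hydrogels this model targets, 1 pN/nm corresponds
#' to roughly 1 kPa of bulk Young's modulus, so a ~0.4 kPa gel maps to a
#' spring constant well below 1 pN/nm and a ~25 kPa gel to ~25 pN/nm.
#'
#' @param k1 Maxwell-arm spring stiffness (pN/nm), `>= 0`.
#' @param k2 parallel equilibrium spring stiffness (pN/nm), `>= 0`.
#' @param eta dashpot viscosity (pN s/nm), `> 0`.
#' @return An object of class `sls_params` with fields `k1`, `k2`, `eta` and
#'   the derived relaxation time `tau` (`eta/k1`, `Inf` when `k1 = 0`).
#' @examples
#' p <- sls_params(k1 = 1, k2 = 1, eta = 1)
#' p$tau
#' @export
sls_params <- function(k1, k2, eta) {
  stopifnot(is.numeric(k1), is.numeric(k2), is.numeric(eta),
            length(k1) == 1L, length(k2) == 1L, length(eta) == 1L)
  if (k1 < 0 || k2 < 0) stop("spring stiffnesses k1, k2 must be >= 0")
  if (!(eta > 0)) stop("dashpot viscosity eta must be > 0")
  structure(
    list(k1 = as.numeric(k1), k2 = as.numeric(k2), eta = as.numeric(eta),
         tau = if (k1 > 0) eta / k1 else Inf),
    class = "sls_params"
  )
}

#' @export
print.sls_params <- function(x, ...) {
  cat(sprintf(
    "SLS substrate: k1 = %g pN/nm, k2 = %g pN/nm, eta = %g pN.s/nm (tau = %g s)\n",
    x$k1, x$k2, x$eta, x$tau))
  invisible(x)
}

#' Substrate deformation state
#'
#' State-space form of the SLS constitutive law: total substrate force is
#' `k2 * x + f_maxwell`, where `x` is the deformation and `f_maxwell` the
#' force currently carried by the Maxwell arm.
#'
#' @param x substrate deformation (nm).
#' @param f_maxwell force carried by the Maxwell arm (pN).
#' @return An object of class `substrate_state`.
#' @export
substrate_state <- function(x = 0, f_maxwell = 0) {
  stopifnot(is.finite(x), is.finite(f_maxwell))
  structure(list(x = as.numeric(x), f_maxwell = as.numeric(f_maxwell)),
            class = "substrate_state")
}

#' Total substrate force for a given state
#'
#' @param params an [sls_params] object.
#' @param state a [substrate_state] object.
#' @return Force in pN (`k2 * x + f_maxwell`).
#' @export
substrate_force <- function(params, state) {
  params$k2 * state$x + state$f_maxwell
}

#' Closed-form stress-relaxation response
#'
#' Force at time `t` after a step displacement `x0` applied at `t = 0` and
#' held: `x0 * (k2 + k1 * exp(-t/tau))`. The response decays monotonically
#' from the instantaneous value `x0*(k1+k2)` to the equilibrium value
#' `x0*k2`.
#'
#' @param params an [sls_params] object.
#' @param x0 step displacement (nm).
#' @param t time since the step (s), `>= 0`; vectorised.
#' @return Force in pN, same length as `t`.
#' @examples
#' relaxation_force(sls_params(1, 1, 1), x0 = 1, t = log(2)) # 1.5
#' @export
relaxation_force <- function(params, x0, t) {
  stopifnot(all(t >= 0))
  if (params$k1 == 0) return(rep(x0 * params$k2, length(t)))
  x0 * (params$k2 + params$k1 * exp(-t / params$tau))
}

#' Storage and loss stiffness of the SLS
#'
#' Frequency-domain response at angular frequency `omega`:
#' storage `k2 + k1*(w*tau)^2 / (1+(w*tau)^2)`, loss
#' `k1*(w*tau) / (1+(w*tau)^2)`. The loss stiffness peaks at
#' `omega = 1/tau` with value `k1/2`; the loss tangent (tan delta) is
#' `loss/storage`.
#'
#' @param params an [sls_params] object.
#' @param omega angular frequency (rad/s), `>= 0`; vectorised.
#' @return A data.frame with columns `omega`, `storage`, `loss`,
#'   `tan_delta` (stiffness analogues of G', G'' in pN/nm).
#' @export
dynamic_moduli <- function(params, omega) {
  stopifnot(all(omega >= 0))
  if (params$k1 == 0) {
    storage <- rep(params$k2, length(omega))
    loss <- rep(0, length(omega))
  } else {
    wt <- omega * params$tau
    storage <- params$k2 + params$k1 * wt^2 / (1 + wt^2)
    loss <- params$k1 * wt / (1 + wt^2)
  }
  data.frame(omega = omega, storage = storage, loss = loss,
             tan_delta = ifelse(storage > 0, loss / storage, NA_real_))
}

# Exponential (exact) Maxwell-arm update coefficients over a step of dt,
# assuming deformation varies linearly within the step:
#   f_m' = a * f_m + c * (x' - x),  a = exp(-dt/tau), c = eta*(1-a)/dt.
# Exact for any dt when x is piecewise linear; reduces to c = k1 as eta -> Inf
# (rigid dashpot) and to a = 1, c = 0 as k1 -> 0 (no Maxwell arm).
.sls_step_coefs <- function(params, dt) {
  if (params$k1 == 0) return(list(a = 1, c = 0))
  a <- exp(-dt / params$tau)
  list(a = a, c = params$eta * (1 - a) / dt)
}

#' Advance the substrate one step under an applied force
#'
#' Integrates the SLS state over `dt` under force control: the end-of-step
#' deformation `x'` solves `k2*x' + f_maxwell' = applied_force`, with the
#' Maxwell-arm force updated by its exact exponential integrator (assuming
#' linear deformation within the step). Under a constant force held for a
#' long time the deformation creeps to `F/k2`; under a held deformation the
#' force decays as [relaxation_force].
#'
#' @param params an [sls_params] object.
#' @param state a [substrate_state] object.
#' @param applied_force applied force at the end of the step (pN).
#' @param dt time step (s); must satisfy `dt <= tau/10` (stability/accuracy
#'   contract of the linear-within-step assumption).
#' @return The new [substrate_state].
#' @export
step_substrate <- function(params, state, applied_force, dt) {
  stopifnot(dt > 0)
  if (dt > params$tau / 10)
    stop("configuration error: dt must be <= tau_relax/10 (dt = ", dt,
         ", tau = ", params$tau, ")")
  co <- .sls_step_coefs(params, dt)
  x_new <- (applied_force - co$a * state$f_maxwell + co$c * state$x) /
    (params$k2 + co$c)
  substrate_state(x = x_new,
                  f_maxwell = co$a * state$f_maxwell + co$c * (x_new - state$x))
}

#' Advance the substrate one step under a prescribed deformation
#'
#' Displacement-controlled counterpart of [step_substrate]: the deformation
#' at the end of the step is imposed and the Maxwell-arm force follows its
#' exact exponential update. Holding `x_new` fixed reproduces the closed-form
#' relaxation response sample by sample.
#'
#' @inheritParams step_substrate
#' @param x_new imposed deformation at the end of the step (nm).
#' @return The new [substrate_state].
#' @export
step_substrate_displacement <- function(params, state, x_new, dt) {
  stopifnot(dt > 0)
  co <- .sls_step_coefs(params, dt)
  substrate_state(x = x_new,
                  f_maxwell = co$a * state$f_maxwell + co$c * (x_new - state$x))
}
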