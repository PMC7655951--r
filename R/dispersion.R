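# Second-order Debye dispersion of the membranes.
#
# Frequency domain: eps(w) = eps_inf + d1/(1+jw t1) + d2/(1+jw t2).
# Time domain, via the polarization vector P = (eps - eps0) E:
#   P + (t1+t2) P' + t1 t2 P'' =
#     (eps_m0-eps0) E + [(eps_m0-d1-eps0) t1 + (eps_m0-d2-eps0) t2] E'
#     + (eps_inf-eps0) t1 t2 E''.
# The integrator does not use this second-order form directly: it carries two
# auxiliary first-order branches  t_k P_k' + P_k = d_k E  plus the
# instantaneous term (eps_inf - eps0) E, whose sum satisfies the same
# equation exactly (factorization of the operator (1 + t1 d/dt)(1 + t2 d/dt)).
# Branches are advanced with the exact exponential solution for a field that
# is linear over the step, which is exact for trapezoidal drives.

#' Complex permittivity of a second-order Debye material
#'
#' @param m A [debye_material()].
#' @param f Frequency (Hz), >= 0; vectorized.
#' @return Complex absolute permittivity (F/m) at each frequency (time
#'   convention `exp(+j w t)`, so the imaginary part is <= 0 for a lossy
#'   medium).
#' @export
complex_permittivity <- function(m, f) {
  stopifnot(inherits(m, "debye_material"), all(f >= 0))
  w <- 2 * pi * f
  m$eps_inf + m$delta_eps_1 / (1 + 1i * w * m$tau_1) +
    m$delta_eps_2 / (1 + 1i * w * m$tau_2)
}

#' Polarization state of a dispersive membrane sample
#'
#' Carries the two relaxation branches `P1`, `P2` and the instantaneous field
#' `E`; the total polarization is
#' `P = (eps_inf - eps0) E + P1 + P2` and satisfies the second-order
#' time-domain dispersion equation.
#'
#' @param n Number of sample locations.
#' @return An object of class `polarization_state` with zero-initialized
#'   fields.
#' @export
polarization_state <- function(n = 1) {
  structure(list(P1 = numeric(n), P2 = numeric(n), E = numeric(n)),
            class = "polarization_state")
}

#' Total polarization of a state
#' @param state A [polarization_state()].
#' @param m The [debye_material()] it belongs to.
#' @return Polarization (C/m^2) per location.
#' @export
total_polarization <- function(state, m) {
  (m$eps_inf - EPS_VACUUM) * state$E + state$P1 + state$P2
}

#' Second time derivative of the polarization (direct second-order form)
#'
#' Solves the printed second-order time-domain dispersion equation for
#' `d2P/dt2` given the current `P`, `dP/dt` and the field drive terms. Used
#' as the reference form; the production integrator uses the algebraically
#' equivalent two-branch factorization (see [step_polarization()]).
#'
#' @param P,dPdt Current polarization and its first derivative.
#' @param E,dEdt,d2Edt2 Field and its first two time derivatives.
#' @param m A [debye_material()].
#' @return `d2P/dt2` (C/m^2/s^2).
#' @export
polarization_derivatives <- function(P, dPdt, E, dEdt, d2Edt2, m) {
  stopifnot(inherits(m, "debye_material"))
  t1 <- m$tau_1; t2 <- m$tau_2
  if (t1 * t2 <= 0) stop("tau_1 * tau_2 must be positive (non-degenerate order)")
  e0 <- EPS_VACUUM
  em0 <- m$eps_inf + m$delta_eps_1 + m$delta_eps_2
  rhs <- (em0 - e0) * E +
    ((em0 - m$delta_eps_1 - e0) * t1 + (em0 - m$delta_eps_2 - e0) * t2) * dEdt +
    (em0 - m$delta_eps_1 - m$delta_eps_2 - e0) * t1 * t2 * d2Edt2
  (rhs - P - (t1 + t2) * dPdt) / (t1 * t2)
}

# Exact one-step branch update for E linear over [0, dt]:
#   tau P' + P = deps E,  E(t) = E0 + (E1-E0) t/dt
# P(dt) = deps (E1 - m tau) + (P0 - deps (E0 - m tau)) exp(-dt/tau)
debye_branch_step <- function(P0, E0, E1, dt, tau, deps) {
  ek <- exp(-dt / tau)
  mm <- (E1 - E0) / dt * tau
  deps * (E1 - mm) + (P0 - deps * (E0 - mm)) * ek
}

# Coefficients expressing the branch update as P1 = a * E1 + h(E0, P0):
#   a = deps (1 - (tau/dt)(1 - e)),  h = deps E0 ((tau/dt)(1 - e) - e) + P0 e
debye_branch_coefs <- function(dt, tau, deps) {
  ek <- exp(-dt / tau)
  w <- tau / dt * (1 - ek)
  list(a = deps * (1 - w), b0 = deps * (w - ek), ek = ek)
}

#' Advance a polarization state one time step
#'
#' Exact exponential update of the two relaxation branches assuming the
#' field varies linearly from `E0` to `E1` across the step (exact for
#' piecewise-linear drives; second-order accurate for smooth drives).
#'
#' @param state A [polarization_state()].
#' @param E0,E1 Field at the beginning and end of the step (V/m), per
#'   location.
#' @param dt Time step (s), > 0.
#' @param m A [debye_material()].
#' @return The advanced `polarization_state`.
#' @export
step_polarization <- function(state, E0, E1, dt, m) {
  stopifnot(inherits(state, "polarization_state"), inherits(m, "debye_material"))
  if (dt <= 0) stop("dt must be > 0")
  state$P1 <- debye_branch_step(state$P1, E0, E1, dt, m$tau_1, m$delta_eps_1)
  state$P2 <- debye_branch_step(state$P2, E0, E1, dt, m$tau_2, m$delta_eps_2)
  state$E <- E1
  state
}

#' Polarization response to an arbitrary sampled field
#'
#' Integrates the membrane dispersion under a given field waveform and
#' returns the total polarization at the sample times. The field is treated
#' as piecewise linear between samples, for which the integration is exact.
#'
#' @param E Field samples (V/m) at times `t`.
#' @param t Strictly increasing sample times (s).
#' @param m A [debye_material()].
#' @return Numeric vector of total polarization (C/m^2) at `t`, starting
#'   from a fully relaxed (zero) state.
#' @export
polarization_response <- function(E, t, m) {
  stopifnot(length(E) == length(t), all(diff(t) > 0))
  st <- polarization_state(1)
  P <- numeric(length(t))
  st$E <- E[1]
  P[1] <- total_polarization(st, m)
  for (i in seq_along(t)[-1]) {
    st <- step_polarization(st, E[i - 1], E[i], t[i] - t[i - 1], m)
    P[i] <- total_polarization(st, m)
  }
  P
}

#' Export a relative-permittivity frequency sweep
#'
#' @param m A [debye_material()].
#' @param path Output file (tab-separated: `f`, `eps_r_real`, `eps_r_imag`).
#' @param fmin,fmax Frequency range (Hz).
#' @param points Number of log-spaced frequencies.
#' @return The sweep as a data frame, invisibly.
#' @export
write_permittivity_sweep <- function(m, path, fmin = 1e4, fmax = 1e11,
                                     points = 200) {
  f <- 10^seq(log10(fmin), log10(fmax), length.out = points)
  eps <- complex_permittivity(m, f) / EPS_VACUUM
  d <- data.frame(f = f, eps_r_real = Re(eps), eps_r_imag = Im(eps))
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(d)
}
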