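# Asymptotic Smoluchowski electroporation of the plasma membrane:
#   dN/dt = alpha exp((1-q) v^2) (exp(q v^2) - N/N0),  v = TMP / V_ep
# and the pore-mediated membrane conductivity
#   sigma_m = sigma_m0 + N pi r_p^2 sigma_p K(v_m),  v_m = F TMP / (R T).

# cap for exponent arguments; beyond this exp() overflows double precision
.EXP_CAP <- 700

#' Pore creation/destruction rate
#'
#' Right-hand side of the asymptotic Smoluchowski pore-density equation.
#'
#' @param N Pore density (m^-2), >= 0; vectorized.
#' @param tmp Transmembrane potential (V); vectorized (recycled with `N`).
#' @param ep An [ep_model()].
#' @return `dN/dt` (m^-2 s^-1).
#' @export
pore_density_rate <- function(N, tmp, ep) {
  stopifnot(inherits(ep, "ep_model"), all(N >= 0))
  v2 <- (tmp / ep$V_ep)^2
  ep$alpha * exp(pmin((1 - ep$q) * v2, .EXP_CAP)) *
    (exp(pmin(ep$q * v2, .EXP_CAP)) - N / ep$N0)
}

#' Equilibrium pore density at a clamped voltage
#'
#' The stationary point of [pore_density_rate()], `N0 * exp(q (tmp/V_ep)^2)`.
#' The exponent is capped just below double-precision overflow; a capped
#' (saturated) result carries the attribute `saturated = TRUE`.
#'
#' @inheritParams pore_density_rate
#' @return Equilibrium pore density (m^-2).
#' @export
equilibrium_pore_density <- function(tmp, ep) {
  stopifnot(inherits(ep, "ep_model"))
  arg <- ep$q * (tmp / ep$V_ep)^2
  cap <- .EXP_CAP - log(ep$N0)  # keep N0 * exp(arg) below double overflow
  out <- ep$N0 * exp(pmin(arg, cap))
  if (any(arg > cap)) attr(out, "saturated") <- TRUE
  out
}

#' Voltage-dependent pore conductance factor K
#'
#' Dimensionless factor scaling the conductance of a single cylindrical
#' pore, with the dimensionless voltage `v_m = F tmp / (R T)`:
#' \deqn{K = \frac{e^{v_m} - 1}{
#'   \frac{w_0 e^{w_0 - n v_m} - n v_m}{w_0 - n v_m} e^{v_m} -
#'   \frac{w_0 e^{w_0 + n v_m} + n v_m}{w_0 + n v_m}}}
#' where `w_0` is the energy barrier inside the pore and `n` the relative
#' entrance length. The removable singularities at `v_m = 0` and
#' `v_m = +/- w_0/n` are handled by analytic limits (series switchover where
#' the offending denominator is below 1e-8 in relative terms).
#'
#' @param tmp Transmembrane potential (V); vectorized.
#' @param ep An [ep_model()].
#' @return Dimensionless `K`, finite and continuous for all `tmp`.
#' @export
pore_conductance_factor <- function(tmp, ep) {
  stopifnot(inherits(ep, "ep_model"))
  vm <- ep$F_const * tmp / (ep$R_gas * ep$T)
  vapply(vm, pore_K_scalar, 0, w0 = ep$w0, n = ep$n_rel)
}

# scalar K(vm); handles the three removable singularities
pore_K_scalar <- function(vm, w0, n) {
  if (abs(vm) < 1e-8) {
    # vm -> 0: numerator and denominator both vanish linearly; take the
    # symmetric average just outside the indeterminate window
    h <- 1e-4
    return((pore_K_scalar(h, w0, n) + pore_K_scalar(-h, w0, n)) / 2)
  }
  (exp(vm) - 1) / pore_K_den(vm, w0, n)
}

# denominator of K, with series treatment of the poles at vm = +/- w0/n
pore_K_den <- function(vm, w0, n) {
  a_den <- w0 - n * vm
  b_den <- w0 + n * vm
  A <- if (abs(a_den) < 1e-8 * w0) {
    # limit of (w0 e^{x} - n vm)/x as x = w0 - n vm -> 0 with n vm -> w0:
    # expand w0 e^{x} - n vm = w0(1 + x + x^2/2 + ...) - (w0 - x)
    #                        = x (1 + w0) + w0 x^2/2 + ...
    (1 + w0) + w0 * a_den / 2
  } else {
    (w0 * exp(w0 - n * vm) - n * vm) / a_den
  }
  B <- if (abs(b_den) < 1e-8 * w0) {
    # mirrored limit at n vm -> -w0
    (1 + w0) + w0 * b_den / 2
  } else {
    (w0 * exp(w0 + n * vm) + n * vm) / b_den
  }
  A * exp(vm) - B
}

#' Membrane conductivity with pores
#'
#' `sigma_m = sigma_m0 + N pi r_p^2 sigma_p K(tmp)`: the intact-membrane
#' conductivity plus the areal pore conductance contribution, applied as a
#' bulk conductivity of the membrane subdomain.
#'
#' @param N Pore density (m^-2), >= 0.
#' @param tmp Transmembrane potential (V).
#' @param ep An [ep_model()].
#' @param sigma_m0 Intact membrane conductivity (S/m).
#' @return Membrane conductivity (S/m).
#' @export
membrane_conductivity <- function(N, tmp, ep, sigma_m0) {
  stopifnot(all(N >= 0))
  sigma_m0 + N * pi * ep$r_p^2 * ep$sigma_p * pore_conductance_factor(tmp, ep)
}

#' Advance the pore density one time step (exponential integrator)
#'
#' For a transmembrane potential frozen over the step the pore-density
#' equation is linear in `N`, `dN/dt = a - b N`, and is advanced exactly:
#' `N(t+dt) = a/b + (N - a/b) exp(-b dt)`. This removes the stability
#' constraint from the stiff creation term.
#'
#' @param N Pore density (m^-2) at the start of the step; vectorized.
#' @param tmp Transmembrane potential (V) over the step; vectorized.
#' @param dt Time step (s).
#' @param ep An [ep_model()].
#' @return Pore density at the end of the step.
#' @export
step_pore_density <- function(N, tmp, dt, ep) {
  v2 <- (tmp / ep$V_ep)^2
  a <- ep$alpha * exp(pmin(v2, .EXP_CAP))             # creation
  b <- ep$alpha / ep$N0 * exp(pmin((1 - ep$q) * v2, .EXP_CAP))  # destruction rate
  bdt <- b * dt
  # N e^{-b dt} + (a/b)(1 - e^{-b dt}); the growth term switches to its
  # a*dt limit where b dt is too small for expm1 to carry it
  growth <- ifelse(bdt > 1e-12, (a / b) * (-expm1(-bdt)), a * dt * (1 - bdt / 2))
  N * exp(-bdt) + growth
}
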