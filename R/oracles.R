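# Closed-form l = 1 (dipole) solutions for concentric layered spheres in a
# uniform field. One core routine serves three purposes:
#   * phasor response of the double-shelled cell (frequency-domain solver),
#   * Laplace-domain response used to build the second-order Schwan
#     transient of the single-shelled cell,
#   * DC conduction reference for mesh verification.
# In every layer the potential is (a r + b / r^2) cos(theta); continuity of
# potential and of the normal complex current density Lambda dphi/dr at each
# interface closes the system. The exterior carries the uniform-field term
# phi = E0 r cos(theta) (so the transmembrane potential at the pole facing
# the positive electrode is positive).

#' Dipole-mode potential coefficients for a layered sphere
#'
#' @param radii Increasing interface radii (m), length `L - 1` for `L`
#'   layers (innermost layer first).
#' @param admittivity Complex admittivity `sigma + j w eps` (or `sigma +
#'   s eps`) per layer, length `L`.
#' @param E0 Uniform far-field amplitude (V/m); the exterior potential is
#'   `E0 r cos(theta)` plus a decaying dipole term.
#' @return A list with complex vectors `a`, `b` (length `L`): potential in
#'   layer `k` is `(a[k] r + b[k]/r^2) cos(theta)`.
#' @keywords internal
layered_sphere_l1 <- function(radii, admittivity, E0 = 1) {
  L <- length(admittivity)
  stopifnot(length(radii) == L - 1, all(diff(radii) > 0), L >= 2)
  # nondimensionalize: radii in units of the outer radius, each flux row in
  # units of its larger admittivity (raw SI scales are 1e-6 m vs 1e10 m^-2
  # and would make the system numerically singular)
  Rs <- radii[L - 1]
  radii <- radii / Rs
  E0 <- E0 * Rs
  n <- 2 * L - 2  # unknowns: a_1, (a_k, b_k) for 1<k<L, b_L
  A <- matrix(0 + 0i, n, n)
  rhs <- complex(n)
  # column index of a_k and b_k in the unknown vector
  ia <- function(k) if (k == 1) 1L else as.integer(2 * k - 2)
  ib <- function(k) if (k == L) as.integer(n) else as.integer(2 * k - 1)  # 1 < k <= L
  row <- 0L
  for (m in seq_len(L - 1)) {
    R <- radii[m]
    lam_in <- admittivity[m]; lam_out <- admittivity[m + 1]
    # potential continuity: a_m R + b_m/R^2 - a_{m+1} R - b_{m+1}/R^2 = 0
    row <- row + 1L
    A[row, ia(m)] <- R
    if (m > 1) A[row, ib(m)] <- 1 / R^2
    if (m + 1 < L) A[row, ia(m + 1)] <- -R else rhs[row] <- E0 * R
    A[row, ib(m + 1)] <- -1 / R^2
    # current continuity: lam_in (a_m - 2 b_m/R^3) = lam_out (a_{m+1} - 2 b_{m+1}/R^3)
    row <- row + 1L
    lsc <- max(Mod(lam_in), Mod(lam_out))
    li <- lam_in / lsc; lo <- lam_out / lsc
    A[row, ia(m)] <- li
    if (m > 1) A[row, ib(m)] <- -2 * li / R^3
    if (m + 1 < L) A[row, ia(m + 1)] <- -lo else rhs[row] <- E0 * lo
    A[row, ib(m + 1)] <- 2 * lo / R^3
  }
  x <- solve(A, rhs)
  a <- complex(L); b <- complex(L)
  a[1] <- x[1]
  if (L > 2) for (k in 2:(L - 1)) { a[k] <- x[ia(k)]; b[k] <- x[ib(k)] }
  a[L] <- E0; b[L] <- x[ib(L)]
  # undo the radius scaling: phi(r) = a' (r/Rs) + b' (Rs/r)^2
  list(a = a / Rs, b = b * Rs^2)
}

# radii and admittivities for the full (possibly double-shelled) cell;
# lam_fun(material) -> complex admittivity. Membrane admittivity passed
# explicitly to allow static vs dispersive choices.
cell_layers <- function(params, lam_e, lam_pm, lam_c, lam_nm, lam_n) {
  g <- params$geometry
  if (g$has_nucleus) {
    list(radii = c(g$nuclear_radius,
                   g$nuclear_radius + g$nuclear_membrane_thickness,
                   g$cell_radius - g$plasma_membrane_thickness,
                   g$cell_radius),
         lam = c(lam_n, lam_nm, lam_c, lam_pm, lam_e),
         i_pm = 4L, i_nm = 2L)
  } else {
    list(radii = c(g$cell_radius - g$plasma_membrane_thickness, g$cell_radius),
         lam = c(lam_c, lam_pm, lam_e),
         i_pm = 2L, i_nm = NA_integer_)
  }
}

# potential drop (outer minus inner face) across layer k, per cos(theta);
# radii_aug = c(0, interface radii), so layer k spans radii_aug[k..k+1]
layer_drop <- function(sol, radii_aug, k) {
  Ri <- radii_aug[k]; Ro <- radii_aug[k + 1]
  (sol$a[k] * Ro + sol$b[k] / Ro^2) - (sol$a[k] * Ri + sol$b[k] / Ri^2)
}

#' Frequency-domain transmembrane potential of the shelled cell
#'
#' Solves the linear phasor dipole problem for the (double-)shelled cell in
#' a uniform sinusoidal field and returns the complex TMP amplitude at the
#' pole (angle 0) for the plasma membrane and, when a nucleus is present,
#' the nuclear membrane. With `dispersive = TRUE` the membrane permittivity
#' follows the second-order Debye relation; otherwise the static value.
#'
#' @param params A [cell_model_params()].
#' @param f Frequency (Hz), > 0; vectorized.
#' @param E0 Applied field amplitude (V/m).
#' @param dispersive Logical; apply membrane Debye dispersion.
#' @return A data frame with columns `f`, `tmp_plasma`, `tmp_nuclear`
#'   (absolute TMP amplitudes at the pole, V; `tmp_nuclear` is `NA` without
#'   a nucleus).
#' @export
solve_frequency_domain <- function(params, f, E0 = 1e6, dispersive = TRUE) {
  stopifnot(inherits(params, "cell_model_params"), all(f > 0))
  e0 <- params$eps_vacuum
  lam_pass <- function(mat, w) mat$conductivity +
    1i * w * mat$relative_permittivity * e0
  out <- t(vapply(f, function(fk) {
    w <- 2 * pi * fk
    if (dispersive) {
      epsm <- complex_permittivity(params$membrane_debye, fk)
      lam_pm <- params$plasma_membrane_static$conductivity + 1i * w * epsm
      lam_nm <- params$nuclear_membrane_static$conductivity + 1i * w * epsm
    } else {
      lam_pm <- lam_pass(params$plasma_membrane_static, w)
      lam_nm <- lam_pass(params$nuclear_membrane_static, w)
    }
    ly <- cell_layers(params,
                      lam_e = lam_pass(params$extracellular, w),
                      lam_pm = lam_pm,
                      lam_c = lam_pass(params$cytoplasm, w),
                      lam_nm = lam_nm,
                      lam_n = lam_pass(params$nucleoplasm, w))
    sol <- layered_sphere_l1(ly$radii, ly$lam, E0)
    aug <- c(0, ly$radii)
    tmp_pm <- abs(layer_drop(sol, aug, ly$i_pm))
    tmp_nm <- if (is.na(ly$i_nm)) NA_real_ else
      abs(layer_drop(sol, aug, ly$i_nm))
    c(tmp_pm, tmp_nm)
  }, c(0, 0)))
  data.frame(f = f, tmp_plasma = out[, 1], tmp_nuclear = out[, 2])
}

# ---- second-order Schwan transient -------------------------------------

# Laplace-domain pole TMP gain H(s) = TMP(s)/E(s) for the single-shelled
# cell (exterior / membrane / cytoplasm), evaluated at (possibly complex) s.
schwan_gain_s <- function(params, s) {
  e0 <- params$eps_vacuum
  g <- params$geometry
  lam <- function(mat) mat$conductivity + s * mat$relative_permittivity * e0
  radii <- c(g$cell_radius - g$plasma_membrane_thickness, g$cell_radius)
  sol <- layered_sphere_l1(radii,
                           c(lam(params$cytoplasm),
                             lam(params$plasma_membrane_static),
                             lam(params$extracellular)), 1)
  layer_drop(sol, c(0, radii), 2L)
}

#' Second-order Schwan response of the single-shelled cell
#'
#' Extracts the exact rational dipole transfer function `H(s) = TMP/E` of
#' the membrane-covered sphere (exterior, membrane, cytoplasm -- the nucleus
#' is omitted, its influence on the plasma-membrane TMP being negligible in
#' the slow regime this oracle serves) and factors it into the classical
#' second-order form with two real relaxation time constants.
#'
#' @param params A [cell_model_params()] (static membrane properties are
#'   used; no dispersion, no electroporation).
#' @return A list of class `schwan_response`: `gain_dc` (V per V/m at the
#'   pole), `tau` (two time constants, s, descending), `poles` (1/s),
#'   `res` (residues of `H(s)/s` at the poles, used for the step response),
#'   and the numerator/denominator coefficients of `H`.
#' @export
schwan_second_order <- function(params) {
  stopifnot(inherits(params, "cell_model_params"))
  # H(s) is rational of order at most (2,2). When the cytoplasm and the
  # extracellular medium have identical admittivities (as in the reference
  # parameter set) the two relaxations coincide and H degenerates exactly to
  # first order; the fit detects the effective order.
  sc <- 1e8  # s-scale bringing the poles to O(1)
  z <- c(0, 10^seq(-2, 2, length.out = 21))
  H <- vapply(z * sc, function(s) Re(schwan_gain_s(params, s)), 0)
  H0 <- H[1]
  Hn <- H / H0
  zt <- 10^seq(-1.8, 1.8, length.out = 13)
  Ht <- vapply(zt * sc, function(s) Re(schwan_gain_s(params, s)), 0) / H0
  fit_order <- function(p) {
    # a_0..a_p and b_0..b_{p-1} with b_p = 1, linear least squares
    Xa <- outer(z, 0:p, `^`)
    Xb <- -Hn * outer(z, 0:(p - 1), `^`)
    cf <- qr.solve(cbind(Xa, Xb), Hn * z^p)
    a <- cf[1:(p + 1)]; b <- c(cf[(p + 2):(2 * p + 1)], 1)
    err <- max(abs(vapply(seq_along(zt), function(i)
      sum(a * zt[i]^(0:p)) / sum(b * zt[i]^(0:p)), 0) - Ht)) / max(abs(Ht))
    list(a = a, b = b, err = err, order = p)
  }
  f1 <- fit_order(1)
  f <- if (f1$err < 1e-8) f1 else fit_order(2)
  if (f$err > 1e-6)
    stop("shelled-sphere transfer function is not second order for these parameters")
  pz <- polyroot(f$b)
  if (max(abs(Im(pz))) > 1e-8 * max(Mod(pz)) || any(Re(pz) >= 0))
    stop("non-physical (complex or unstable) relaxation time constants")
  poles <- Re(pz) * sc
  p <- f$order
  num <- function(s) sum(f$a * (s / sc)^(0:p)) * H0
  den_prime <- function(s) sum(f$b[-1] * (1:p) * (s / sc)^(0:(p - 1))) / sc
  res <- vapply(poles, function(pp) num(pp) / (pp * den_prime(pp)), 0)
  structure(list(gain_dc = H0,
                 tau = sort(-1 / poles, decreasing = TRUE),
                 poles = poles, res = res, order = p,
                 num = f$a * H0, den = f$b, s_scale = sc),
            class = "schwan_response")
}

# step response (unit field turned on at t = 0) of a schwan_response at the
# pole; vectorized over t, zero for t < 0
schwan_step <- function(sr, t) {
  out <- numeric(length(t))
  pos <- t >= 0
  tp <- t[pos]
  acc <- rep(sr$gain_dc, length(tp))
  for (k in seq_along(sr$poles)) acc <- acc + sr$res[k] * exp(sr$poles[k] * tp)
  out[pos] <- acc
  out
}

# integral of the unit step response from 0 to t (for ramp assembly)
schwan_step_integral <- function(sr, t) {
  out <- numeric(length(t))
  pos <- t >= 0
  tp <- t[pos]
  acc <- sr$gain_dc * tp
  for (k in seq_along(sr$poles))
    acc <- acc + sr$res[k] * (exp(sr$poles[k] * tp) - 1) / sr$poles[k]
  out[pos] <- acc
  out
}

#' Second-order Schwan transmembrane potential for a pulse
#'
#' Analytic TMP at angle `theta` for a trapezoidal pulse train (or a step
#' field), assembled by superposition of ramp responses of the second-order
#' Schwan transfer function.
#'
#' @param params A [cell_model_params()].
#' @param E0 Step field amplitude (V/m) if `pulse` is `NULL`.
#' @param t Times (s); vectorized.
#' @param theta Polar angle from the electrode-facing pole (degrees).
#' @param pulse Optional [pulse_train()]; overrides the step drive.
#' @param sr Optional precomputed [schwan_second_order()] response.
#' @return TMP (V) at each time.
#' @export
schwan_second_order_tmp <- function(params, E0 = 1e5, t, theta = 0,
                                    pulse = NULL, sr = NULL) {
  if (is.null(sr)) sr <- schwan_second_order(params)
  ct <- cospi(theta / 180)
  if (is.null(pulse)) return(E0 * ct * schwan_step(sr, t))
  # trapezoid = sum of ramps: slope +A/r at start, -A/r after rise,
  # -A/f at fall start, +A/f after fall; ramp response = slope * integral
  acc <- numeric(length(t))
  for (ph in pulse$phases) {
    r <- ph$rise_time; f <- ph$fall_time
    t0 <- ph$start_time; t1 <- t0 + r
    t2 <- t1 + ph$plateau_duration; t3 <- t2 + f
    acc <- acc + ph$amplitude *
      (schwan_step_integral(sr, t - t0) / r - schwan_step_integral(sr, t - t1) / r -
       schwan_step_integral(sr, t - t2) / f + schwan_step_integral(sr, t - t3) / f)
  }
  acc * ct
}

#' First-order steady-state transmembrane potential plateau
#'
#' Classical thin-shell steady state
#' `TMP = 1.5 E0 R cos(theta) / (1 + Gm R (sigma_i + 2 sigma_e) /
#' (2 sigma_i sigma_e))` with the areal membrane conductance
#' `Gm = sigma_m0 / d`; the correction factor is within a fraction of a
#' percent of 1 for physiological membranes.
#'
#' @param params A [cell_model_params()].
#' @param E0 Applied field (V/m).
#' @param theta Polar angle from the pole (degrees).
#' @return Steady-state TMP (V).
#' @export
first_order_plateau <- function(params, E0, theta = 0) {
  g <- params$geometry
  R <- g$cell_radius
  Gm <- params$plasma_membrane_static$conductivity / g$plasma_membrane_thickness
  si <- params$cytoplasm$conductivity
  se <- params$extracellular$conductivity
  corr <- 1 / (1 + Gm * R * (si + 2 * se) / (2 * si * se))
  1.5 * E0 * R * cospi(theta / 180) * corr
}

#' @export
print.schwan_response <- function(x, ...) {
  cat(sprintf("Schwan response (effective order %d): DC gain %.4g V/(V/m), tau = %s s\n",
              x$order, x$gain_dc,
              paste(signif(x$tau, 3), collapse = " / ")))
  invisible(x)
}
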