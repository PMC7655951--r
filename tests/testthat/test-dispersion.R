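md <- params_default$membrane_debye
e0 <- eps_vacuum()

test_that("complex permittivity has the printed limits and is passive", {
  expect_equal(Re(complex_permittivity(md, 0)), 4.43e-11, tolerance = 1e-10)
  expect_equal(Re(complex_permittivity(md, 0)) / e0, 5.00, tolerance = 1e-3)
  expect_equal(Re(complex_permittivity(md, 1e10)) / e0, 1.57, tolerance = 0.005)
  expect_equal(Re(complex_permittivity(md, 1e15)), md$eps_inf, tolerance = 1e-10)
  f <- 10^seq(3, 12, length.out = 40)
  expect_true(all(Im(complex_permittivity(md, f)) < 0))
  # monotone real part (two simple relaxations)
  expect_true(all(diff(Re(complex_permittivity(md, f))) < 0))
})

test_that("constant-field steady state equals (eps_m0 - eps0) E", {
  E <- 1e6
  tt <- seq(0, 50e-9, by = 0.1e-9)
  P <- polarization_response(rep(E, length(tt)), tt, md)
  expect_equal(P[length(P)], (4.43e-11 - e0) * E, tolerance = 1e-6)
  expect_equal(P[length(P)], 3.54e-5, tolerance = 0.01)
  # direct second-order form at steady state returns zero acceleration
  Pss <- (4.43e-11 - e0) * E
  expect_equal(polarization_derivatives(Pss, 0, E, 0, 0, md), 0,
               tolerance = 1e-20)
})

test_that("step response follows the two-exponential closed form", {
  E0 <- 1e6
  tt <- seq(0, 20e-9, by = 0.02e-9)
  P <- polarization_response(rep(E0, length(tt)), tt, md)
  exact <- (md$eps_inf - e0) * E0 +
    md$delta_eps_1 * E0 * (1 - exp(-tt / md$tau_1)) +
    md$delta_eps_2 * E0 * (1 - exp(-tt / md$tau_2))
  expect_equal(P, exact, tolerance = 1e-10)
})

test_that("relaxation from a charged state decays to zero under zero field", {
  st <- polarization_state(1)
  st$P1 <- 1e-5; st$P2 <- 5e-6
  for (i in 1:400) st <- step_polarization(st, 0, 0, 0.05e-9, md)
  expect_lt(abs(total_polarization(st, md)), 1e-5 * exp(-20e-9 / md$tau_1) * 1.01)
  # one step from the zero state with zero field stays zero
  z <- step_polarization(polarization_state(1), 0, 0, 0.02e-9, md)
  expect_identical(total_polarization(z, md), 0)
})

test_that("time-domain tone amplitude matches the frequency-domain law", {
  for (f in c(1e8, 1e9)) {
    dt <- min(1 / f / 40, md$tau_2 / 20)
    tt <- seq(0, 40e-9 + 10 / f, by = dt)
    E <- 1e6 * sin(2 * pi * f * tt)
    P <- polarization_response(E, tt, md)
    last <- tt > max(tt) - 1 / f
    amp <- (max(P[last]) - min(P[last])) / 2
    expect_equal(amp, Mod(complex_permittivity(md, f) - e0) * 1e6,
                 tolerance = 0.01)
  }
})

test_that("two-branch integrator agrees with the direct second-order form", {
  skip_if_not_installed("deSolve")
  E0 <- 1e6; f <- 2e8; w <- 2 * pi * f
  rhs <- function(t, y, parms) {
    E <- E0 * sin(w * t); dE <- E0 * w * cos(w * t); d2E <- -E0 * w^2 * sin(w * t)
    list(c(y[2], polarization_derivatives(y[1], y[2], E, dE, d2E, md)))
  }
  tt <- seq(0, 20e-9, by = 0.01e-9)
  # start from the consistent instantaneous state P(0) = 0, dP/dt matching
  # the instantaneous (eps_inf - eps0) dE/dt response
  y0 <- c(0, (md$eps_inf - e0) * E0 * w)
  sol <- deSolve::ode(y0, tt, rhs, NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-18)
  P_direct <- sol[, 2]
  P_branch <- polarization_response(E0 * sin(w * tt), tt, md)
  expect_lt(max(abs(P_branch - P_direct)) / max(abs(P_direct)), 0.01)
})

test_that("self-convergence: halving the step changes the result below 1%", {
  f <- 1e8
  endt <- 30e-9
  pe <- function(dt) {
    tt <- seq(0, endt, by = dt)
    P <- polarization_response(1e6 * sin(2 * pi * f * tt), tt, md)
    P[length(P)]
  }
  expect_lt(abs(pe(md$tau_2 / 10) - pe(md$tau_2 / 20)) / abs(pe(md$tau_2 / 20)),
            0.01)
})

test_that("degenerate inputs error", {
  expect_error(step_polarization(polarization_state(1), 0, 1, -1e-9, md), "dt")
  md_bad <- md; md_bad$tau_1 <- 0
  expect_error(polarization_derivatives(0, 0, 1, 0, 0, md_bad), "degenerate")
})
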