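ep <- params_default$ep

test_that("pore rate has its equilibrium and hand-computed values", {
  expect_equal(pore_density_rate(ep$N0, 0, ep), 0)
  # at zero voltage both exponentials are 1: rate = alpha (1 - N/N0)
  expect_equal(pore_density_rate(2 * ep$N0, 0, ep), -ep$alpha)
  # independent hand evaluation at 1 V: v2 = (1/0.258)^2 = 15.0235...,
  # rate = 1e9 * exp(-1.46 v2) * (exp(2.46 v2) - 1) = 3.34e15
  v2 <- (1 / 0.258)^2
  oracle <- 1e9 * exp((1 - 2.46) * v2) * (exp(2.46 * v2) - 1)
  expect_equal(pore_density_rate(ep$N0, 1, ep), oracle, tolerance = 1e-12)
  expect_equal(oracle, 3.3e15, tolerance = 0.02)
})

test_that("equilibrium pore density is the closed-form stationary point", {
  expect_equal(equilibrium_pore_density(0, ep), 1.5e9)
  expect_equal(equilibrium_pore_density(ep$V_ep, ep), ep$N0 * exp(ep$q))
  for (v in c(0.1, 0.3, 0.7, 1.1))
    expect_equal(pore_density_rate(equilibrium_pore_density(v, ep), v, ep), 0,
                 tolerance = 1e-6 * ep$alpha)
  # overflow guard saturates instead of returning Inf
  big <- equilibrium_pore_density(20, ep)
  expect_true(is.finite(big))
  expect_true(isTRUE(attr(big, "saturated")))
})

test_that("pore conductance factor is finite, continuous at its removable
           singularities, and matches an independent series evaluation", {
  # continuity at tmp = 0
  expect_equal(pore_conductance_factor(1e-6, ep),
               pore_conductance_factor(-1e-6, ep), tolerance = 1e-4)
  expect_true(is.finite(pore_conductance_factor(0, ep)))
  # the pole of the first denominator term: v_m = w0/n ->
  # tmp* = w0 R T / (n F) = 2.65 * 8.314 * 295 / (0.15 * 9.65e4)
  tmp_star <- ep$w0 * ep$R_gas * ep$T / (ep$n_rel * ep$F_const)
  expect_equal(tmp_star, 0.449, tolerance = 1e-3)
  ks <- pore_conductance_factor(tmp_star + c(-1e-7, 0, 1e-7), ep)
  expect_true(all(is.finite(ks)))
  expect_lt(diff(range(ks)) / abs(ks[2]), 1e-4)
  # independent oracle: same formula rearranged through expm1/series-free
  # evaluation away from the singular points
  K_oracle <- function(tmp) {
    vm <- ep$F_const * tmp / (ep$R_gas * ep$T)
    A <- (ep$w0 * exp(ep$w0 - ep$n_rel * vm) - ep$n_rel * vm) / (ep$w0 - ep$n_rel * vm)
    B <- (ep$w0 * exp(ep$w0 + ep$n_rel * vm) + ep$n_rel * vm) / (ep$w0 + ep$n_rel * vm)
    expm1(vm) / (A * exp(vm) - B)
  }
  for (tmp in c(0.2, 0.45 + 1e-3, 1.0))
    expect_equal(pore_conductance_factor(tmp, ep), K_oracle(tmp),
                 tolerance = 1e-10)
})

test_that("membrane conductivity is the linear pore superposition", {
  s0 <- 1.1e-7
  expect_equal(membrane_conductivity(0, 0.5, ep, s0), s0)
  ep0 <- ep; ep0$sigma_p <- 0
  expect_equal(membrane_conductivity(1e15, 0.5, ep0, s0), s0)
  # porated membrane: about five orders above the intact value at 1 V
  ratio <- membrane_conductivity(3.9e15, 1, ep, s0) / s0
  expect_gt(log10(ratio), 4)
  expect_lt(log10(ratio), 6)
  # non-decreasing and exactly linear in N
  s1 <- membrane_conductivity(1e15, 0.8, ep, s0)
  s2 <- membrane_conductivity(2e15, 0.8, ep, s0)
  s3 <- membrane_conductivity(3e15, 0.8, ep, s0)
  expect_gt(s2, s1)
  expect_equal(s3 - s2, s2 - s1, tolerance = 1e-12)
})

test_that("exponential integrator converges monotonically to the closed-form
           equilibrium at clamped voltage", {
  for (v in c(0.4, 0.8)) {
    Neq <- equilibrium_pore_density(v, ep)
    # destruction rate sets the relaxation time; step a fraction of it
    b <- ep$alpha / ep$N0 * exp((1 - ep$q) * (v / ep$V_ep)^2)
    N <- ep$N0
    path <- numeric(60)
    for (i in seq_along(path)) {
      N <- step_pore_density(N, v, 1 / b, ep)
      path[i] <- N
    }
    expect_true(all(diff(path) >= -1e-6 * Neq))
    expect_equal(N, Neq, tolerance = 1e-6)
  }
  # destruction side: starting above equilibrium decays to it
  N <- 10 * ep$N0
  for (i in 1:200) N <- step_pore_density(N, 0, 1, ep)
  expect_equal(N, ep$N0, tolerance = 1e-6)
})
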