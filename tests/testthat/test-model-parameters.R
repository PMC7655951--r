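test_that("default parameter set reproduces the published table in SI units", {
  p <- params_default
  expect_equal(p$geometry$cell_radius, 5e-6)
  expect_equal(p$geometry$plasma_membrane_thickness, 0.01e-6)
  expect_equal(p$geometry$nuclear_radius, 2.5e-6)
  expect_equal(p$geometry$nuclear_membrane_thickness, 0.01e-6)
  expect_equal(p$extracellular$conductivity, 0.55)
  expect_equal(p$plasma_membrane_static$conductivity, 1.1e-7)
  expect_equal(p$nuclear_membrane_static$conductivity, 1.1e-5)
  expect_equal(p$extracellular$relative_permittivity, 67)
  expect_equal(p$plasma_membrane_static$relative_permittivity, 5)
  md <- p$membrane_debye
  expect_equal(c(md$tau_1, md$tau_2), c(3.0e-9, 4.6e-10))
  expect_equal(c(md$eps_inf, md$delta_eps_1, md$delta_eps_2),
               c(13.9e-12, 2.3e-11, 7.4e-12))
  ep <- p$ep
  expect_equal(c(ep$alpha, ep$N0, ep$V_ep, ep$q), c(1e9, 1.5e9, 0.258, 2.46))
  expect_equal(c(ep$r_p, ep$w0, ep$sigma_p, ep$n_rel), c(0.76e-9, 2.65, 1.3, 0.15))
  expect_equal(c(ep$T, ep$R_gas, ep$F_const), c(295, 8.314, 9.65e4))
  expect_equal(ep$pt_threshold, 1e15)
})

test_that("Debye static limit is consistent with the declared permittivity", {
  md <- params_default$membrane_debye
  # direct sum (13.9 + 23 + 7.4) x 1e-12 F/m over the vacuum permittivity
  er <- (13.9e-12 + 2.3e-11 + 7.4e-12) / eps_vacuum()
  expect_equal(static_relative_permittivity(md), er)
  expect_lt(abs(er - 5) / 5, 0.02)
  # degenerate Debye: amplitudes -> 0 gives eps_inf alone
  md0 <- debye_material(delta_eps_1 = 1e-30, delta_eps_2 = 1e-30)
  expect_equal(static_relative_permittivity(md0), md0$eps_inf / eps_vacuum(),
               tolerance = 1e-12)
  expect_equal(13.9e-12 / eps_vacuum(), 1.57, tolerance = 0.005)
})

test_that("validation rejects non-physical constants", {
  expect_error(cell_geometry(cell_radius = -1e-6), "positive")
  expect_error(cell_geometry(nuclear_radius = 5e-6), "inside")
  expect_error(passive_material(-0.1, 67), "non-negative")
  expect_error(passive_material(0.5, 0.5), ">= 1")
  expect_error(debye_material(tau_1 = 0), "positive")
  expect_error(ep_model(q = 0.5), "q must")
  expect_error(ep_model(n_rel = 1.5), "n_rel")
  # inconsistent static permittivity vs Debye limit
  expect_error(cell_model_params(
    plasma_membrane_static = passive_material(1.1e-7, 9),
    nuclear_membrane_static = passive_material(1.1e-5, 9)), "disagree")
})

test_that("config file round-trips identically", {
  p <- cell_model_params(geometry = cell_geometry(cell_radius = 6e-6,
                                                  has_nucleus = FALSE),
                         extracellular = passive_material(1.2, 72))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_cell_model(p, path)
  q <- read_cell_model(path)
  expect_equal(unclass(q), unclass(p), tolerance = 1e-12)
})
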