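p <- params_default

test_that("first-order plateau matches the classical thin-shell value", {
  expect_equal(first_order_plateau(p, 1e5, 0), 0.75, tolerance = 0.001)
  expect_equal(first_order_plateau(p, 0, 0), 0)
  expect_equal(first_order_plateau(p, 1e5, 90), 0, tolerance = 1e-12)
  expect_equal(first_order_plateau(p, 1e5, 60), first_order_plateau(p, 1e5, 0) / 2)
})

test_that("the exact transfer function recovers the plateau and decays at 90 deg", {
  sr <- schwan_second_order(p)
  expect_equal(sr$gain_dc * 1e5, first_order_plateau(p, 1e5, 0), tolerance = 0.01)
  expect_true(all(sr$tau > 0))
  # long-time step response reaches the plateau
  expect_equal(schwan_second_order_tmp(p, 1e5, 1e-3, 0, sr = sr),
               first_order_plateau(p, 1e5, 0), tolerance = 1e-4)
  expect_equal(schwan_second_order_tmp(p, 1e5, 1e-3, 90, sr = sr), 0,
               tolerance = 1e-12)
  # monotone step response for real positive time constants
  tt <- seq(0, 500e-9, by = 1e-9)
  expect_true(all(diff(schwan_second_order_tmp(p, 1e5, tt, 0, sr = sr)) >= 0))
})

test_that("identical electrolytes degenerate to one relaxation; distinct ones
           give two separated positive time constants", {
  # reference set: cytoplasm and medium identical -> first order
  expect_equal(schwan_second_order(p)$order, 1L)
  # a cell with distinct cytoplasm: genuine second order
  p2 <- cell_model_params(cytoplasm = passive_material(0.2, 50))
  sr2 <- schwan_second_order(p2)
  expect_equal(sr2$order, 2L)
  expect_true(all(sr2$tau > 0))
  expect_gt(sr2$tau[1] / sr2$tau[2], 5)
})

test_that("pulse response is the superposition of delayed ramp responses", {
  sr <- schwan_second_order(p)
  pulse <- pulse_train(list(pulse_phase(0, 9e-9, 1e-9, 1e-9, 1e6)))
  tt <- seq(0, 30e-9, by = 0.1e-9)
  resp <- schwan_second_order_tmp(p, t = tt, theta = 0, pulse = pulse, sr = sr)
  # during the long plateau the pulse response approaches the step response
  step <- 1e6 * schwan_second_order_tmp(p, 1, tt - 0.5e-9, 0, sr = sr)
  mid <- tt > 5e-9 & tt < 10e-9
  expect_equal(resp[mid], step[mid], tolerance = 0.01)
  # zero before the pulse and decaying after it
  expect_equal(resp[tt < 1e-12], 0)
  tail <- tt > 12e-9
  expect_true(all(diff(resp[tail]) < 0))
})

test_that("frequency response is low-pass on the plasma membrane and
           band-pass on the nuclear membrane", {
  f <- 10^seq(4, 10, length.out = 25)
  fd <- solve_frequency_domain(p, f, 1e6, dispersive = FALSE)
  # plasma: plateau then monotone non-increasing
  expect_equal(fd$tmp_plasma[1], 7.5, tolerance = 0.01)
  expect_true(all(diff(fd$tmp_plasma) < 1e-6))
  # nuclear: interior maximum
  im <- which.max(fd$tmp_nuclear)
  expect_gt(im, 3); expect_lt(im, length(f) - 2)
  # dispersion raises the high-frequency plasma response (1e10 Hz)
  fdd <- solve_frequency_domain(p, f, 1e6, dispersive = TRUE)
  expect_gt(fdd$tmp_plasma[length(f)], 2 * fd$tmp_plasma[length(f)])
  # low-frequency plateau: classical 1.5 E R cos(theta)
  expect_equal(fd$tmp_plasma[1], 1.5 * 1e6 * 5e-6, tolerance = 0.01)
})
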