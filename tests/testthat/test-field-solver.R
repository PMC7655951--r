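p <- params_default

test_that("zero drive keeps the state identically zero and pores at N0", {
  r <- solve_time_domain(p, NULL,
                         quick_opts(t_end = 1e-9),
                         spec = coarse_spec(), field_fun = function(t) 0)
  expect_equal(max(abs(r$tmp_theta)), 0)
  expect_equal(max(abs(r$tmp_nuclear)), 0)
  expect_true(all(r$N_theta == p$ep$N0))
})

test_that("static-mode solver is linear and antisymmetric about the equator", {
  mk <- function(amp) pulse_train(list(pulse_phase(0, 2e-9, 1e-9, 1e-9, amp)))
  o <- quick_opts(dispersive = FALSE, electroporate = FALSE, t_end = 4e-9)
  r1 <- solve_time_domain(p, mk(1e6), o, spec = coarse_spec())
  r2 <- solve_time_domain(p, mk(2e6), o, spec = coarse_spec())
  expect_equal(r2$tmp_theta, 2 * r1$tmp_theta, tolerance = 1e-10)
  # TMP(theta) = -TMP(180 - theta) on the uniform polar grid
  last <- nrow(r1$tmp_theta)
  prof <- r1$tmp_theta[last, ]
  expect_equal(prof, -rev(prof), tolerance = 1e-9)
  # equatorial probe stays at zero
  expect_lt(max(abs(r1$tmp[, 7])), 1e-9 * max(abs(r1$tmp[, 1])))
})

test_that("single-shell transient reproduces the analytic shelled-sphere
           response through the whole pulse", {
  pulse <- standard_pulse("p10ns")
  r <- solve_time_domain(p, pulse,
                         quick_opts(dispersive = FALSE, electroporate = FALSE,
                                    include_nucleus = FALSE),
                         spec = coarse_spec())
  sch <- schwan_second_order_tmp(p, t = r$time, theta = 0, pulse = pulse)
  expect_lt(max(abs(r$tmp[, 1] - sch)) / max(abs(sch)), 0.03)
  # and at an off-axis probe (45 degrees)
  sch45 <- schwan_second_order_tmp(p, t = r$time, theta = 45, pulse = pulse)
  expect_lt(max(abs(r$tmp[, 4] - sch45)) / max(abs(sch45)), 0.03)
})

test_that("single-tone drive reproduces the phasor amplitudes within 2%
           (self-consistent dispersion)", {
  f <- 1e9
  r <- solve_time_domain(p, NULL,
                         solver_options(dispersive = TRUE, electroporate = FALSE,
                                        dispersion_drive = "local",
                                        dt = 0.05e-9, t_end = 100e-9),
                         spec = coarse_spec(),
                         field_fun = function(t) 1e6 * sin(2 * pi * f * t))
  last <- r$time > 95e-9
  amp <- (max(r$tmp[last, 1]) - min(r$tmp[last, 1])) / 2
  fd <- solve_frequency_domain(p, f, 1e6, dispersive = TRUE)
  expect_equal(amp, fd$tmp_plasma, tolerance = 0.02)
})

test_that("removing the nucleus changes the transient only modestly", {
  pulse <- standard_pulse("p10ns")
  o <- quick_opts(dispersive = FALSE, electroporate = FALSE, t_end = 12e-9)
  r2 <- solve_time_domain(p, pulse, o, spec = coarse_spec())
  o$include_nucleus <- FALSE
  r1 <- solve_time_domain(p, pulse, o, spec = coarse_spec())
  expect_false(isTRUE(all.equal(r1$tmp[, 1], r2$tmp[, 1], tolerance = 1e-6)))
  expect_lt(max(abs(r1$tmp[, 1] - r2$tmp[, 1])) / max(abs(r1$tmp[, 1])), 0.1)
})

test_that("cosine-law misfit and poration-extent classifiers behave on
           constructed profiles", {
  th <- seq(1, 179, by = 2)
  prof <- data.frame(theta_deg = th, tmp = 1.3 * cospi(th / 180))
  expect_equal(cos_theta_deviation(prof), 0, tolerance = 1e-12)
  # flattened polar cap (porated): large misfit
  flat <- prof; flat$tmp <- pmin(flat$tmp, 0.5 * max(flat$tmp))
  expect_gt(cos_theta_deviation(flat), 0.05)
  fake <- list(theta_centers_deg = th,
               N_max_theta = rep(params_default$ep$N0, length(th)))
  expect_equal(classify_electroporated_extent(fake, params_default$ep), 0)
  fake$N_max_theta[th < 40] <- 2e15
  ext <- classify_electroporated_extent(fake, params_default$ep)
  expect_equal(ext, 40, tolerance = 2.5)
})

test_that("run export writes readable probe series", {
  pulse <- standard_pulse("p3ns")
  r <- solve_time_domain(p, pulse,
                         quick_opts(dispersive = FALSE, electroporate = FALSE,
                                    t_end = 5e-9,
                                    profile_times = 3e-9),
                         spec = coarse_spec())
  dir <- withr::local_tempdir()
  write_run(r, dir)
  probes <- read.delim(file.path(dir, "probes.tsv"))
  expect_equal(nrow(probes), length(r$time))
  expect_true(all(c("tmp_A1", "N_A1", "sigma_A7") %in% names(probes)))
  prof <- read.delim(file.path(dir, "profiles.tsv"))
  expect_equal(unique(prof$time), 3e-9, tolerance = 0.1)
})
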