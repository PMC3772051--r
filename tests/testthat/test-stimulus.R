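test_that("AM drive follows a(f) * b(c) * sin(2 pi f t)", {
  tf <- punit_transfer(c(10, 20), c(0.4, 0.6), adaptation_factor = 0.9,
                       adaptation_cutoff = 2)
  # zero contrast: no modulation at any time or frequency
  s0 <- am_stimulus(7, 0, 1)
  expect_equal(am_drive(s0, tf, seq(0, 1, 0.01)), rep(0, 101))
  # phase symmetry: zero at t = 0, peak a(f)*b(c) at quarter period
  sp <- am_stimulus(8, 10, 1)
  expect_equal(am_drive(sp, tf, 0), 0)
  expect_equal(am_drive(sp, tf, 1 / 32), 0.4)
  # below the adaptation cutoff the factor 0.9 applies
  slow <- am_stimulus(2, 10, 1)
  expect_equal(am_drive(slow, tf, 1 / 8), 0.9 * 0.4)
  # exact period 1/f and zero mean over one period
  tt <- seq(0, 1 / 8, length.out = 513)[-513]
  expect_equal(am_drive(sp, tf, tt + 1 / 8), am_drive(sp, tf, tt))
  expect_lt(abs(mean(am_drive(sp, tf, tt))), 1e-12)
})

test_that("transfer interpolation is linear with clamped extrapolation", {
  tf <- punit_transfer(c(10, 20), c(0.4, 0.6))
  # hand interpolation: (0,0), (10,0.4), (20,0.6) queried at 15
  expect_equal(transfer_amplitude(tf, 15), 0.5)
  # identity at calibration points
  expect_equal(transfer_amplitude(tf, c(0, 10, 20)), c(0, 0.4, 0.6))
  # midway = arithmetic mean
  expect_equal(transfer_amplitude(tf, 5), 0.2)
  # clamp above the calibrated range (saturated regime)
  expect_equal(transfer_amplitude(tf, 35), 0.6)
  expect_error(transfer_amplitude(tf, -1), "non-negative")
})

test_that("transfer constructor enforces its invariants", {
  expect_error(punit_transfer(c(10), c(0.4)), "two calibration")
  expect_error(punit_transfer(c(10, 20), c(0.6, 0.4)), "non-decreasing")
  expect_error(punit_transfer(c(20, 10), c(0.4, 0.6)), "increasing")
  expect_error(punit_transfer(c(10, 20), c(0.4, 0.6),
                              adaptation_factor = 1.2), "adaptation_factor")
  # b(0) = 0 anchor added automatically
  tf <- punit_transfer(c(10, 20), c(0.4, 0.6))
  expect_equal(tf$contrasts[1], 0)
  expect_equal(tf$amplitudes[1], 0)
})

test_that("stimulus validation rejects unphysical parameters", {
  expect_error(am_stimulus(-1, 10, 1), "frequency")
  expect_error(am_stimulus(8, -2, 1), "contrast")
  expect_error(am_stimulus(8, 25, 1), "validated range")
  expect_no_error(am_stimulus(8, 25, 1, contrast_max = 30))
  expect_error(am_stimulus(8, 10, 0), "duration")
})

test_that("default transfer is concave (saturating) and non-decreasing", {
  tf <- default_transfer()
  b <- tf$amplitudes
  expect_true(all(diff(b) >= 0))
  expect_true(all(diff(diff(b)) <= 1e-12))
})

test_that("transfer calibration recovers known amplitudes (closed loop)", {
  np <- neuron_params()
  dp <- dap_params()
  f_ref <- 8; cycles <- 200; dt <- 5e-5
  b_true <- c(0.25, 0.45)
  targets <- vapply(b_true, function(b) {
    set.seed(11)
    sp <- negimage:::simulate_sp_raw(cycles / f_ref, dt, f_ref, b, np, dp)
    psth_peak_rate(compute_psth(sp$spikes, f_ref, 32, cycles / f_ref))
  }, numeric(1))
  tf <- calibrate_transfer(
    data.frame(contrast = c(10, 20), max_rate = targets),
    neuron = np, dap = dp, f_ref = f_ref, cycles = cycles, dt = dt,
    seed = 11, tol = 5e-3)
  got <- transfer_amplitude(tf, c(10, 20))
  expect_lt(max(abs(got - b_true)), 0.04)
  expect_gt(got[2], got[1])  # monotone amplitude-rate curve
  # a target equal to the spontaneous peak maps to amplitude zero
  set.seed(11)
  sp0 <- negimage:::simulate_sp_raw(cycles / f_ref, dt, f_ref, 0, np, dp)
  r0 <- psth_peak_rate(compute_psth(sp0$spikes, f_ref, 32, cycles / f_ref))
  tf0 <- calibrate_transfer(
    data.frame(contrast = c(5, 10), max_rate = c(r0, targets[1])),
    neuron = np, dap = dp, f_ref = f_ref, cycles = cycles, dt = dt,
    seed = 11, tol = 5e-3)
  expect_equal(transfer_amplitude(tf0, 5), 0)
  # unreachable target reports the achievable range
  expect_error(calibrate_transfer(
    data.frame(contrast = 10, max_rate = 1e5),
    neuron = np, dap = dp, f_ref = f_ref, cycles = 20, dt = dt,
    seed = 11), "achievable range")
})
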