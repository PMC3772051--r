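test_that("segment arrays tile one stimulus period", {
  suppressMessages({
    pf8 <- pf_segments(8, 2e-3)
    pf2 <- pf_segments(2, 2e-3)
  })
  # 125 ms / 2 ms: 62 or 63 segments, residual logged in the object
  expect_true(length(pf8$weights) %in% c(62, 63))
  expect_equal(length(pf8$weights) * pf8$segment_duration, 1 / 8)
  # 4x more segments at 2 Hz than at 8 Hz
  expect_equal(length(pf2$weights) / length(pf8$weights), 4, tolerance = 0.02)
  # exact tiling: period/4 gives 4 segments at phases 0, pi/2, pi, 3pi/2
  pf4 <- pf_segments(8, (1 / 8) / 4)
  expect_length(pf4$weights, 4)
  expect_equal(2 * pi * pf4$onsets * 8, c(0, pi / 2, pi, 3 * pi / 2))
  expect_equal(pf4$rounding_residual, 0)
  expect_error(pf_segments(8, 0.08), "half the stimulus period")
})

test_that("feedback gain factorizes as G0 * s(c) * b(c) and is 0 locally", {
  tf <- punit_transfer(c(10, 20), c(0.4, 0.6))
  gn <- feedback_gain_params(G0 = 2)
  expect_identical(feedback_gain(15, tf, gn, "local"), 0)
  # saturation disabled: G(c)/b(c) constant in c
  g1 <- feedback_gain_params(G0 = 2, saturation = FALSE)
  ratio <- vapply(c(5, 10, 15, 20),
                  function(cc) feedback_gain(cc, tf, g1) /
                    transfer_amplitude(tf, cc), numeric(1))
  expect_equal(ratio, rep(2, 4))
  # arithmetic from the configured saturation table
  gs <- feedback_gain_params(G0 = 2, sat_contrasts = c(5, 10, 15, 20),
                             sat_factors = c(1, 1, 0.95, 0.9))
  expect_equal(feedback_gain(20, tf, gs) / feedback_gain(15, tf, gs),
               0.9 * transfer_amplitude(tf, 20) /
                 (0.95 * transfer_amplitude(tf, 15)))
  # the feedback inherits the P-unit low-frequency adaptation
  tfa <- punit_transfer(c(10, 20), c(0.4, 0.6), adaptation_factor = 0.9,
                        adaptation_cutoff = 2)
  expect_equal(feedback_gain(10, tfa, g1, frequency = 2),
               0.9 * feedback_gain(10, tfa, g1, frequency = 4))
})

test_that("saturation factors interpolate and extend monotonically", {
  gn <- feedback_gain_params(sat_contrasts = c(5, 10, 15, 20),
                             sat_factors = c(1, 1, 0.9, 0.8))
  expect_equal(saturation_factor(gn, 12.5), 0.95)
  expect_equal(saturation_factor(gn, 20), 0.8)
  # linear extension beyond the table: saturation keeps deepening
  expect_equal(saturation_factor(gn, 25), 0.7)
  expect_true(all(diff(saturation_factor(gn, seq(5, 30, 1))) <= 0))
  off <- feedback_gain_params(saturation = FALSE)
  expect_equal(saturation_factor(off, c(5, 25)), c(1, 1))
})

test_that("feedback term is step-wise constant, periodic and shunted", {
  pf <- pf_segments(8, (1 / 8) / 4)
  pf$weights <- c(1.2, 0.3, 0.8, 1.5)
  # zero weights: the weighted grouping contributes nothing; the pooled
  # grouping retains the population shunt, which vanishes at rest
  pf0 <- pf; pf0$weights <- rep(0, 4)
  tt <- seq(0, 0.5, 1e-4)
  expect_true(all(feedback_term(tt, 0.5, pf0, G = 1,
                                shunt_mode = "weighted") == 0))
  expect_true(all(feedback_term(tt, 0, pf0, G = 1) == 0))
  expect_equal(unique(feedback_term(tt, 0.5, pf0, G = 1)),
               -1.44 * 0.5)
  # at rest (V = 0) the pooled term is pure excitation G * w_j
  expect_equal(feedback_term(0.001, 0, pf, G = 2), 2 * 1.2)
  expect_equal(feedback_term(0.032, 0, pf, G = 2), 2 * 0.3)
  # piecewise constancy within a segment at fixed V
  in_seg <- seq(0.0005, 0.0305, 1e-4)
  in_seg <- in_seg[in_seg < 1 / 32]
  expect_equal(length(unique(feedback_term(in_seg, 0.4, pf, G = 1))), 1)
  # periodicity over whole cycles for arbitrary V
  expect_equal(feedback_term(tt + 1 / 8, 0.37, pf, G = 1.3),
               feedback_term(tt, 0.37, pf, G = 1.3))
  # weighted grouping scales the shunt by the active weight
  expect_equal(feedback_term(0.001, 0.5, pf, G = 2, shunt_mode = "weighted"),
               2 * 1.2 * (1 - 1.44 * 0.5))
  expect_equal(feedback_term(0.001, 0.5, pf, G = 2, shunt_mode = "pooled"),
               2 * (1.2 - 1.44 * 0.5))
})

test_that("gain calibration recovers a known G0 (closed loop)", {
  tf <- default_transfer()
  gn <- feedback_gain_params(G0 = 2)
  f_ref <- 8; cycles <- 60; dt <- 5e-5
  pf <- pf_segments(f_ref, 2e-3)
  spec <- am_stimulus(f_ref, 10, cycles / f_ref, "global")
  target <- {
    sim <- simulate_sp(spec, tf, feedback = pf, gain = gn, dt = dt,
                       seed = 21)
    length(sim$spikes) / sim$duration
  }
  got <- calibrate_gain(target, tf, f_ref = f_ref, cycles = cycles,
                        dt = dt, seed = 21, G_max = 4, tol = 5e-3)
  expect_lt(abs(got$G0 - 2), 0.25)
  expect_error(calibrate_gain(1e4, tf, f_ref = f_ref, cycles = 20,
                              dt = dt, seed = 21),
               "achievable range")
})
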