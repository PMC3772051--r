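test_that("burst detection handles the canonical cases", {
  # two spikes within the 10 ms window: one small burst at the first spike
  b <- detect_bursts(c(0, 0.005))
  expect_equal(b$type, "small")
  expect_equal(b$time, 0)
  # four spikes spanning 90 ms < 100 ms: one large burst, and no small
  # burst carved out of its spikes
  b <- detect_bursts(c(0, 0.030, 0.060, 0.090))
  expect_equal(b$type, "large")
  expect_equal(nrow(b), 1)
  # all ISIs beyond both windows: no bursts
  expect_equal(nrow(detect_bursts(c(0, 0.2, 0.4))), 0)
  # five spikes cannot yield a large and a small burst: the large
  # consumes four, the leftover single spike is no burst
  b <- detect_bursts(c(0, 0.03, 0.06, 0.09, 0.095))
  expect_equal(b$type, "large")
  expect_equal(nrow(b), 1)
  expect_error(detect_bursts(c(0.2, 0.1)), "increasing")
})

test_that("greedy detection equals exhaustive preferred assignment", {
  pp <- plasticity_params()
  for (seed in 1:300) {
    set.seed(seed)
    n <- sample(0:12, 1)
    spikes <- sort(runif(n, 0, 0.4))
    got <- detect_bursts(spikes, pp)
    want <- enumerate_bursts(spikes, pp$t_small, pp$t_large)
    expect_equal(got$time, want$time, info = paste("seed", seed))
    expect_equal(got$type, want$type, info = paste("seed", seed))
  }
})

test_that("depression follows the causal linear kernel with a zero floor", {
  pp <- plasticity_params()
  pf <- pf_segments(8, (1 / 8) / 4)          # onsets at 0, 31.25, 62.5, 93.75 ms
  # burst 5 ms into the cycle: only segment 1 (dt = 5 ms) is inside the
  # 15 ms small window; depression = eta2 * (1 - 5/15)
  out <- apply_depression(pf, 0.005, "small", pp)
  expect_equal(out$weights[1], 1.5 - pp$eta_small * (1 - 5 / 15))
  expect_equal(out$weights[2:4], rep(1.5, 3))  # outside: unchanged
  # segment onset in the previous cycle still matches via wrap-around
  out2 <- apply_depression(pf, 0.125 + 0.005, "small", pp)
  expect_equal(out2$weights, out$weights)
  # large bursts use eta4 and the wider window
  out4 <- apply_depression(pf, 0.005, "large", pp)
  expect_equal(out4$weights[1], 1.5 - pp$eta_large * (1 - 5 / 30))
  # a large burst depresses at least as much as a small one (eta4 >= eta2)
  expect_lt(out4$weights[1], out$weights[1])
  # floor at zero
  pf0 <- pf; pf0$weights <- rep(0, 4)
  expect_equal(apply_depression(pf0, 0.005, "large", pp)$weights,
               rep(0, 4))
})

test_that("potentiation is the exact exponential relaxation to w_max", {
  pp <- plasticity_params()                    # tau_w = 980 s, w_max = 1.5
  pf <- pf_segments(8, (1 / 8) / 4)
  # fixed point: w = w_max unchanged for any elapsed time
  expect_equal(apply_potentiation(pf, 123)$weights, rep(1.5, 4))
  # closed form at one time constant: 1.5 - 1.0 * exp(-1) ~ 1.1321
  pf$weights <- rep(0.5, 4)
  w1 <- apply_potentiation(pf, 980, pp)$weights[1]
  expect_equal(w1, 1.5 - exp(-1), tolerance = 1e-12)
  expect_equal(round(w1, 4), 1.1321)
  # matches a fine-step Euler integration of dw/dt = (w_max - w)/tau_w
  w <- 0.5; h <- 0.01
  for (i in seq_len(980 / h)) w <- w + h * (1.5 - w) / 980
  expect_equal(w1, w, tolerance = 1e-4)
  # asymptote from zero
  pf$weights <- rep(0, 4)
  expect_equal(apply_potentiation(pf, 1e6, pp)$weights, rep(1.5, 4))
  expect_error(apply_potentiation(pf, -1), "non-negative")
})

test_that("weights stay in [0, w_max] under random update sequences", {
  pp <- plasticity_params()
  set.seed(9)
  pf <- pf_segments(4, 5e-3)
  for (i in 1:400) {
    if (runif(1) < 0.7) {
      pf <- apply_depression(pf, runif(1, 0, 0.25),
                             sample(c("small", "large"), 1), pp)
    } else {
      pf <- apply_potentiation(pf, runif(1, 0, 50), pp)
    }
    expect_true(all(pf$weights >= 0 & pf$weights <= pp$w_max + 1e-12))
  }
})

test_that("with no bursts the weight trajectory is purely the exponential", {
  # simulate with plasticity enabled but a silent neuron (no drive, no
  # noise): no spikes, so only potentiation acts, in closed form
  np <- neuron_params(bias = 0, sigma = 0)
  pf <- pf_segments(8, (1 / 8) / 4)
  pf$weights <- rep(0.3, 4)
  pp <- plasticity_params(tau_w = 5)
  res <- negimage:::simulate_sp_raw(2, 5e-5, 8, 0, np,
                                    dap_params(enabled = FALSE),
                                    feedback = pf, G = 0,
                                    plastic = TRUE, plasticity = pp)
  expect_length(res$spikes, 0)
  expect_equal(res$weights, rep(1.5 + (0.3 - 1.5) * exp(-2 / 5), 4),
               tolerance = 1e-10)
})
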