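std_epoch <- function(amplitude = 2) {
  data.frame(onset_s = 12.5, duration_s = 6, amplitude_pct = amplitude)
}

test_that("bleach correction flattens a pure exponential to 1", {
  sim <- simulate_trace(std_epoch(0), f0 = 120, bleach_tau = 60, noise_sd = 0)
  corr <- bleach_correct(sim$trace)
  expect_equal(corr$trace$corrected, rep(1, nrow(corr$trace)),
               tolerance = 1e-6)
  expect_equal(corr$tau, 60, tolerance = 1e-6)
  expect_equal(corr$method, "exponential")
})

test_that("a constant trace is normalized to 1 with no decay", {
  trace <- data.frame(time_s = seq(0, 50, by = 0.25), intensity = 88)
  corr <- bleach_correct(trace)
  expect_equal(corr$trace$corrected, rep(1, nrow(trace)), tolerance = 1e-9)
  expect_true(is.infinite(corr$tau) || abs(50 / corr$tau) < 1e-6)
})

test_that("protected windows keep the transient out of the bleach fit", {
  sim <- simulate_trace(std_epoch(2), bleach_tau = 60, noise_sd = 0)
  corr <- bleach_correct(sim$trace, protect_epochs(sim$epochs))
  t <- corr$trace$time_s
  on <- t >= 12.5 & t <= 18.5
  expect_equal(mean(corr$trace$corrected[!on]), 1, tolerance = 1e-6)
  expect_equal(mean(corr$trace$corrected[on]), 1.02, tolerance = 1e-6)
})

test_that("the 4-s window statistic recovers transient amplitudes exactly", {
  # flat trace: zero response
  flat <- data.frame(time_s = seq(0, 50, by = 0.125), intensity = 100)
  expect_equal(windowed_response(flat, 12.5, 6)$delta_percent, 0)

  # noiseless 2% boxcar through the full pipeline
  sim <- simulate_trace(std_epoch(2), noise_sd = 0)
  corr <- bleach_correct(sim$trace, protect_epochs(sim$epochs))
  rs <- windowed_response(corr, 12.5, 6)
  expect_equal(rs$delta_percent, 2, tolerance = 1e-9)
  expect_equal(rs$response_window, c(14.5, 18.5))
  expect_gte(rs$n_baseline_frames, 14)   # 4 s at >= 3.5 Hz

  # 1% transient on a second epoch lands at stimulus_index 2
  eps <- data.frame(onset_s = c(12.5, 35), duration_s = c(6, 6),
                    amplitude_pct = c(2, 1))
  sim2 <- simulate_trace(eps, noise_sd = 0)
  corr2 <- bleach_correct(sim2$trace, protect_epochs(sim2$epochs))
  rs2 <- windowed_response(corr2, 35, 6, stimulus_index = 2)
  expect_equal(rs2$delta_percent, 1, tolerance = 1e-9)
  expect_equal(rs2$stimulus_index, 2L)
})

test_that("response errors name the missing pre-stimulus data", {
  sim <- simulate_trace(std_epoch(2), noise_sd = 0)
  corr <- bleach_correct(sim$trace, protect_epochs(sim$epochs))
  expect_error(windowed_response(corr, 2, 6), "pre-stimulus")
  expect_error(windowed_response(corr, 12.5, 3), "shorter than window")
})

test_that("adaptation profiles order responses across repeated stimuli", {
  eps <- data.frame(onset_s = c(10, 25, 40), duration_s = 6,
                    amplitude_pct = c(2, 1, 1))
  sim <- simulate_trace(eps, total_duration = 50, noise_sd = 0)
  corr <- bleach_correct(sim$trace, protect_epochs(sim$epochs))
  prof <- adaptation_profile(corr, sim$epochs)
  expect_equal(prof$stimulus_index, 1:3)
  expect_equal(prof$delta_percent, c(2, 1, 1), tolerance = 1e-9)

  # identical transients give identical responses
  eq <- data.frame(onset_s = c(10, 30), duration_s = 6, amplitude_pct = 1.5)
  sime <- simulate_trace(eq, noise_sd = 0)
  corre <- bleach_correct(sime$trace, protect_epochs(sime$epochs))
  prof_eq <- adaptation_profile(corre, sime$epochs)$delta_percent
  expect_equal(prof_eq[1], prof_eq[2], tolerance = 1e-9)

  # single epoch: length-1 profile
  expect_equal(nrow(adaptation_profile(corr, sim$epochs[1, ])), 1)

  overlap <- data.frame(onset_s = c(10, 14), duration_s = 6,
                        amplitude_pct = 1)
  expect_error(adaptation_profile(corr, overlap), "overlap")
})

test_that("delta_percent is invariant to overall trace scaling", {
  sim <- simulate_trace(std_epoch(2), noise_sd = 0.2, seed = 17)
  for (scale in c(0.01, 1, 250)) {
    tr <- sim$trace
    tr$intensity <- tr$intensity * scale
    corr <- bleach_correct(tr, protect_epochs(sim$epochs))
    if (scale == 0.01) base <- windowed_response(corr, 12.5, 6)$delta_percent
    expect_equal(windowed_response(corr, 12.5, 6)$delta_percent, base,
                 tolerance = 1e-9)
  }
})

test_that("amplitudes round-trip across decay, amplitude and noise grids", {
  for (tau in c(30, 60, 120)) {
    for (amp in c(0.5, 1, 2, 5)) {
      sim <- simulate_trace(std_epoch(amp), bleach_tau = tau, noise_sd = 0)
      corr <- bleach_correct(sim$trace, protect_epochs(sim$epochs))
      expect_equal(windowed_response(corr, 12.5, 6)$delta_percent, amp,
                   tolerance = 0.1)
    }
  }
  # noisy: recovered within 3 Monte Carlo SE of the window-mean contrast
  # (two 32-frame windows of 0.2% frame noise -> SE ~ 0.05%)
  set.seed(23)
  err <- replicate(40, {
    sim <- simulate_trace(std_epoch(2), bleach_tau = 60, noise_sd = 0.2)
    corr <- bleach_correct(sim$trace, protect_epochs(sim$epochs))
    windowed_response(corr, 12.5, 6)$delta_percent - 2
  })
  expect_lt(abs(mean(err)), 3 * sd(err) / sqrt(length(err)))
  expect_lt(sd(err), 0.2)
})

test_that("the partially-restrained 4-frame protocol averages correctly", {
  expect_equal(partial_restraint_response(rep(5, 4), rep(5, 4), rep(5, 4)), 0)
  expect_equal(partial_restraint_response(rep(100, 4), rep(120, 4),
                                          rep(100, 4)), 20)
  # post-stimulus drift pulls the reference down: 100 vs mean(90)
  expect_equal(partial_restraint_response(rep(100, 4), rep(100, 4),
                                          rep(80, 4)), 100 / 9,
               tolerance = 1e-9)
  expect_error(partial_restraint_response(rep(1, 3), rep(1, 4), rep(1, 4)))
  expect_error(partial_restraint_response(rep(1, 4), c(1, 1, -2, 1),
                                          rep(1, 4)), "positive")
})

test_that("group response test separates real responses from noise", {
  expect_equal(group_response_test(rep(1, 5), rep(1, 5))$p, 1)

  set.seed(31)
  base <- rnorm(7, 100, 0.5)
  resp <- base * (1 + rnorm(7, 0.02, 0.005))   # 2% +/- 0.5% responses
  out <- group_response_test(base, resp)
  expect_lt(out$p, 0.05)

  # null: no systematic change, most seeds stay non-significant
  set.seed(32)
  ps <- replicate(60, {
    b <- rnorm(6, 100, 0.5)
    group_response_test(b, b + rnorm(6, 0, 0.5))$p
  })
  expect_gte(mean(ps > 0.05), 0.9)

  expect_error(group_response_test(1:2, 1:2), ">= 3")
})
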