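test_that("all generators are bit-identical under a fixed seed", {
  expect_identical(sample_headings(50, 132, 1, seed = 5)$angles,
                   sample_headings(50, 132, 1, seed = 5)$angles)
  expect_false(identical(sample_headings(50, 132, 1, seed = 5)$angles,
                         sample_headings(50, 132, 1, seed = 6)$angles))

  expect_identical(simulate_assay_counts(8, 0.6, seed = 3),
                   simulate_assay_counts(8, 0.6, seed = 3))

  ep <- data.frame(onset_s = 12.5, duration_s = 6, amplitude_pct = 2)
  expect_identical(simulate_trace(ep, noise_sd = 0.5, seed = 9),
                   simulate_trace(ep, noise_sd = 0.5, seed = 9))
  expect_false(identical(simulate_trace(ep, noise_sd = 0.5, seed = 9)$trace,
                         simulate_trace(ep, noise_sd = 0.5, seed = 10)$trace))

  f <- synthetic_isolate_fields()
  expect_identical(simulate_isolate_table(f, 0.8, seed = 2),
                   simulate_isolate_table(f, 0.8, seed = 2))
})

test_that("seeded generation leaves the caller's RNG stream untouched", {
  set.seed(1234)
  before <- .Random.seed
  invisible(sample_headings(10, 0, 1, seed = 77))
  invisible(simulate_assay_counts(3, 0.5, seed = 77))
  expect_identical(.Random.seed, before)
})

test_that("von Mises headings cover the concentration extremes", {
  # huge kappa degenerates to the mean
  tight <- sample_headings(5, 210, kappa = 1e6, seed = 1)
  expect_true(all(abs(angular_difference(tight$angles, 210)) < 0.2))

  # kappa = 0 is circular-uniform: Rayleigh rarely rejects
  set.seed(88)
  p_uniform <- vapply(1:200, function(i) {
    rayleigh_test(sample_headings(300, 0, kappa = 0))$p
  }, numeric(1))
  expect_gte(mean(p_uniform > 0.05), 0.9)
  expect_lte(mean(p_uniform > 0.05), 0.99)

  expect_error(sample_headings(10, 0, kappa = -1), "kappa")
})

test_that("sampler concentration matches von Mises theory", {
  # empirical resultant length ~ A(kappa) = I1/I0 (Bessel-function oracle)
  for (kappa in c(0.5, 1, 2, 4)) {
    s <- sample_headings(5000, 132, kappa, seed = round(100 * kappa))
    expect_lt(abs(circular_summary(s)$R - vm_mean_resultant(kappa)), 0.025)
    expect_lt(abs(angular_difference(circular_summary(s)$mean_direction, 132)),
              3 * circ_mean_se_deg(vm_mean_resultant(kappa), 5000))
  }
})

test_that("assay-count generator reproduces binomial expectations", {
  all_a <- simulate_assay_counts(6, choice_probability = 1, seed = 1)
  expect_true(all(all_a$side_b == 0))
  expect_equal(magnetotaxis_index(all_a$side_a, all_a$side_b), rep(1, 6))

  big <- simulate_assay_counts(5000, choice_probability = 0.5,
                               worms_per_assay = 50, seed = 2)
  expect_lt(abs(mean((big$side_a - big$side_b) / (big$side_a + big$side_b))),
            0.01)

  ten <- simulate_assay_counts(10, choice_probability = 2 / 3,
                               worms_per_assay = 50, seed = 3)
  expect_lt(abs(aggregate_indices(ten)$mean_index - 1 / 3), 0.1)

  # arrivals respect the arrival fraction
  part <- simulate_assay_counts(2000, 0.5, worms_per_assay = 48,
                                arrival_fraction = 0.5, seed = 4)
  expect_lt(abs(mean(part$side_a + part$side_b) - 24), 0.5)

  expect_error(simulate_assay_counts(5, 1.2), "choice_probability")
  expect_error(simulate_assay_counts(5, 0.5, arrival_fraction = -0.1),
               "arrival_fraction")
})

test_that("trace generator enforces epoch geometry and positivity", {
  bad_late <- data.frame(onset_s = 48, duration_s = 6, amplitude_pct = 2)
  expect_error(simulate_trace(bad_late), "within")
  bad_overlap <- data.frame(onset_s = c(10, 12), duration_s = 6,
                            amplitude_pct = 2)
  expect_error(simulate_trace(bad_overlap), "overlap")

  sim <- simulate_trace(data.frame(onset_s = 12.5, duration_s = 6,
                                   amplitude_pct = 2),
                        noise_sd = 1, sample_rate = 3.5, seed = 6)
  expect_true(all(sim$trace$intensity > 0))
  expect_equal(max(sim$trace$time_s), 50, tolerance = 1 / 3.5)
  # nominal 50 s at 3.5 Hz
  expect_equal(nrow(sim$trace), length(seq(0, 50, by = 1 / 3.5)))
})

test_that("the alpha-kernel transient is smooth but boxcar round-trips", {
  ep <- data.frame(onset_s = 12.5, duration_s = 6, amplitude_pct = 2)
  box <- simulate_trace(ep, noise_sd = 0, kernel = "boxcar")
  alpha <- simulate_trace(ep, noise_sd = 0, kernel = "alpha")
  corr_box <- bleach_correct(box$trace, protect_epochs(box$epochs))
  expect_equal(windowed_response(corr_box, 12.5, 6)$delta_percent, 2,
               tolerance = 1e-9)
  # the alpha kernel spreads the transient, so the window mean is lower
  corr_a <- bleach_correct(alpha$trace, protect_epochs(alpha$epochs, 20))
  ra <- windowed_response(corr_a, 12.5, 6)$delta_percent
  expect_gt(ra, 0.5)
  expect_lt(ra, 2)
})

test_that("isolate tables couple the index to the chosen predictor only", {
  fields <- synthetic_isolate_fields(11)
  exact <- simulate_isolate_table(fields, slope = 0.9, noise_sd = 0)
  expect_equal(correlate_performance(exact, "vertical")$r, 1, tolerance = 1e-9)
  expect_equal(sum(exact$holdout), 1L)

  # horizontal is symmetric in the vertical component, so it carries no
  # linear signal about an index generated from the vertical component
  noisy <- simulate_isolate_table(fields, slope = 0.9, noise_sd = 0.05,
                                  seed = 44)
  expect_lt(abs(correlate_performance(noisy, "horizontal")$r), 0.5)
  expect_gt(abs(correlate_performance(noisy, "vertical")$r), 0.9)

  expect_error(simulate_isolate_table(fields[1:3, ], 0.9), "nrow")
  expect_error(simulate_isolate_table(fields, 0.9, holdout_index = 99),
               "holdout_index")
  expect_true(all(abs(simulate_isolate_table(fields, slope = 10,
                                             noise_sd = 0, seed = 1)$mi_mean)
                  <= 1))
})
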