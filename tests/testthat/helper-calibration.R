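# Monte Carlo calibration drivers shared between module tests and the
# acceptance suite. All take an explicit seed and restore nothing: callers
# wrap them in set.seed().

# p-values of the Rayleigh test over `reps` uniform samples of size n
mc_rayleigh_pvalues <- function(reps, n) {
  vapply(seq_len(reps), function(i) {
    rayleigh_test(runif(n, 0, 360))$p
  }, numeric(1))
}

# V-test p-values under a rotated uniform null: each replicate draws a
# uniform heading sample and an arbitrary expected direction
mc_vtest_pvalues <- function(reps, n) {
  vapply(seq_len(reps), function(i) {
    v_test(runif(n, 0, 360), expected_direction = runif(1, 0, 360))$p
  }, numeric(1))
}

# rejection rate of the index-vs-zero test when worms choose at random
mc_index_null_rejections <- function(reps, n_assays = 10, worms = 50,
                                     alpha = 0.05) {
  hits <- vapply(seq_len(reps), function(i) {
    counts <- simulate_assay_counts(n_assays, choice_probability = 0.5,
                                    worms_per_assay = worms)
    aggregate_indices(counts)$p_vs_zero < alpha
  }, logical(1))
  mean(hits)
}
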