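# Ground truths used across the suite: the bamboo study conditions with and
# without noise.

bamboo_truth <- function(...) ground_truth(...)

noiseless_truth <- function(...) ground_truth(noise_fraction = 0, ...)

# true equatorial peak positions under the default cell
true_q <- function(hkl, truth = noiseless_truth()) {
  tab <- truth_peak_table(truth)
  tab$q0[tab$hkl == hkl]
}

expect_rel_equal <- function(actual, expected, rel_tol) {
  expect_lt(max(abs(actual - expected) / abs(expected)), rel_tol)
}
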