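# small fixtures built in code, shared across test files

tinyGrid <- function(n_freq = 5, n_level = 2, n_trial = 4, spacing_oct = 0.5) {
  StimulusGrid(1000 * 2^(spacing_oct * (seq_len(n_freq) - 1)),
               seq(30, by = 20, length.out = n_level),
               n_trials = n_trial)
}

# deterministic [n_freq x n_level x n_trial] tensor with per-cell means mu
tensorFromMeans <- function(mu, n_trial, noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- dim(mu)
  arr <- array(rep(as.vector(mu), n_trial), dim = c(d, n_trial))
  if (noise_sd > 0) arr <- arr + rnorm(length(arr), 0, noise_sd)
  arr
}

# brute-force count of connected suprathreshold regions in a profile
regionCount <- function(profile, thr) {
  above <- profile > thr
  sum(diff(c(FALSE, above)) == 1)
}

sensitiveOnlyMix <- function() {
  c(single = 0.43, double = 0.32, complex = 0.25, nonsensitive = 0)
}
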