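# Shared fixture builders for the test suite (everything is generated in
# code; no binary fixtures).

# a small synthetic calibration used throughout the nanopore tests
test_calibration <- function() synthetic_power_law_calibration()

# build a trace by injecting rectangular dips into Gaussian noise directly,
# bypassing gen_trace, so detection tests control depth/duration exactly
inject_trace <- function(onsets_s, durations_s, depths_pa,
                         baseline_pa = 1000, noise_sd_pa = 1,
                         fs = 200000, duration_s = 1, seed = 42) {
  set.seed(seed)
  n <- round(duration_s * fs)
  x <- baseline_pa + rnorm(n, sd = noise_sd_pa)
  for (k in seq_along(onsets_s)) {
    i0 <- round(onsets_s[k] * fs) + 1L
    i1 <- i0 + round(durations_s[k] * fs) - 1L
    x[i0:i1] <- x[i0:i1] - depths_pa[k]
  }
  current_trace(x, sampling_hz = fs, source = "injected")
}

# independent mass-weighted mean oracle
mass_weighted_mw <- function(mw) sum(mw^2) / sum(mw)
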