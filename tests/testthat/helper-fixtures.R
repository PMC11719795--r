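# Shared fixture builders; everything is generated in code at test time.

# A recording with a given X trace (Y/Z default to scaled copies), 100 Hz.
make_rec <- function(omega_x, fs = 100, test_id = "fix",
                     omega_y = 0.3 * omega_x, omega_z = 0.2 * omega_x,
                     meta = list()) {
  n <- length(omega_x)
  gyro_recording(test_id, t = (seq_len(n) - 1) / fs, omega_x = omega_x,
                 omega_y = omega_y, omega_z = omega_z,
                 sample_rate_hz = fs, meta = meta)
}

extdata <- function(f) {
  p <- system.file("extdata", f, package = "pivotshift")
  stopifnot(nzchar(p))
  p
}

# Independent O(n^2) DFT oracle for spectrum tests.
naive_dft_magnitude <- function(x) {
  n <- length(x)
  sapply(0:(n %/% 2), function(k) {
    Mod(sum(x * exp(-2i * pi * k * (0:(n - 1)) / n)))
  })
}

# Features + labels for a small simulated cohort (shared by classify tests).
cohort_features <- function(n, seed, cfg = simulation_config()) {
  ds <- simulate_cohort(n, cfg = cfg, seed = seed)
  X <- t(vapply(ds$recordings, extract_features,
                numeric(length(all_feature_names()))))
  list(X = X, manifest = ds$manifest, dataset = ds)
}
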