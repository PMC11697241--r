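# Shared fixtures and independent brute-force oracles.

# Small, fast protocol for tests that only need the structure (band up to
# 100 Hz needs fs >= 200; 2 kHz keeps segment traces light).
tiny_protocol <- function(seed = 1, rheobase_pa = 100, fs = 2000, ...) {
  stimulus_protocol(noise_template(seed, sampling_rate_hz = fs),
                    rheobase_pa = rheobase_pa, ...)
}

# O(n*m) nearest-spike oracle, independent of the findInterval path.
brute_nearest <- function(a, b) {
  vapply(a, function(t) min(abs(t - b)), numeric(1))
}

brute_matching_fraction <- function(a, b, window_ms) {
  mean(vapply(a, function(t) any(abs(t - b) <= window_ms / 1000),
              logical(1)))
}

# Random sorted spike train in [0, t_max].
random_train <- function(n, t_max = 3) sort(stats::runif(n, 0, t_max))

# Sweep set of independent uniform-random trains (the firing-rate null).
null_sweep_set <- function(id, n_sweeps, mean_count, window = c(0, 3)) {
  sweeps <- lapply(seq_len(n_sweeps), function(k) {
    n <- stats::rpois(1, mean_count)
    sort(stats::runif(n, window[1], window[2]))
  })
  sweep_set(id, "Noise1", 100, sweeps, stimulus_window_s = window)
}

# Gaussian action-potential waveform with a given half-amplitude width.
gaussian_spike <- function(width_us, fs = 2e5, amp_mv = 80,
                           baseline_mv = -65, span_ms = 4) {
  sd_s <- width_us * 1e-6 / (2 * sqrt(2 * log(2)))
  t <- seq(-span_ms / 2, span_ms / 2, by = 1000 / fs) / 1000
  spike_waveform(baseline_mv + amp_mv * exp(-t^2 / (2 * sd_s^2)), fs)
}
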