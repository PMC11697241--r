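test_that("noise template hits its CV target and is frozen by seed", {
  tpl <- noise_template(seed = 7, sampling_rate_hz = 2000)
  expect_equal(mean(tpl$samples), 0, tolerance = 1e-12)
  # after the unit DC offset: sd / mean = cv
  expect_equal(sd(tpl$samples) / (mean(tpl$samples) + 1), 0.2,
               tolerance = 1e-9)
  expect_identical(tpl$samples,
                   noise_template(seed = 7, sampling_rate_hz = 2000)$samples)
  expect_false(identical(
    tpl$samples, noise_template(seed = 8, sampling_rate_hz = 2000)$samples))
  expect_error(noise_template(1, duration_s = -1), "positive")
  expect_error(noise_template(1, cv = 0), "positive")
  expect_error(noise_template(1, f_max_hz = 100, sampling_rate_hz = 150),
               "Nyquist")
})

test_that("single-band template is a zero-mean sinusoid", {
  tpl <- noise_template(seed = 3, f_min_hz = 10, f_max_hz = 10,
                        sampling_rate_hz = 1000)
  expect_equal(mean(tpl$samples), 0, tolerance = 1e-12)
  # a pure sinusoid crosses zero 2 f T times
  expect_equal(sum(diff(sign(tpl$samples)) != 0), 20, tolerance = 1)
})

test_that("spectral power falls as 1/f", {
  tpl <- noise_template(seed = 11, sampling_rate_hz = 1000)
  p <- Mod(stats::fft(tpl$samples))^2
  f <- (seq_along(p) - 1) * 1000 / length(p)
  # amplitude ~ 1/sqrt(f) => power at 10 Hz / power at 20 Hz = 2
  ratio <- p[which.min(abs(f - 10))] / p[which.min(abs(f - 20))]
  expect_equal(ratio, 2, tolerance = 0.05)
  # log-log slope -1, and invariant to the sampling rate
  expect_equal(spectral_slope(tpl), -1, tolerance = 0.05)
  expect_equal(spectral_slope(noise_template(11, sampling_rate_hz = 5000)),
               -1, tolerance = 0.05)
})

test_that("protocol has ordered 3 s segments with exact rheobase scaling", {
  prot <- tiny_protocol(seed = 2, rheobase_pa = 100)
  st <- prot$segment_table
  expect_equal(st$label, c(75, 100, 150))
  expect_equal(st$end_s - st$start_s, rep(3, 3))
  fs <- prot$sampling_rate_hz
  seg <- function(i) {
    prot$trace[seq(st$start_s[i] * fs + 1, st$end_s[i] * fs)]
  }
  # mean current of the 150 % segment = 1.5 x rheobase
  expect_equal(mean(seg(3)), 150, tolerance = 1e-9)
  # within-segment periodicity: samples 1 s and 2 s apart are identical
  s3 <- seg(3)
  expect_identical(s3[1:fs], s3[fs + 1:fs])
  expect_identical(s3[1:fs], s3[2 * fs + 1:fs])
  # recovery windows carry zero current
  gap <- prot$trace[seq(st$end_s[1] * fs + 1, st$start_s[2] * fs)]
  expect_true(all(gap == 0))
  expect_error(stimulus_protocol(noise_template(1, sampling_rate_hz = 2000),
                                 rheobase_pa = -5), "positive")
  expect_error(tiny_protocol(intensities = c(0.5, -1)), "positive")
})

test_that("identity scaling and linearity in rheobase hold", {
  tpl <- noise_template(seed = 4, sampling_rate_hz = 1000)
  p1 <- stimulus_protocol(tpl, rheobase_pa = 1)
  fs <- 1000
  st <- p1$segment_table
  mid <- p1$trace[seq(st$start_s[2] * fs + 1, st$end_s[2] * fs)]
  expect_equal(mid, rep(tpl$samples, 3) + 1, tolerance = 1e-12)
  p3 <- stimulus_protocol(tpl, rheobase_pa = 3)
  expect_equal(p3$trace, 3 * p1$trace, tolerance = 1e-12)
})

test_that("autocorrelation is normalized and peaks at the template period", {
  tpl <- noise_template(seed = 5, sampling_rate_hz = 2000)
  stim <- rep(tpl$samples, 3) + 1
  ac <- trace_autocorrelation(stim, 1.2, 2000)
  expect_equal(ac$acf[1], 1)
  inner <- ac$acf[ac$lag_s > 0.5]
  expect_equal(ac$lag_s[ac$lag_s > 0.5][which.max(inner)], 1,
               tolerance = 1e-9)
  expect_error(trace_autocorrelation(rep(2, 100), 0.01, 1000), "constant")
  expect_error(trace_autocorrelation(stim, 10, 2000), "exceeds")
})
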