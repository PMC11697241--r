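test_that("nearest-spike latencies match direct minima and the brute oracle", {
  a <- c(0.010, 0.020, 0.030)
  b <- c(0.0105, 0.025, 0.0302)
  expect_equal(nearest_spike_latencies(a, b), c(0.0005, 0.005, 0.0002))
  expect_equal(nearest_spike_latencies(a, a), c(0, 0, 0))
  expect_error(nearest_spike_latencies(a, numeric(0)), "empty")
  set.seed(41)
  for (r in 1:200) {
    x <- random_train(sample(1:30, 1))
    y <- random_train(sample(1:30, 1))
    expect_equal(nearest_spike_latencies(x, y), brute_nearest(x, y))
  }
})

test_that("latency CDF is a proper CDF under both estimators", {
  g <- seq(0, 0.01, by = 0.0005)
  expect_equal(latency_cdf(rep(0, 5), g), rep(1, length(g)))
  set.seed(2)
  u <- runif(1e5, 0, 0.001)
  expect_equal(latency_cdf(u, 0.0005), 0.5, tolerance = 0.01)
  x <- rexp(500, 1000)
  for (m in c("empirical", "gaussian-kernel")) {
    cdf <- latency_cdf(x, g, method = m)
    expect_true(all(diff(cdf) >= 0))
    expect_true(all(cdf >= 0 & cdf <= 1))
  }
  expect_error(latency_cdf(numeric(0), g), "non-empty")
})

test_that("matching fraction counts coincidences inclusively", {
  expect_equal(matching_fraction(c(0.010, 0.020, 0.030),
                                 c(0.0105, 0.025, 0.0302), 1), 2 / 3)
  expect_equal(matching_fraction(c(0.1, 0.2), c(0.1, 0.2), 1), 1)
  expect_equal(matching_fraction(c(0.1, 0.2), c(1.5), 1e7), 1)
  expect_equal(matching_fraction(0, 0.001, 1), 1)    # |dt| == window matches
  expect_equal(matching_fraction(0, 0.0011, 1), 0)
  expect_error(matching_fraction(numeric(0), 0.1, 1), "empty")
  set.seed(5)
  for (r in 1:100) {
    x <- random_train(sample(1:20, 1))
    y <- random_train(sample(1:20, 1))
    expect_equal(matching_fraction(x, y, 2), brute_matching_fraction(x, y, 2))
    # non-decreasing in the window
    w <- sort(runif(4, 0.1, 50))
    f <- vapply(w, function(wi) matching_fraction(x, y, wi), numeric(1))
    expect_true(all(diff(f) >= 0))
  }
})

test_that("spiking reliability averages ordered pairs and needs 2 sweeps", {
  tr <- list(c(0.1, 0.5), c(0.1, 0.5), c(0.1, 0.5))
  expect_equal(spiking_reliability(tr), 1)
  expect_equal(spiking_reliability(list(c(0.1), c(0.5))), 0)
  expect_error(spiking_reliability(list(c(0.1))), "at least 2")
  # zero-spike sweeps are excluded from pair formation
  expect_equal(spiking_reliability(list(c(0.1, 0.5), numeric(0),
                                        c(0.1, 0.5))), 1)
  expect_error(spiking_reliability(list(numeric(0), c(0.1))), "at least 2")
})

test_that("reliability expectation does not depend on the trial count", {
  # i.i.d. jittered sweeps: the mean over ordered pairs has the same
  # expectation for 2 and for 8 trials (the estimator is unbiased in n).
  prot <- tiny_protocol(seed = 3)
  tmpl <- segment_trains(prot, template_spike_train(prot, 10, seed = 8))[["100"]]
  cl <- cell_class("x", jitter_sd_ms = 1.5)
  draw <- function(n, seed) {
    sweeps <- lapply(derive_seeds(seed, n), function(s) {
      jitter_spike_train(tmpl, cl, s)
    })
    spiking_reliability(sweeps, 1)
  }
  m2 <- mean(vapply(1:300, function(s) draw(2, s), numeric(1)))
  m8 <- mean(vapply(301:450, function(s) draw(8, s + 1000), numeric(1)))
  expect_equal(m2, m8, tolerance = 0.03)
})

test_that("firing-rate correction recovers near-1 for frozen sparse trains", {
  tr <- c(0.5, 1.0, 1.5, 2.0, 2.5)
  ss <- sweep_set("n1", "Noise1", 100, list(tr, tr, tr))
  r <- corrected_reliability(ss, 1, 100, seed = 5)
  expect_equal(r$raw_reliability, 1)
  expect_gt(r$corrected_reliability, 0.99)
  expect_true(r$shuffled_mean >= 0 && r$shuffled_mean <= 1)
  expect_equal(r$n_pairs, 6L)
  # determinism and the raw - shuffled identity
  r2 <- corrected_reliability(ss, 1, 100, seed = 5)
  expect_identical(r$corrected_reliability, r2$corrected_reliability)
  expect_equal(r$corrected_reliability,
               r$raw_reliability - r$shuffled_mean)
  expect_error(corrected_reliability(ss, 1, 0), "positive")
})

test_that("corrected reliability decreases with jitter in expectation", {
  sigmas <- c(0, 0.5, 2, 10)
  means <- matrix(NA_real_, 3, length(sigmas))
  prot <- tiny_protocol(seed = 1)
  for (s in 1:3) {
    tmpl <- segment_trains(prot,
                           template_spike_train(prot, 12, seed = s))[["100"]]
    for (k in seq_along(sigmas)) {
      cl <- cell_class("x", jitter_sd_ms = sigmas[k])
      vals <- vapply(1:6, function(i) {
        sweeps <- lapply(derive_seeds(s * 100 + i, 4), function(sd) {
          jitter_spike_train(tmpl, cl, sd)
        })
        ss <- sweep_set("n", "Noise1", 100, sweeps)
        corrected_reliability(ss, 1, 30, seed = i)$corrected_reliability
      }, numeric(1))
      means[s, k] <- mean(vals)
    }
  }
  expect_true(all(diff(colMeans(means)) < 0))
})

test_that("subthreshold reliability is rank-based and null-calibrated", {
  set.seed(31)
  v <- cumsum(rnorm(2000))
  expect_equal(subthreshold_reliability(list(v, v)), 1)
  expect_equal(subthreshold_reliability(list(v, exp(v / 10))), 1)
  traces <- lapply(1:4, function(i) rnorm(1e4))
  expect_lt(abs(subthreshold_reliability(traces)), 0.05)
  expect_error(subthreshold_reliability(list(v, v[-1])), "equal lengths")
  expect_warning(
    r <- subthreshold_reliability(list(v, v, rep(1, 2000))), "constant")
  expect_equal(r, 1)
  expect_error(
    suppressWarnings(subthreshold_reliability(list(v, rep(1, 2000)))),
    "usable")
})
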