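test_that("template trains follow the stimulus and are frozen by seed", {
  prot <- tiny_protocol(seed = 2)
  counts <- vapply(1:200, function(s) {
    length(template_spike_train(prot, 5, seed = s))
  }, numeric(1))
  # Poisson mean = rate x total stimulus duration (9 s)
  expect_equal(mean(counts), 45, tolerance = 3 * sd(counts) / sqrt(200))
  tr <- template_spike_train(prot, 10, seed = 1)
  expect_identical(tr, template_spike_train(prot, 10, seed = 1))
  # no spikes in the zero-current recovery windows
  st <- prot$segment_table
  in_seg <- rep(FALSE, length(tr))
  for (i in seq_len(nrow(st))) {
    in_seg <- in_seg | (tr >= st$start_s[i] & tr < st$end_s[i])
  }
  expect_true(all(in_seg))
  expect_error(template_spike_train(prot, 0, 1), "positive")
})

test_that("segment slicing re-references spike times to segment onset", {
  prot <- tiny_protocol(seed = 2)
  tr <- template_spike_train(prot, 10, seed = 3)
  segs <- segment_trains(prot, tr)
  expect_named(segs, c("75", "100", "150"))
  expect_true(all(unlist(segs) >= 0 & unlist(segs) < 3))
  expect_equal(sum(lengths(segs)), length(tr))
})

test_that("jittering applies deletion, Gaussian shifts and extras", {
  tmpl <- c(0.5, 1, 1.5, 2)
  cl0 <- cell_class("id", jitter_sd_ms = 0)
  expect_identical(jitter_spike_train(tmpl, cl0, seed = 1), tmpl)
  cl_del <- cell_class("del", 0, spike_deletion_prob = 1,
                       extra_spike_rate_hz = 2)
  out <- jitter_spike_train(tmpl, cl_del, seed = 2)
  expect_true(all(!out %in% tmpl))
  # mean |shift| of a Gaussian jitter = sd * sqrt(2/pi) (half-normal mean);
  # spikes are spaced far apart so sorting cannot swap neighbours
  cl_j <- cell_class("j", jitter_sd_ms = 2)
  tmpl_sparse <- seq(0.05, 2.95, length.out = 200)
  shifts <- unlist(lapply(1:10, function(s) {
    abs(jitter_spike_train(tmpl_sparse, cl_j, seed = s) - tmpl_sparse)
  }))
  expect_equal(mean(shifts), 0.002 * sqrt(2 / pi), tolerance = 0.05)
})

test_that("populations respect repetition bounds and frozen-noise metadata", {
  pop <- simulate_population(default_cell_classes()[c(1, 4)], 3, seed = 9,
                             sampling_rate_hz = 2000)
  expect_s3_class(pop, "neuron_population")
  expect_length(pop, 6)
  for (nr in pop) {
    reps <- vapply(nr$sweep_sets, function(s) length(s$sweeps), 1L)
    expect_true(all(reps >= 2 & reps <= 8))
    expect_equal(sort(unique(vapply(nr$sweep_sets, `[[`, 1, "intensity_pct"))),
                 c(75, 100, 150))
    expect_setequal(vapply(nr$sweep_sets, `[[`, "", "noise_id"),
                    c("Noise1", "Noise2"))
    for (s in nr$sweep_sets) expect_equal(s$stimulus_window_s, c(0, 3))
    expect_named(nr$intrinsic_features,
                 c("membrane_tau_ms", "rheobase_pa",
                   "upstroke_downstroke_ratio", "ramp_time_to_spike_s",
                   "capacitance_pf", "conductance_ns"))
  }
  expect_error(simulate_population(default_cell_classes(), 0), ">= 1")
  # reproducibility of the full population under the master seed
  pop2 <- simulate_population(default_cell_classes()[c(1, 4)], 3, seed = 9,
                              sampling_rate_hz = 2000)
  expect_identical(pop[[1]]$sweep_sets[[2]]$sweeps,
                   pop2[[1]]$sweep_sets[[2]]$sweeps)
  expect_identical(pop[[4]]$intrinsic_features, pop2[[4]]$intrinsic_features)
})

test_that("low-jitter classes recover higher corrected reliability", {
  cls <- list(cell_class("tight", 0.2, 0.05, 0.5, 15, 8, 220),
              cell_class("loose", 5, 0.15, 1.5, 8, 25, 90))
  pop <- simulate_population(cls, 8, seed = 21, sampling_rate_hz = 2000)
  tab <- reliability_table(pop, 1, 30, 100, seed = 3)
  m <- tapply(tab$corrected, tab$class_name, mean)
  expect_gt(m[["tight"]], m[["loose"]])
  expect_true(all(tab$raw >= 0 & tab$raw <= 1))
  expect_true(all(tab$corrected >= -1 & tab$corrected <= 1))
})

test_that("voltage traces share stimulus-driven structure across sweeps", {
  cl <- cell_class("v", 1, mean_rate_hz = 8)
  pop <- simulate_population(list(cl), 2, seed = 5, sampling_rate_hz = 2000,
                             with_voltage = TRUE, voltage_intensity = 75,
                             shared_variance_frac = 0.7)
  s75 <- Filter(function(s) s$intensity_pct == 75, pop[[1]]$sweep_sets)[[1]]
  expect_false(is.null(s75$voltage))
  expect_length(s75$voltage, length(s75$sweeps))
  r <- subthreshold_reliability(s75)
  expect_gt(r, 0.3)   # shared fraction 0.7 induces clear rank correlation
  expect_lt(r, 1)
})

test_that("population round-trips through the plain-text format", {
  pop <- simulate_population(default_cell_classes()[c(1, 4)], 2, seed = 11,
                             sampling_rate_hz = 2000, with_voltage = TRUE)
  dir <- file.path(tempdir(), "popio")
  write_population(pop, dir)
  back <- read_population(dir)
  expect_length(back, length(pop))
  for (i in seq_along(pop)) {
    expect_identical(back[[i]]$neuron_id, pop[[i]]$neuron_id)
    expect_identical(back[[i]]$transcriptomic_group,
                     pop[[i]]$transcriptomic_group)
    for (k in seq_along(pop[[i]]$sweep_sets)) {
      expect_identical(back[[i]]$sweep_sets[[k]]$sweeps,
                       pop[[i]]$sweep_sets[[k]]$sweeps)
    }
  }
  # voltage round-trips numerically
  v0 <- Filter(function(s) !is.null(s$voltage), pop[[1]]$sweep_sets)[[1]]
  v1 <- Filter(function(s) !is.null(s$voltage), back[[1]]$sweep_sets)[[1]]
  expect_equal(v1$voltage[[1]], v0$voltage[[1]])
  unlink(dir, recursive = TRUE)
})

test_that("protocol files round-trip bit-exactly", {
  prot <- tiny_protocol(seed = 6, fs = 500)
  prefix <- file.path(tempdir(), "prot1")
  write_protocol(prot, prefix)
  back <- read_protocol(prefix)
  expect_identical(back$trace, prot$trace)
  expect_identical(back$time_s, prot$time_s)
  expect_equal(as.data.frame(back$segment_table),
               as.data.frame(prot$segment_table))
  expect_equal(back$rheobase_pa, prot$rheobase_pa)
  unlink(paste0(prefix, c(".csv", ".json")))
})
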