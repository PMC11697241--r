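# Synthetic sweep populations with known reliability structure.
#
# Ground-truth spike trains are inhomogeneous-Poisson draws whose intensity
# follows the positive part of the frozen-noise stimulus; per-sweep
# variability is injected solely through Gaussian timing jitter, random
# spike deletion, and homogeneous extra spikes. Keeping jitter/deletion as
# the only reliability knobs makes parameter recovery by the metrics module
# directly interpretable.

#' Define a synthetic cell class
#'
#' @param name class label, e.g. `"PV-like"`.
#' @param jitter_sd_ms SD of the Gaussian spike-timing jitter (ms, >= 0);
#'   the sole driver of timing reliability.
#' @param spike_deletion_prob probability that a ground-truth spike is
#'   missing from a sweep.
#' @param extra_spike_rate_hz rate of homogeneous spurious spikes added
#'   within the stimulus window.
#' @param mean_rate_hz mean firing rate at 100 % rheobase.
#' @param membrane_tau_ms,rheobase_pa class-typical intrinsic features;
#'   per-neuron values are drawn lognormally around them.
#' @param n_repetitions_range integer pair within \[2, 8\]; repetition counts
#'   per noise are drawn uniformly in this range.
#' @param transcriptomic_group one of `"PV"`, `"non-PV inhibitory"`,
#'   `"mixed"`, `"excitatory"`.
#' @param morpho_type one of `"aspiny"`, `"sparsely spiny"`, `"spiny"`.
#' @param spike_width_us stereotyped action-potential half-width used when
#'   voltage traces are synthesized and for the ground-truth fast/regular
#'   annotation (< 400 us = fast).
#' @return an object of class `cell_class`.
#' @export
cell_class <- function(name, jitter_sd_ms, spike_deletion_prob = 0,
                       extra_spike_rate_hz = 0, mean_rate_hz = 10,
                       membrane_tau_ms = 20, rheobase_pa = 100,
                       n_repetitions_range = c(2L, 8L),
                       transcriptomic_group = "excitatory",
                       morpho_type = "spiny",
                       spike_width_us = 500) {
  check_scalar(jitter_sd_ms, "jitter_sd_ms", nonneg = TRUE)
  check_prob(spike_deletion_prob, "spike_deletion_prob")
  check_scalar(extra_spike_rate_hz, "extra_spike_rate_hz", nonneg = TRUE)
  check_scalar(mean_rate_hz, "mean_rate_hz", positive = TRUE)
  check_scalar(membrane_tau_ms, "membrane_tau_ms", positive = TRUE)
  check_scalar(rheobase_pa, "rheobase_pa", positive = TRUE)
  check_scalar(spike_width_us, "spike_width_us", positive = TRUE)
  r <- as.integer(n_repetitions_range)
  if (length(r) != 2L || r[1] > r[2] || r[1] < 2L || r[2] > 8L) {
    stop("`n_repetitions_range` must be an integer pair within [2, 8]",
         call. = FALSE)
  }
  structure(
    list(name = name, jitter_sd_ms = jitter_sd_ms,
         spike_deletion_prob = spike_deletion_prob,
         extra_spike_rate_hz = extra_spike_rate_hz,
         mean_rate_hz = mean_rate_hz, membrane_tau_ms = membrane_tau_ms,
         rheobase_pa = rheobase_pa, n_repetitions_range = r,
         transcriptomic_group = transcriptomic_group,
         morpho_type = morpho_type, spike_width_us = spike_width_us),
    class = "cell_class"
  )
}

#' Default synthetic cell classes
#'
#' Four classes mirroring the transcriptomic grouping of cortical neurons:
#' fast-spiking PV-like cells with sub-millisecond jitter, non-PV inhibitory
#' and mixed cells with intermediate jitter, and regular-spiking
#' excitatory-like cells with several milliseconds of jitter. Intrinsic
#' features co-vary with jitter so that feature-reliability correlations
#' with the signs observed in cortex (e.g. reliability falling with membrane
#' time constant) are embedded by construction.
#'
#' @return named list of [cell_class()] objects.
#' @export
default_cell_classes <- function() {
  list(
    `PV-like` = cell_class("PV-like", jitter_sd_ms = 0.2,
                           spike_deletion_prob = 0.05,
                           extra_spike_rate_hz = 0.5, mean_rate_hz = 15,
                           membrane_tau_ms = 8, rheobase_pa = 220,
                           transcriptomic_group = "PV",
                           morpho_type = "aspiny", spike_width_us = 250),
    `nonPV-like` = cell_class("nonPV-like", jitter_sd_ms = 2,
                              spike_deletion_prob = 0.1,
                              extra_spike_rate_hz = 1, mean_rate_hz = 10,
                              membrane_tau_ms = 16, rheobase_pa = 130,
                              transcriptomic_group = "non-PV inhibitory",
                              morpho_type = "aspiny", spike_width_us = 450),
    `mixed-like` = cell_class("mixed-like", jitter_sd_ms = 3,
                              spike_deletion_prob = 0.1,
                              extra_spike_rate_hz = 1, mean_rate_hz = 9,
                              membrane_tau_ms = 20, rheobase_pa = 110,
                              transcriptomic_group = "mixed",
                              morpho_type = "sparsely spiny",
                              spike_width_us = 500),
    `excitatory-like` = cell_class("excitatory-like", jitter_sd_ms = 5,
                                   spike_deletion_prob = 0.15,
                                   extra_spike_rate_hz = 1.5,
                                   mean_rate_hz = 8, membrane_tau_ms = 25,
                                   rheobase_pa = 90,
                                   transcriptomic_group = "excitatory",
                                   morpho_type = "spiny",
                                   spike_width_us = 550)
  )
}

#' Ground-truth spike train from a stimulus protocol
#'
#' Inhomogeneous Poisson draw whose intensity is proportional to the
#' positive part of the stimulus current within the stimulus segments and
#' zero in recovery windows; the expected total count equals
#' `mean_rate_hz` times the total stimulus duration.
#'
#' @param protocol a [stimulus_protocol()].
#' @param mean_rate_hz mean firing rate over the stimulus windows (> 0).
#' @param seed integer seed; identical seeds give identical trains.
#' @return sorted numeric vector of absolute spike times (s).
#' @export
template_spike_train <- function(protocol, mean_rate_hz, seed) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  check_scalar(mean_rate_hz, "mean_rate_hz", positive = TRUE)
  fs <- protocol$sampling_rate_hz
  w <- pmax(protocol$trace, 0)
  mask <- logical(length(w))
  st <- protocol$segment_table
  for (i in seq_len(nrow(st))) {
    idx <- seq(floor(st$start_s[i] * fs) + 1L, round(st$end_s[i] * fs))
    mask[idx] <- TRUE
  }
  w[!mask] <- 0
  if (all(w == 0)) stop("stimulus has no positive current", call. = FALSE)
  cw <- cumsum(w)
  total <- mean_rate_hz * stimulus_duration(protocol)
  with_seed(seed, {
    n <- stats::rpois(1L, total)
    u <- stats::runif(n, 0, cw[length(cw)])
    idx <- findInterval(u, cw) + 1L
    sort((idx - 1 + stats::runif(n)) / fs)
  })
}

#' Slice an absolute-time spike train into segment-relative trains
#'
#' @param protocol a [stimulus_protocol()].
#' @param times absolute spike times (s) over the protocol.
#' @return list (one element per segment, named by intensity label) of
#'   spike times relative to segment onset.
#' @export
segment_trains <- function(protocol, times) {
  st <- protocol$segment_table
  out <- lapply(seq_len(nrow(st)), function(i) {
    sel <- times >= st$start_s[i] & times < st$end_s[i]
    times[sel] - st$start_s[i]
  })
  names(out) <- as.character(st$label)
  out
}

#' Apply per-sweep variability to a ground-truth train
#'
#' Each template spike is independently deleted with
#' `spike_deletion_prob`; survivors are shifted by Gaussian noise with SD
#' `jitter_sd_ms`; homogeneous extra spikes at `extra_spike_rate_hz` are
#' added within the stimulus window. Shifted spikes are clamped to the
#' window (negligible for millisecond jitter against multi-second windows).
#'
#' @param template sorted spike-time vector (s), relative to window start.
#' @param class a [cell_class()].
#' @param seed integer seed.
#' @param window `(start, end)` stimulus window in seconds (default
#'   `c(0, 3)`).
#' @return sorted spike-time vector (s).
#' @export
jitter_spike_train <- function(template, class, seed, window = c(0, 3)) {
  stopifnot(inherits(class, "cell_class"))
  template <- sort(as.numeric(template))
  with_seed(seed, {
    keep <- stats::runif(length(template)) >= class$spike_deletion_prob
    kept <- template[keep]
    if (class$jitter_sd_ms > 0 && length(kept)) {
      kept <- kept + stats::rnorm(length(kept), 0, class$jitter_sd_ms / 1000)
      kept <- pmin(pmax(kept, window[1]), window[2])
    }
    extras <- if (class$extra_spike_rate_hz > 0) {
      n_extra <- stats::rpois(1L, class$extra_spike_rate_hz * diff(window))
      stats::runif(n_extra, window[1], window[2])
    } else numeric(0)
    sort(c(kept, extras))
  })
}

# Per-neuron intrinsic features derived from class-typical tau and rheobase
# plus lognormal noise; signs of the feature-reliability correlations are
# fixed by construction (small-jitter classes have short tau, high rheobase,
# low upstroke/downstroke ratio, long ramp time, low capacitance, high
# conductance).
draw_features <- function(class, seed) {
  with_seed(seed, {
    ln <- function(x, sd = 0.15) x * exp(stats::rnorm(1, 0, sd))
    tau <- ln(class$membrane_tau_ms)
    rheo <- ln(class$rheobase_pa)
    cap <- ln(12 * tau^0.7, 0.1)
    list(membrane_tau_ms = tau,
         rheobase_pa = rheo,
         upstroke_downstroke_ratio = ln(0.8 + 0.11 * tau, 0.1),
         ramp_time_to_spike_s = ln(1 + 25 / tau, 0.1),
         capacitance_pf = cap,
         conductance_ns = cap / tau)
  })
}

# Inhomogeneous Poisson train for a single protocol segment, returned
# relative to segment onset.
segment_template_train <- function(protocol, segment_index, rate_hz, seed) {
  st <- protocol$segment_table
  fs <- protocol$sampling_rate_hz
  idx <- seq(floor(st$start_s[segment_index] * fs) + 1L,
             round(st$end_s[segment_index] * fs))
  w <- pmax(protocol$trace[idx], 0)
  dur <- st$end_s[segment_index] - st$start_s[segment_index]
  cw <- cumsum(w)
  with_seed(seed, {
    n <- stats::rpois(1L, rate_hz * dur)
    u <- stats::runif(n, 0, cw[length(cw)])
    j <- findInterval(u, cw) + 1L
    sort((j - 1 + stats::runif(n)) / fs)
  })
}

# Exponential low-pass of a current trace (membrane filtering) followed by
# standardization; used as the shared component of synthetic voltage traces.
filtered_component <- function(trace, tau_ms, fs) {
  a <- exp(-1 / (tau_ms * 1e-3 * fs))
  v <- stats::filter((1 - a) * trace, a, method = "recursive")
  v <- as.numeric(v)
  s <- stats::sd(v)
  if (s == 0) return(numeric(length(v)))
  (v - mean(v)) / s
}

synth_voltage <- function(seg_trace, fs, class, spikes_s, seed,
                          shared_frac, amp_mv, rest_mv = -65) {
  shared <- filtered_component(seg_trace, class$membrane_tau_ms, fs)
  n <- length(shared)
  with_seed(seed, {
    a <- exp(-1 / (class$membrane_tau_ms * 1e-3 * fs))
    noise <- as.numeric(stats::filter(stats::rnorm(n), a, method = "recursive"))
    noise <- (noise - mean(noise)) / stats::sd(noise)
    v <- rest_mv + amp_mv * (sqrt(shared_frac) * shared +
                               sqrt(1 - shared_frac) * noise)
    if (length(spikes_s)) {
      sd_s <- class$spike_width_us * 1e-6 / (2 * sqrt(2 * log(2)))
      t <- (seq_len(n) - 1) / fs
      for (ts in spikes_s) {
        sel <- which(abs(t - ts) < 6 * sd_s)
        v[sel] <- v[sel] + 85 * exp(-(t[sel] - ts)^2 / (2 * sd_s^2))
      }
    }
    v
  })
}

#' Simulate a population of neurons with known reliability structure
#'
#' For each neuron: intrinsic features and rheobase are drawn around the
#' class-typical values; a repetition count per noise is drawn uniformly in
#' the class range; one ground-truth Poisson train is drawn per noise and
#' intensity; sweeps are jittered copies of it. The same two frozen-noise
#' templates (seeds `noise_seeds`) drive every neuron.
#'
#' @param classes list of [cell_class()] objects (a single class may be
#'   passed directly).
#' @param n_per_class neurons per class (>= 1).
#' @param seed master seed; per-neuron seeds are derived from it.
#' @param sampling_rate_hz protocol sampling rate (default 25000).
#' @param noise_seeds integer pair of frozen-noise seeds (default `c(1, 2)`).
#' @param intensities rheobase fractions (default `c(0.75, 1, 1.5)`).
#' @param rate_scale relative firing rate at each intensity (default
#'   `c(0.05, 1, 1.6)`: 75 % rheobase is just below threshold, 150 % drives
#'   more spikes).
#' @param species species label for every neuron (default `"mouse"`).
#' @param with_voltage also synthesize voltage traces (shared filtered
#'   stimulus + per-sweep noise + stereotyped spike waveforms).
#' @param voltage_intensity intensity (percent) at which voltage is
#'   synthesized (default 75, the subthreshold condition).
#' @param shared_variance_frac fraction of voltage variance shared across
#'   sweeps; sets the expected pairwise subthreshold correlation.
#' @param voltage_amp_mv SD of the subthreshold voltage fluctuation (mV).
#' @return object of class `neuron_population`: list of `neuron_record`s.
#' @export
simulate_population <- function(classes, n_per_class, seed = 1L,
                                sampling_rate_hz = 25000,
                                noise_seeds = c(1L, 2L),
                                intensities = c(0.75, 1, 1.5),
                                rate_scale = c(0.05, 1, 1.6),
                                species = "mouse",
                                with_voltage = FALSE,
                                voltage_intensity = 75,
                                shared_variance_frac = 0.7,
                                voltage_amp_mv = 2) {
  if (inherits(classes, "cell_class")) classes <- list(classes)
  stopifnot(length(classes) >= 1L,
            all(vapply(classes, inherits, logical(1), "cell_class")))
  if (!is.numeric(n_per_class) || n_per_class < 1) {
    stop("`n_per_class` must be >= 1", call. = FALSE)
  }
  if (length(rate_scale) != length(intensities)) {
    stop("`rate_scale` must match `intensities`", call. = FALSE)
  }

  # Frozen noise: one protocol per noise, shared by all neurons (unit
  # rheobase; the Poisson intensity is scale-invariant).
  protocols <- lapply(seq_along(noise_seeds), function(k) {
    stimulus_protocol(
      noise_template(noise_seeds[k], sampling_rate_hz = sampling_rate_hz),
      rheobase_pa = 1, intensities = intensities,
      noise_id = paste0("Noise", k))
  })

  n_total <- length(classes) * n_per_class
  neuron_seeds <- derive_seeds(seed, n_total)
  labels <- as.character(round(intensities * 100))

  pop <- vector("list", n_total)
  idx <- 0L
  for (ci in seq_along(classes)) {
    cl <- classes[[ci]]
    for (ni in seq_len(n_per_class)) {
      idx <- idx + 1L
      nid <- sprintf("%s_%03d", gsub("\\s+", "", cl$name), ni)
      sub <- derive_seeds(neuron_seeds[idx],
                          3L + length(protocols) *
                            (1L + 17L * length(intensities)))
      feats <- draw_features(cl, sub[1L])
      rheo <- feats$rheobase_pa
      s_at <- 3L
      sweep_sets <- list()
      for (pk in seq_along(protocols)) {
        prot <- protocols[[pk]]
        n_rep <- with_seed(sub[s_at <- s_at + 1L],
                           sample(seq(cl$n_repetitions_range[1],
                                      cl$n_repetitions_range[2]), 1L))
        for (ii in seq_along(intensities)) {
          tmpl <- segment_template_train(
            prot, ii, cl$mean_rate_hz * rate_scale[ii],
            sub[s_at <- s_at + 1L])
          dur <- prot$segment_table$end_s[ii] - prot$segment_table$start_s[ii]
          sweeps <- lapply(seq_len(n_rep), function(k) {
            jitter_spike_train(tmpl, cl, sub[s_at + k], window = c(0, dur))
          })
          s_at <- s_at + 8L
          volt <- NULL
          if (with_voltage && labels[ii] == as.character(voltage_intensity)) {
            fs <- prot$sampling_rate_hz
            seg_idx <- seq(floor(prot$segment_table$start_s[ii] * fs) + 1L,
                           round(prot$segment_table$end_s[ii] * fs))
            seg_trace <- prot$trace[seg_idx]
            volt <- lapply(seq_len(n_rep), function(k) {
              synth_voltage(seg_trace, fs, cl, sweeps[[k]],
                            sub[s_at + k], shared_variance_frac,
                            voltage_amp_mv)
            })
          }
          s_at <- s_at + 8L
          sweep_sets[[length(sweep_sets) + 1L]] <- sweep_set(
            nid, prot$noise_id, as.numeric(labels[ii]), sweeps,
            stimulus_window_s = c(0, dur), voltage = volt,
            sampling_rate_hz = if (is.null(volt)) NULL else
              prot$sampling_rate_hz)
        }
      }
      feats$rheobase_pa <- rheo
      pop[[idx]] <- structure(
        list(neuron_id = nid, species = species,
             morpho_type = cl$morpho_type,
             ephys_type = if (cl$spike_width_us < 400) "fast" else "regular",
             transcriptomic_group = cl$transcriptomic_group,
             class_name = cl$name, jitter_sd_ms = cl$jitter_sd_ms,
             intrinsic_features = feats, sweep_sets = sweep_sets),
        class = "neuron_record")
    }
  }
  structure(pop, class = "neuron_population")
}

#' @export
print.neuron_record <- function(x, ...) {
  cat(sprintf("<neuron_record> %s (%s, %s): %d sweep sets\n", x$neuron_id,
              x$class_name, x$species, length(x$sweep_sets)))
  invisible(x)
}

#' @export
print.neuron_population <- function(x, ...) {
  cls <- table(vapply(x, function(n) n$class_name, character(1)))
  cat(sprintf("<neuron_population> %d neurons: %s\n", length(x),
              paste(sprintf("%s x%d", names(cls), cls), collapse = ", ")))
  invisible(x)
}

#' Per-neuron reliability table for a population
#'
#' Runs [corrected_reliability()] on each neuron's sweep sets at the chosen
#' intensity and averages the raw, shuffled and corrected values across the
#' two frozen noises, following the convention of analysing 100 % rheobase
#' responses (with a confirmation run possible at 150 %).
#'
#' @param population a `neuron_population` (or list of `neuron_record`s).
#' @param window_ms coincidence window (ms, default 1).
#' @param n_permutations surrogate draws per sweep set (default 100).
#' @param intensity_pct analysis intensity (default 100).
#' @param seed master seed for the permutation surrogates.
#' @return data.frame, one row per neuron: annotations, intrinsic features,
#'   `raw`, `shuffled_mean`, `corrected`, `n_pairs`. Neurons with fewer
#'   than 2 spiking sweeps in every noise get NA with a warning.
#' @export
reliability_table <- function(population, window_ms = 1,
                              n_permutations = 100, intensity_pct = 100,
                              seed = 1L) {
  seeds <- derive_seeds(seed, length(population) * 4L)
  rows <- lapply(seq_along(population), function(i) {
    nr <- population[[i]]
    sets <- Filter(function(s) s$intensity_pct == intensity_pct,
                   nr$sweep_sets)
    vals <- list()
    for (k in seq_along(sets)) {
      r <- tryCatch(
        corrected_reliability(sets[[k]], window_ms, n_permutations,
                              seed = seeds[(i - 1L) * 4L + k]),
        error = function(e) NULL)
      if (!is.null(r)) vals[[length(vals) + 1L]] <- r
    }
    base <- data.frame(
      neuron_id = nr$neuron_id, species = nr$species,
      morpho_type = nr$morpho_type, ephys_type = nr$ephys_type,
      transcriptomic_group = nr$transcriptomic_group,
      class_name = nr$class_name, jitter_sd_ms = nr$jitter_sd_ms,
      stringsAsFactors = FALSE)
    for (f in names(nr$intrinsic_features)) {
      base[[f]] <- nr$intrinsic_features[[f]]
    }
    if (length(vals) == 0L) {
      base$raw <- NA_real_; base$shuffled_mean <- NA_real_
      base$corrected <- NA_real_; base$n_pairs <- 0L
    } else {
      base$raw <- mean(vapply(vals, `[[`, 1, "raw_reliability"))
      base$shuffled_mean <- mean(vapply(vals, `[[`, 1, "shuffled_mean"))
      base$corrected <- mean(vapply(vals, `[[`, 1, "corrected_reliability"))
      base$n_pairs <- sum(vapply(vals, `[[`, 1L, "n_pairs"))
    }
    base
  })
  out <- do.call(rbind, rows)
  if (anyNA(out$corrected)) {
    warning(sprintf("%d neuron(s) had no sweep set with >= 2 spiking sweeps",
                    sum(is.na(out$corrected))), call. = FALSE)
  }
  out
}

#' Pool nearest-spike latencies across a population
#'
#' Latencies are pooled over both frozen noises (the convention used for
#' matching-spike CDF displays) and all neurons at one intensity.
#'
#' @inheritParams reliability_table
#' @param by optional annotation column to split by (e.g.
#'   `"transcriptomic_group"`).
#' @return if `by` is NULL a numeric vector of latencies (s); otherwise a
#'   named list of vectors.
#' @export
pooled_latencies <- function(population, intensity_pct = 100, by = NULL) {
  one <- function(nr) {
    sets <- Filter(function(s) s$intensity_pct == intensity_pct,
                   nr$sweep_sets)
    unlist(lapply(sets, function(s) {
      tr <- usable_sweeps(s$sweeps)
      if (length(tr) < 2L) return(numeric(0))
      unlist(lapply(seq_along(tr), function(i) {
        unlist(lapply(seq_along(tr), function(j) {
          if (i == j) return(numeric(0))
          nearest_spike_latencies(tr[[i]], tr[[j]])
        }))
      }))
    }), use.names = FALSE)
  }
  if (is.null(by)) {
    return(unlist(lapply(population, one), use.names = FALSE))
  }
  groups <- vapply(population, function(nr) as.character(nr[[by]]),
                   character(1))
  lapply(split(seq_along(population), groups), function(ix) {
    unlist(lapply(population[ix], one), use.names = FALSE)
  })
}
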