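# Spike-timing reliability metrics.
#
# The central statistic: for each ordered pair of repetitions of the same
# frozen noise at the same intensity, the fraction of spikes in one sweep
# that fall within a coincidence window (default 1 ms) of at least one spike
# in the other. Averaging over all ordered pairs gives a per-neuron value
# that is unbiased in the number of trials. A firing-rate correction
# subtracts the same statistic computed on surrogate sweeps whose spike
# counts are preserved but whose spike times are redrawn uniformly within
# the stimulus window (100 permutations by default).

#' Construct a sweep set
#'
#' Bundles one neuron's repeated responses to one frozen noise at one
#' intensity. Spike times are in seconds relative to stimulus-segment onset.
#'
#' @param neuron_id character id.
#' @param noise_id "Noise1" or "Noise2".
#' @param intensity_pct stimulus intensity as percent rheobase (75, 100, 150).
#' @param sweeps list of numeric spike-time vectors, each sorted ascending.
#' @param stimulus_window_s numeric length-2 `(start, end)` of the stimulus
#'   window in seconds (default `c(0, 3)`).
#' @param voltage optional list of voltage traces (mV), one per sweep.
#' @param sampling_rate_hz sampling rate of `voltage`, if present.
#' @return an object of class `sweep_set`.
#' @export
sweep_set <- function(neuron_id, noise_id, intensity_pct, sweeps,
                      stimulus_window_s = c(0, 3), voltage = NULL,
                      sampling_rate_hz = NULL) {
  stopifnot(is.list(sweeps))
  if (length(stimulus_window_s) != 2L ||
      stimulus_window_s[2] <= stimulus_window_s[1]) {
    stop("`stimulus_window_s` must be an increasing (start, end) pair",
         call. = FALSE)
  }
  sweeps <- lapply(seq_along(sweeps), function(i) {
    check_train(sweeps[[i]], sprintf("sweeps[[%d]]", i))
    sort(as.numeric(sweeps[[i]]))
  })
  if (!is.null(voltage) && length(voltage) != length(sweeps)) {
    stop("`voltage` must have one trace per sweep", call. = FALSE)
  }
  structure(
    list(neuron_id = as.character(neuron_id), noise_id = noise_id,
         intensity_pct = intensity_pct, sweeps = sweeps,
         stimulus_window_s = as.numeric(stimulus_window_s),
         voltage = voltage, sampling_rate_hz = sampling_rate_hz),
    class = "sweep_set"
  )
}

#' @export
print.sweep_set <- function(x, ...) {
  cat(sprintf("<sweep_set> %s %s @%g%%: %d sweeps, %s spikes\n",
              x$neuron_id, x$noise_id, x$intensity_pct, length(x$sweeps),
              paste(vapply(x$sweeps, length, 1L), collapse = "/")))
  invisible(x)
}

# Distance from each element of `a` to the nearest element of sorted `b`.
nearest_distance <- function(a, b) {
  i <- findInterval(a, b)
  lo <- pmax(i, 1L)
  hi <- pmin(i + 1L, length(b))
  pmin(abs(a - b[lo]), abs(a - b[hi]))
}

#' Latency from each spike to the closest spike of a reference train
#'
#' For each spike of `train_a`, the absolute time to the nearest spike in
#' `train_b`. Pooled over both directions and all sweep pairs these
#' latencies form the matching-spike cumulative distribution.
#'
#' @param train_a,train_b numeric spike-time vectors in seconds, sorted.
#' @return non-negative numeric vector, one latency per spike of `train_a`.
#' @examples
#' nearest_spike_latencies(c(0.010, 0.020, 0.030), c(0.0105, 0.025, 0.0302))
#' @export
nearest_spike_latencies <- function(train_a, train_b) {
  check_train(train_a, "train_a")
  check_train(train_b, "train_b")
  if (length(train_b) == 0L) {
    stop("`train_b` is empty: latency to the nearest spike is undefined",
         call. = FALSE)
  }
  if (length(train_a) == 0L) return(numeric(0))
  nearest_distance(train_a, train_b)
}

#' Cumulative distribution of nearest-spike latencies
#'
#' @param latencies non-negative numeric vector (seconds).
#' @param grid numeric vector of window sizes at which to evaluate the CDF.
#' @param method `"empirical"` (step ECDF) or `"gaussian-kernel"` (smooth
#'   Gaussian-kernel CDF estimate with the Silverman plug-in bandwidth;
#'   degenerates to the empirical CDF when the bandwidth is zero).
#' @return numeric vector of cumulative probabilities, same length as
#'   `grid`, non-decreasing within \[0, 1\].
#' @export
latency_cdf <- function(latencies, grid,
                        method = c("empirical", "gaussian-kernel")) {
  method <- match.arg(method)
  if (length(latencies) == 0L) {
    stop("`latencies` must be non-empty", call. = FALSE)
  }
  if (anyNA(latencies) || any(latencies < 0)) {
    stop("`latencies` must be non-negative and free of NA", call. = FALSE)
  }
  if (method == "gaussian-kernel") {
    h <- tryCatch(stats::bw.nrd0(latencies), error = function(e) 0)
    if (is.finite(h) && h > 0) {
      return(vapply(grid, function(g) mean(stats::pnorm((g - latencies) / h)),
                    numeric(1)))
    }
  }
  ec <- stats::ecdf(latencies)
  ec(grid)
}

#' Fraction of spikes matched within a coincidence window
#'
#' The fraction of spikes in `train_a` with at least one spike of `train_b`
#' within `window_ms` (inclusive boundary, |dt| <= window).
#'
#' @param train_a,train_b numeric spike-time vectors in seconds.
#' @param window_ms coincidence window in milliseconds (default 1).
#' @return a fraction in \[0, 1\].
#' @examples
#' matching_fraction(c(0.010, 0.020, 0.030), c(0.0105, 0.025, 0.0302)) # 2/3
#' @export
matching_fraction <- function(train_a, train_b, window_ms = 1) {
  check_scalar(window_ms, "window_ms", positive = TRUE)
  check_train(train_a, "train_a")
  check_train(train_b, "train_b")
  if (length(train_a) == 0L) {
    stop("`train_a` is empty: matching fraction is undefined", call. = FALSE)
  }
  if (length(train_b) == 0L) return(0)
  mean(nearest_distance(train_a, train_b) <= window_ms / 1000)
}

# Usable sweeps = those with at least one spike (a 0/0 fraction is
# undefined); callers may log the number excluded.
usable_sweeps <- function(sweeps) {
  sweeps[vapply(sweeps, length, 1L) > 0L]
}

# Validation-free mean directed matching fraction over all ordered pairs;
# trains must already be sorted and non-empty. Hot path of the permutation
# correction.
pairwise_mean_fraction <- function(trains, window_s) {
  n <- length(trains)
  tot <- 0
  for (i in seq_len(n)) {
    a <- trains[[i]]
    for (j in seq_len(n)) {
      if (i == j) next
      b <- trains[[j]]
      k <- findInterval(a, b)
      lo <- pmax(k, 1L)
      hi <- pmin(k + 1L, length(b))
      tot <- tot + mean(pmin(abs(a - b[lo]), abs(a - b[hi])) <= window_s)
    }
  }
  tot / (n * (n - 1L))
}

#' Raw matching-spike reliability of a sweep set
#'
#' Mean of [matching_fraction()] over all ordered pairs of usable sweeps
#' (sweeps without spikes are excluded). With the two directed fractions per
#' unordered pair averaged, the estimator's expectation does not depend on
#' the number of trials.
#'
#' @param sweeps a [sweep_set()] or a plain list of spike-time vectors.
#' @param window_ms coincidence window in milliseconds (default 1).
#' @return a fraction in \[0, 1\].
#' @export
spiking_reliability <- function(sweeps, window_ms = 1) {
  trains <- if (inherits(sweeps, "sweep_set")) sweeps$sweeps else sweeps
  trains <- usable_sweeps(trains)
  n <- length(trains)
  if (n < 2L) {
    stop("need at least 2 sweeps with >= 1 spike each", call. = FALSE)
  }
  tot <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      tot <- tot + matching_fraction(trains[[i]], trains[[j]], window_ms)
    }
  }
  tot / (n * (n - 1L))
}

#' Firing-rate-corrected matching-spike reliability
#'
#' Subtracts from the raw reliability its expectation under surrogate sweep
#' sets in which each sweep keeps its spike count but spike times are
#' redrawn uniformly within the stimulus window. This removes the chance
#' coincidence level set by the firing rate alone.
#'
#' @param sweeps a [sweep_set()].
#' @param window_ms coincidence window in milliseconds (default 1).
#' @param n_permutations number of surrogate draws (default 100).
#' @param seed integer seed for the surrogate generator.
#' @return an object of class `reliability_result` with fields `neuron_id`,
#'   `noise_id`, `intensity_pct`, `window_ms`, `raw_reliability`,
#'   `shuffled_mean`, `corrected_reliability` (raw minus shuffled mean; may
#'   be negative), `n_pairs`, `n_sweeps_excluded`, `n_permutations`,
#'   `latencies_s` (pooled bidirectional nearest-spike latencies).
#' @export
corrected_reliability <- function(sweeps, window_ms = 1, n_permutations = 100,
                                  seed = 1L) {
  stopifnot(inherits(sweeps, "sweep_set"))
  check_scalar(n_permutations, "n_permutations", positive = TRUE)
  trains <- usable_sweeps(sweeps$sweeps)
  n_excluded <- length(sweeps$sweeps) - length(trains)
  n <- length(trains)
  if (n < 2L) {
    stop("need at least 2 sweeps with >= 1 spike each", call. = FALSE)
  }
  raw <- spiking_reliability(trains, window_ms)

  win <- sweeps$stimulus_window_s
  counts <- vapply(trains, length, 1L)
  perm_seeds <- derive_seeds(seed, n_permutations)
  shuffled <- vapply(seq_len(n_permutations), function(p) {
    surr <- with_seed(perm_seeds[p], lapply(counts, function(k) {
      sort(stats::runif(k, win[1], win[2]))
    }))
    pairwise_mean_fraction(surr, window_ms / 1000)
  }, numeric(1))

  lat <- unlist(lapply(seq_len(n), function(i) {
    unlist(lapply(seq_len(n), function(j) {
      if (i == j) return(numeric(0))
      nearest_spike_latencies(trains[[i]], trains[[j]])
    }), use.names = FALSE)
  }), use.names = FALSE)

  structure(
    list(neuron_id = sweeps$neuron_id, noise_id = sweeps$noise_id,
         intensity_pct = sweeps$intensity_pct, window_ms = window_ms,
         raw_reliability = raw, shuffled_mean = mean(shuffled),
         corrected_reliability = raw - mean(shuffled),
         n_pairs = n * (n - 1L), n_sweeps_excluded = n_excluded,
         n_permutations = as.integer(n_permutations), latencies_s = lat),
    class = "reliability_result"
  )
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf(
    "<reliability_result> %s %s @%g%% (window %g ms)\n  raw %.4f  shuffled %.4f  corrected %.4f  (%d ordered pairs, %d permutations)\n",
    x$neuron_id, x$noise_id, x$intensity_pct, x$window_ms,
    x$raw_reliability, x$shuffled_mean, x$corrected_reliability,
    x$n_pairs, x$n_permutations))
  invisible(x)
}

#' Subthreshold voltage reliability
#'
#' Mean pairwise Spearman rank correlation between repetitions of the
#' membrane-voltage time course, computed on the below-threshold (75 %
#' rheobase) stimulus window. Constant traces are excluded from pair
#' formation with a warning.
#'
#' @param voltages list of equal-length numeric voltage traces (mV), already
#'   restricted to the stimulus window, or a [sweep_set()] carrying voltage.
#' @param window optional `(start, end)` in seconds to window the traces;
#'   requires `sampling_rate_hz`.
#' @param sampling_rate_hz sampling rate, required when `window` is given.
#' @return mean pairwise Spearman rho.
#' @export
subthreshold_reliability <- function(voltages, window = NULL,
                                     sampling_rate_hz = NULL) {
  if (inherits(voltages, "sweep_set")) {
    sampling_rate_hz <- voltages$sampling_rate_hz
    voltages <- voltages$voltage
  }
  if (!is.list(voltages) || length(voltages) < 2L) {
    stop("need at least 2 voltage traces", call. = FALSE)
  }
  if (length(unique(vapply(voltages, length, 1L))) != 1L) {
    stop("voltage traces must have equal lengths", call. = FALSE)
  }
  if (!is.null(window)) {
    if (is.null(sampling_rate_hz)) {
      stop("`sampling_rate_hz` is required when `window` is given",
           call. = FALSE)
    }
    idx <- seq(max(1L, floor(window[1] * sampling_rate_hz) + 1L),
               min(length(voltages[[1L]]), ceiling(window[2] * sampling_rate_hz)))
    voltages <- lapply(voltages, function(v) v[idx])
  }
  const <- vapply(voltages, function(v) stats::sd(v) == 0, logical(1))
  if (any(const)) {
    warning(sprintf("%d constant trace(s) excluded from pair formation",
                    sum(const)), call. = FALSE)
    voltages <- voltages[!const]
  }
  n <- length(voltages)
  if (n < 2L) stop("fewer than 2 usable (non-constant) traces", call. = FALSE)
  rhos <- c()
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      rhos <- c(rhos, stats::cor(voltages[[i]], voltages[[j]],
                                 method = "spearman"))
    }
  }
  mean(rhos)
}
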